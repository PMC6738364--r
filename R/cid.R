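#' @title Coefficient of intrinsic dependence (CID) and partial CID (pCID)
#' @description
#' `cid()` measures how much the conditional distribution of a response given
#' one or more predictors departs from its marginal distribution,
#'
#' \deqn{CID(Y|X) = \frac{1}{N}\;
#'   \frac{\sum_{i=1}^N \sum_{j=1}^N
#'     [\hat F(y_i|x_j) - \hat F(y_i)]^2}
#'   {\sum_{i=1}^N \hat F(y_i)[1 - \hat F(y_i)]}}
#'
#' with distribution functions estimated by kernel smoothing (see
#' [kernel_config()]).  CID is 0 when the conditional equals the marginal
#' (independence) and, in the empirical-CDF limit, exactly 1 for a strictly
#' monotone bijective pairing.  It is asymmetric: `CID(Y|X)` need not equal
#' `CID(X|Y)`, which is what permits direction assignment in network
#' construction.
#'
#' `pcid()` is the partial CID, the share of response-distribution
#' variability left unexplained by a conditioning set `X1` that a new
#' predictor `X2` explains:
#'
#' \deqn{pCID(Y|X_2;X_1) = \frac{CID(Y|X_2,X_1) - CID(Y|X_1)}{1 - CID(Y|X_1)}.}
#'
#' Unlike CID it may be slightly negative in finite samples.
#'
#' @param y Numeric response vector (N >= 5), or a probe id when `data` is
#'   supplied.
#' @param x Numeric predictor vector or N x d matrix, or probe ids.
#' @param cfg A [kernel_config()].
#' @param data Optional probes x samples expression matrix; when given, `y`
#'   and `x` (and `x1` for `pcid`) are interpreted as probe ids.
#' @return A `dependence_result` with fields `kind`, `response`,
#'   `predictors`, `value` (and unset `p_value`/`n_perm`; see [cid_test()]
#'   for permutation significance).
#' @examples
#' cfg <- kernel_config(degenerate_limit = TRUE)
#' cid(1:5, 5:1, cfg)$value            # strictly monotone pairing -> 1
#' set.seed(1)
#' y <- rnorm(50); x2 <- rnorm(50); x1 <- rnorm(50)
#' pcid(y, x2, x1)
#' @param smoothing_dim Optional override of the smoothing dimension `ncon`
#'   used by the dimension-adaptive bandwidth rule; `pcid()` evaluates both
#'   CIDs of its recursion at the joint dimension, and this argument lets a
#'   standalone `cid()` call reproduce those evaluations exactly.
#' @seealso [cid_test()], [pcid_test()] for permutation p-values.
#' @export
cid <- function(y, x, cfg = kernel_config(), data = NULL,
                smoothing_dim = NULL) {
  ids <- .resolve_vars(y, x, data)
  ws <- .cid_workspace(ids$y, ids$X, cfg, smoothing_dim = smoothing_dim)
  value <- .cid_value(ws$Ac, ws$Wn, ws$den, ws$N)
  .dependence_result("CID", ids$response, ids$predictors, value)
}

#' @rdname cid
#' @param x2 New predictor (vector or probe id).
#' @param x1 Conditioning set: numeric N x k matrix/vector or probe ids.
#' @export
pcid <- function(y, x2, x1, cfg = kernel_config(), data = NULL) {
  idy <- .resolve_vars(y, x2, data)
  idc <- .resolve_vars(y, x1, data)
  pair <- .pcid_workspaces(idy$y, idy$X, idc$X, cfg)
  value <- .pcid_value(pair, pair$joint$Ac, pair$cond$Ac)
  .dependence_result("pCID", idy$response,
                     c(idy$predictors, idc$predictors), value)
}

# ---- internals -------------------------------------------------------------

.resolve_vars <- function(y, x, data) {
  if (is.null(data)) {
    yv <- as.numeric(y)
    X <- as.matrix(x)
    response <- "Y"
    predictors <- if (!is.null(colnames(X))) colnames(X)
                  else paste0("X", seq_len(ncol(X)))
  } else {
    data <- .check_expression_matrix(data)
    yv <- as.numeric(data[y, ])
    X <- .probe_rows(data, x)
    response <- y
    predictors <- x
  }
  if (nrow(X) != length(yv)) stop("response and predictors differ in sample size")
  list(y = yv, X = X, response = response, predictors = predictors)
}

.dependence_result <- function(kind, response, predictors, value,
                               p_value = NA_real_, n_perm = NA_integer_) {
  structure(list(kind = kind, response = response, predictors = predictors,
                 value = value, p_value = p_value, n_perm = n_perm),
            class = "dependence_result")
}

#' @export
print.dependence_result <- function(x, ...) {
  cond <- if (x$kind == "pCID" && length(x$predictors) > 1L)
    paste0("; ", paste(x$predictors[-1L], collapse = ", ")) else ""
  preds <- if (x$kind == "pCID") x$predictors[1L]
           else paste(x$predictors, collapse = ", ")
  cat(sprintf("%s(%s|%s%s) = %.4f", x$kind, x$response, preds, cond, x$value))
  if (!is.na(x$p_value))
    cat(sprintf("  (p = %.4f, %d permutations)", x$p_value, x$n_perm))
  cat("\n")
  invisible(x)
}

# Drop predictor columns that duplicate an earlier column, so a conditioning
# variable listed twice carries no extra weight and the bandwidth dimension
# stays honest.
.dedup_cols <- function(X) {
  if (ncol(X) <= 1L) return(X)
  keep <- !duplicated(lapply(seq_len(ncol(X)), function(j) X[, j]))
  X[, keep, drop = FALSE]
}

# Precompute everything reusable across response permutations for CID(Y|X):
#   Ac  - row-centered response CDF kernel, Ac[i,k] = Phi_h(y_i - y_k) - Fm[i]
#   Wn  - column-normalized conditioning weights (fixed under Y-permutation)
#   den - sum_i Fm_i (1 - Fm_i), also permutation-invariant
.cid_workspace <- function(y, X, cfg, smoothing_dim = NULL) {
  N <- length(y)
  if (N < 5L) stop("need at least 5 samples")
  if (anyNA(y) || anyNA(X)) stop("missing values in statistics input")
  X <- .dedup_cols(as.matrix(X))
  d <- ncol(X)
  if (stats::sd(y) == 0) stop("degenerate response")
  ncon <- if (is.null(smoothing_dim)) 1L + d else smoothing_dim
  hy <- .bandwidth(y, ncon, cfg)
  Phi <- .cdf_kernel(y, y, hy, cfg$degenerate_limit)
  Fm <- rowMeans(Phi)
  den <- sum(Fm * (1 - Fm))
  if (den < 1e-12) stop("degenerate response")
  hx <- vapply(seq_len(d), function(p) .bandwidth(X[, p], ncon, cfg), 0)
  Wn <- .cond_weights(X, X, hx, cfg$degenerate_limit)
  list(N = N, Ac = Phi - Fm, Fm = Fm, Wn = Wn, den = den)
}

.cid_value <- function(Ac, Wn, den, N) {
  sum((Ac %*% Wn)^2) / (N * den)
}

# Joint and conditioning workspaces for pCID(Y|X2; X1).  Both CIDs of the
# recursion are smoothed at the joint statistic's dimension so that their
# difference compares like-smoothed quantities; otherwise the lower-
# dimensional conditioning CID would be systematically sharper and the
# partial statistic biased downward.
.pcid_workspaces <- function(y, X2, X1, cfg) {
  X1 <- .dedup_cols(as.matrix(X1))
  Xj <- .dedup_cols(cbind(as.matrix(X2), X1))
  dim_joint <- 1L + ncol(Xj)
  joint <- .cid_workspace(y, Xj, cfg, smoothing_dim = dim_joint)
  cond <- .cid_workspace(y, X1, cfg, smoothing_dim = dim_joint)
  list(joint = joint, cond = cond, N = joint$N)
}

# pCID from (possibly permuted) centered response kernels.
.pcid_value <- function(pair, Ac_joint, Ac_cond) {
  c1 <- .cid_value(Ac_joint, pair$joint$Wn, pair$joint$den, pair$N)
  c0 <- .cid_value(Ac_cond, pair$cond$Wn, pair$cond$den, pair$N)
  if (1 - c0 < 1e-12) stop("saturated conditioning set")
  (c1 - c0) / (1 - c0)
}
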