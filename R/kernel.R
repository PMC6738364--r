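#' Kernel configuration for CDF estimation
#'
#' Settings for the nonparametric distribution-function estimators behind the
#' CID and pCID statistics.  The response CDF is smoothed with an integrated
#' Gaussian kernel; conditioning uses a product of Gaussian density weights
#' (Nadaraya-Watson) over the predictors.
#'
#' Bandwidths follow a normal-reference rule
#' `h = 1.06 * sigma * N^(-gamma) * bandwidth_scale` per variable, with
#' `sigma = min(sd, IQR/1.349)`.  Two variants of the exponent are offered:
#' `"normal-reference"` (default) uses `gamma = 1/(4 + ncon)` where `ncon`
#' counts the continuous variables in the statistic (response plus distinct
#' predictors), so joint conditioning sets are smoothed more heavily, as
#' multivariate reference rules do; `"normal-reference-fixed"` pins
#' `gamma = 1/5` for every statistic (the univariate rule-of-thumb applied
#' per variable, regardless of dimension).
#'
#' @param kernel_family Kernel family; only `"gaussian"` is implemented.
#' @param bandwidth_rule `"normal-reference"` (default) or
#'   `"normal-reference-fixed"`, as described above.
#' @param bandwidth_scale Positive multiplier applied to every bandwidth.
#' @param degenerate_limit If `TRUE`, use the bandwidth-to-zero limit:
#'   empirical (indicator) CDFs and conditioning weights concentrated on
#'   samples with exactly matching predictor values.  This limit admits exact
#'   finite-sample oracles and gives CID = 1 for strictly monotone pairings.
#' @return An object of class `kernel_config`.
#' @examples
#' kernel_config()
#' kernel_config(degenerate_limit = TRUE)
#' @export
kernel_config <- function(kernel_family = "gaussian",
                          bandwidth_rule = "normal-reference",
                          bandwidth_scale = 1,
                          degenerate_limit = FALSE) {
  kernel_family <- match.arg(kernel_family, "gaussian")
  bandwidth_rule <- match.arg(bandwidth_rule,
                              c("normal-reference", "normal-reference-fixed"))
  if (!is.numeric(bandwidth_scale) || length(bandwidth_scale) != 1L ||
      !is.finite(bandwidth_scale) || bandwidth_scale <= 0)
    stop("bandwidth_scale must be a positive number")
  structure(list(kernel_family = kernel_family,
                 bandwidth_rule = bandwidth_rule,
                 bandwidth_scale = bandwidth_scale,
                 degenerate_limit = isTRUE(degenerate_limit)),
            class = "kernel_config")
}

# Robust scale estimate used by the normal-reference rule.  Returns 0 for a
# constant vector.
.sigma_hat <- function(v) {
  s1 <- stats::sd(v)
  s2 <- stats::IQR(v) / 1.349
  cand <- c(s1, s2)
  cand <- cand[is.finite(cand) & cand > 0]
  if (!length(cand)) return(0)
  min(cand)
}

# Normal-reference bandwidth for one variable within a statistic that
# involves `ncon` continuous variables in total.
.bandwidth <- function(v, ncon, cfg) {
  N <- length(v)
  s <- .sigma_hat(v)
  if (s <= 0) return(0)
  gamma <- if (cfg$bandwidth_rule == "normal-reference-fixed") 1 / 5
           else 1 / (4 + ncon)
  1.06 * s * N^(-gamma) * cfg$bandwidth_scale
}

# Smoothed CDF kernel matrix: entry [i, k] = Phi((eval_i - y_k) / h).
# In the degenerate limit this is the indicator 1{y_k <= eval_i}.
.cdf_kernel <- function(eval_points, y, h, degenerate) {
  if (degenerate || h <= 0) {
    outer(eval_points, y, ">=") * 1
  } else {
    stats::pnorm(outer(eval_points, y, "-") / h)
  }
}

# Column-normalized conditioning weights W[k, j]: contribution of data
# sample k to the conditional CDF evaluated at predictor row j of eval_x.
# Zero-variance predictors contribute uniform weights (with a warning), so
# the conditional estimate falls back toward the marginal.
.cond_weights <- function(x, eval_x, hx, degenerate) {
  N <- nrow(x); m <- nrow(eval_x); d <- ncol(x)
  W <- matrix(1, N, m)
  for (p in seq_len(d)) {
    if (hx[p] <= 0 && !degenerate) {
      warning(sprintf("predictor %d has zero variance; using uniform weights", p))
      next
    }
    if (degenerate) {
      W <- W * outer(x[, p], eval_x[, p], "==") * 1
    } else {
      W <- W * stats::dnorm(outer(x[, p], eval_x[, p], "-") / hx[p])
    }
  }
  cs <- colSums(W)
  zero <- cs <= 0
  if (any(zero)) {        # no matching sample / numerically empty window
    W[, zero] <- 1
    cs[zero] <- N
  }
  sweep(W, 2, cs, "/")
}

#' Kernel-smoothed marginal CDF
#'
#' Estimates the marginal distribution function of a response at arbitrary
#' evaluation points, either smoothed (integrated Gaussian kernel with the
#' normal-reference bandwidth) or as the empirical CDF in the degenerate
#' limit.
#'
#' @param y Numeric response vector (N >= 5).
#' @param eval_points Finite numeric vector of evaluation points.
#' @param cfg A [kernel_config()].
#' @return Numeric vector of CDF values in \[0, 1\], one per evaluation point.
#' @examples
#' estimate_marginal_cdf(1:5, 1:5, kernel_config(degenerate_limit = TRUE))
#' @export
estimate_marginal_cdf <- function(y, eval_points, cfg = kernel_config()) {
  stopifnot(inherits(cfg, "kernel_config"))
  y <- as.numeric(y)
  if (length(y) < 5L) stop("need at least 5 samples")
  if (anyNA(y) || !all(is.finite(y))) stop("missing values in response")
  if (!all(is.finite(eval_points))) stop("eval_points must be finite")
  if (.sigma_hat(y) <= 0 && stats::sd(y) == 0) stop("degenerate response")
  h <- .bandwidth(y, ncon = 1L, cfg)
  K <- .cdf_kernel(as.numeric(eval_points), y, h, cfg$degenerate_limit)
  rowMeans(K)
}

#' Kernel-smoothed conditional CDF
#'
#' Estimates `F(y | x)` by Nadaraya-Watson weighting: a product of Gaussian
#' density kernels over the predictor columns supplies the weights, and the
#' response enters through an integrated Gaussian kernel.  Entry `(i, j)` of
#' the result estimates `F(eval_y[i] | X = eval_x[j, ])`.
#'
#' @param y Numeric response vector of length N.
#' @param x Numeric predictor matrix (N x d, d >= 1); a vector is treated as
#'   a single column.
#' @param eval_y Numeric vector of response evaluation points.
#' @param eval_x Numeric matrix (m x d) of predictor evaluation points.
#' @param cfg A [kernel_config()].
#' @return A `length(eval_y)` x `nrow(eval_x)` matrix of values in \[0, 1\].
#' @export
estimate_conditional_cdf <- function(y, x, eval_y, eval_x, cfg = kernel_config()) {
  stopifnot(inherits(cfg, "kernel_config"))
  y <- as.numeric(y)
  x <- as.matrix(x)
  eval_x <- as.matrix(eval_x)
  if (nrow(x) != length(y)) stop("y and x must have the same number of samples")
  if (ncol(eval_x) != ncol(x)) stop("eval_x must have the same columns as x")
  if (length(y) < 5L) stop("need at least 5 samples")
  ncon <- 1L + ncol(x)
  hy <- .bandwidth(y, ncon, cfg)
  hx <- vapply(seq_len(ncol(x)), function(p) .bandwidth(x[, p], ncon, cfg), 0)
  K <- .cdf_kernel(as.numeric(eval_y), y, hy, cfg$degenerate_limit)
  W <- .cond_weights(x, eval_x, hx, cfg$degenerate_limit)
  K %*% W
}
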