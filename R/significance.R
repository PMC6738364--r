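#' Permutation plan for CID/pCID significance
#'
#' Settings for the response-permutation null.  Only the response vector is
#' permuted; predictors and conditioning sets stay fixed.  With the default
#' 1000 permutations and observed-inclusive counting the attainable minimum
#' p-value is 1/1001 = 0.0010.
#'
#' Each statistic draws its permutations from an RNG substream derived from
#' the master `seed` and a stable hash of (response id, predictor ids,
#' conditioning ids, elongation step), so results are independent of the
#' order in which candidate tests are evaluated.
#'
#' @param n_perm Number of permutations (>= 1), default 1000.
#' @param seed Master integer seed.
#' @param refit_bandwidths If `TRUE`, bandwidths and conditioning weights are
#'   recomputed from scratch for every permuted response (slow path, used for
#'   verification).  Under the normal-reference rule a response permutation
#'   leaves all bandwidths unchanged, so the default `FALSE` is exact, not an
#'   approximation.
#' @return An object of class `permutation_plan`.
#' @export
permutation_plan <- function(n_perm = 1000L, seed = 1L, refit_bandwidths = FALSE) {
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) stop("n_perm must be a positive integer")
  structure(list(n_perm = n_perm, seed = seed,
                 refit_bandwidths = isTRUE(refit_bandwidths),
                 count_rule = "observed-inclusive >="),
            class = "permutation_plan")
}

#' Permutation p-value with observed-inclusive counting
#'
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.  The observed statistic
#' counts as one of the "values greater than or equal to" itself, so with
#' 1000 permutations the smallest attainable p-value is 1/1001 = 0.0010.
#'
#' @param observed Observed statistic (finite scalar).
#' @param null Numeric vector of null statistics (nonempty, finite).
#' @return p-value in `[1/(n_perm+1), 1]`.
#' @examples
#' pvalue(0.5, c(0.1, 0.2, 0.5, 0.6))   # (1 + 2) / 5
#' @export
pvalue <- function(observed, null) {
  if (length(null) < 1L) stop("null distribution is empty")
  if (!is.finite(observed) || !all(is.finite(null)))
    stop("NaN/non-finite values in p-value inputs")
  # ties counted with a small tolerance so that exactly-null statistics
  # (e.g. a constant predictor, value 0 in every permutation) give p = 1
  # instead of ranking floating-point noise
  (1 + sum(null >= observed - 1e-12)) / (length(null) + 1)
}

# Statistic specification constructor shared by the significance layer and
# the simulator's summary tables.  `conditioning` empty => CID, else pCID.
.stat_spec <- function(response, predictor, conditioning = character()) {
  list(response = response, predictor = predictor,
       conditioning = as.character(conditioning))
}

#' Parse a statistic label
#'
#' Converts labels such as `"CID(A11|A21)"` or
#' `"pCID(A21|A31; A11, A22)"` into the specification list used by
#' [permutation_null()] and [replicate_experiment()].
#'
#' @param label Character scalar.
#' @return List with `response`, `predictor`, `conditioning`.
#' @export
parse_stat_label <- function(label) {
  m <- regmatches(label, regexec(
    "^\\s*p?CID\\(\\s*([^|]+?)\\s*\\|\\s*([^;\\)]+?)\\s*(?:;\\s*([^\\)]*?)\\s*)?\\)\\s*$",
    label))[[1]]
  if (!length(m)) stop("cannot parse statistic label: ", label)
  cond <- if (is.na(m[4]) || m[4] == "") character()
          else trimws(strsplit(m[4], ",")[[1]])
  .stat_spec(trimws(m[2]), trimws(m[3]), cond)
}

.stat_key <- function(spec, step = 0L) {
  paste(spec$response, spec$predictor,
        paste(spec$conditioning, collapse = ","), step, sep = "|")
}

# Generate the permutation indices for one statistic, reproducibly.
.perm_indices <- function(N, n_perm, seed) {
  .with_seed(seed, replicate(n_perm, sample.int(N), simplify = FALSE))
}

#' Permutation null distribution of a CID or pCID statistic
#'
#' Recomputes the statistic `n_perm` times after independently permuting the
#' response vector only.  For a pCID the full recursion (joint and
#' conditioning CID) is re-evaluated on each permuted response.
#'
#' @param statistic A specification from [parse_stat_label()] or a label
#'   string.
#' @param data Probes x samples expression matrix containing all named
#'   probes.
#' @param plan A [permutation_plan()].
#' @param cfg A [kernel_config()].
#' @param step Elongation step index, part of the substream key.
#' @return Numeric vector of `n_perm` null statistics.
#' @export
permutation_null <- function(statistic, data, plan = permutation_plan(),
                             cfg = kernel_config(), step = 0L) {
  .perm_test(statistic, data, plan, cfg, step)$null
}

# Shared engine: observed statistic plus permutation null.
.perm_test <- function(statistic, data, plan, cfg, step = 0L) {
  if (is.character(statistic) && length(statistic) == 1L)
    statistic <- parse_stat_label(statistic)
  data <- .check_expression_matrix(data)
  if (statistic$predictor == statistic$response ||
      statistic$response %in% statistic$conditioning)
    stop("response must be distinct from predictors")
  y <- as.numeric(data[statistic$response, ])
  N <- length(y)
  seed <- .substream_seed(plan$seed, .stat_key(statistic, step))
  perms <- .perm_indices(N, plan$n_perm, seed)
  is_pcid <- length(statistic$conditioning) > 0L

  if (is_pcid) {
    X2 <- .probe_rows(data, statistic$predictor)
    X1 <- .probe_rows(data, statistic$conditioning)
    pair <- .pcid_workspaces(y, X2, X1, cfg)
    observed <- .pcid_value(pair, pair$joint$Ac, pair$cond$Ac)
    null <- vapply(seq_along(perms), function(b) {
      p <- perms[[b]]
      if (plan$refit_bandwidths) {
        pb <- .pcid_workspaces(y[p], X2, X1, cfg)
        .pcid_value(pb, pb$joint$Ac, pb$cond$Ac)
      } else {
        tryCatch(
          .pcid_value(pair, pair$joint$Ac[p, p], pair$cond$Ac[p, p]),
          error = function(e) stop(sprintf("permutation %d: %s", b,
                                           conditionMessage(e)), call. = FALSE))
      }
    }, 0)
  } else {
    X <- .probe_rows(data, statistic$predictor)
    ws <- .cid_workspace(y, X, cfg)
    observed <- .cid_value(ws$Ac, ws$Wn, ws$den, ws$N)
    null <- vapply(seq_along(perms), function(b) {
      p <- perms[[b]]
      if (plan$refit_bandwidths) {
        wb <- .cid_workspace(y[p], X, cfg)
        .cid_value(wb$Ac, wb$Wn, wb$den, wb$N)
      } else {
        .cid_value(ws$Ac[p, p], ws$Wn, ws$den, ws$N)
      }
    }, 0)
  }
  list(observed = observed, null = null, statistic = statistic)
}

#' Permutation significance test for CID / pCID
#'
#' Composes the statistic evaluation, the response-permutation null and the
#' observed-inclusive p-value into a filled `dependence_result`.
#'
#' @param data Probes x samples expression matrix.
#' @param response,predictor Probe ids.
#' @param conditioning Character vector of conditioning probe ids (empty for
#'   a plain CID).
#' @param plan A [permutation_plan()].
#' @param cfg A [kernel_config()].
#' @param step Elongation step index (affects only the RNG substream).
#' @return A `dependence_result` with `value`, `p_value` and `n_perm` set.
#' @export
cid_test <- function(data, response, predictor, plan = permutation_plan(),
                     cfg = kernel_config(), step = 0L) {
  r <- .perm_test(.stat_spec(response, predictor), data, plan, cfg, step)
  .dependence_result("CID", response, predictor, r$observed,
                     pvalue(r$observed, r$null), plan$n_perm)
}

#' @rdname cid_test
#' @export
pcid_test <- function(data, response, predictor, conditioning,
                      plan = permutation_plan(), cfg = kernel_config(),
                      step = 0L) {
  if (!length(conditioning)) return(cid_test(data, response, predictor, plan, cfg, step))
  r <- .perm_test(.stat_spec(response, predictor, conditioning),
                  data, plan, cfg, step)
  .dependence_result("pCID", response, c(predictor, conditioning), r$observed,
                     pvalue(r$observed, r$null), plan$n_perm)
}
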