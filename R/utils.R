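# Internal helpers shared across modules.

# Deterministic 31-bit hash of a character key, used to derive independent
# RNG substreams per statistic so that results do not depend on the order in
# which candidate tests are evaluated.
.hash31 <- function(key) {
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483647
  h
}

# Combine a master seed with a string key into a substream seed < 2^31.
.substream_seed <- function(seed, key) {
  s <- as.numeric(seed) %% 2147483647
  (s * 48271 + .hash31(key)) %% 2147483647
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the global
# RNG state is restored afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483646) + 1L)
  expr
}

# Validate a probes x samples expression matrix and return it as a plain
# numeric matrix.  Rows containing missing values are dropped with a warning.
.check_expression_matrix <- function(data, min_samples = 5L) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("expression data must be a numeric matrix (probes x samples)")
  if (is.null(rownames(data)) || anyDuplicated(rownames(data)))
    stop("expression matrix must have unique probe ids as row names")
  bad <- rowSums(!is.finite(data)) > 0
  if (any(bad)) {
    warning(sprintf("dropping %d probe(s) with missing/non-finite values", sum(bad)))
    data <- data[!bad, , drop = FALSE]
  }
  if (ncol(data) < min_samples)
    stop(sprintf("need at least %d samples, got %d", min_samples, ncol(data)))
  data
}

.probe_rows <- function(data, ids) {
  missing <- setdiff(ids, rownames(data))
  if (length(missing))
    stop("unknown probe id(s): ", paste(missing, collapse = ", "))
  t(data[ids, , drop = FALSE])   # samples x probes
}
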