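# Shared fixtures, generated in code.

# Small dependent dataset: y = x + noise.
toy_linear <- function(N = 100, seed = 42) {
  set.seed(seed)
  x <- rnorm(N)
  list(x = x, y = x + rnorm(N, sd = 0.3))
}

# Expression matrix wrapping arbitrary vectors.
as_expr <- function(...) {
  vs <- list(...)
  m <- do.call(rbind, vs)
  rownames(m) <- names(vs)
  colnames(m) <- paste0("S", seq_len(ncol(m)))
  m
}

# The printed selection walk-through statistics for one N = 25 draw of the
# six-node benchmark: CID/pCID values with their permutation p-values, as
# a table the replay engine can consume.
walkthrough_table <- function() {
  txt <- "
CID(A11|A21)@0.2146@0.0010
CID(A11|A22)@0.2039@0.0010
CID(A11|A31)@0.1019@0.0060
CID(A11|A32)@0.0425@0.0949
CID(A11|B)@0.0534@0.0639
CID(A21|A11)@0.1905@0.0010
pCID(A11|A22; A21)@0.1679@0.0010
pCID(A22|A11; A21)@0.1460@0.0030
pCID(A11|A31; A21)@0.0288@0.5075
pCID(A11|A32; A21)@0.0315@0.4575
pCID(A11|B; A21)@0.0133@0.6444
pCID(A21|A22; A11)@0.0027@0.8462
pCID(A21|A31; A11)@0.1581@0.0010
pCID(A21|A32; A11)@0.0934@0.0120
pCID(A21|B; A11)@0.0363@0.2957
pCID(A11|A31; A21, A22)@0.0285@0.0889
pCID(A11|A32; A21, A22)@0.0129@0.3247
pCID(A11|B; A21, A22)@-0.0010@0.6114
pCID(A21|A31; A11, A22)@0.1751@0.0020
pCID(A31|A21; A11, A22)@0.1707@0.0020
pCID(A21|A32; A11, A22)@0.1001@0.0559
pCID(A21|B; A11, A22)@0.0523@0.3187
pCID(A22|A31; A11, A21)@0.0007@0.8961
pCID(A22|A32; A11, A21)@0.0059@0.7872
pCID(A22|B; A11, A21)@-0.0036@0.9171
pCID(A11|A32; A21, A22, A31)@-0.0019@0.7772
pCID(A11|B; A21, A22, A31)@-0.0055@0.7972
pCID(A21|A32; A11, A22, A31)@0.1165@0.0070
pCID(A32|A21; A11, A22, A31)@0.0768@0.8392
pCID(A21|B; A11, A22, A31)@0.0272@0.7772
pCID(A22|A32; A11, A21, A31)@0.0147@0.7692
pCID(A22|B; A11, A21, A31)@0.0008@0.9411
pCID(A31|A32; A11, A21, A22)@0.0523@0.2567
pCID(A31|B; A11, A21, A22)@0.0196@0.8192
pCID(A11|B; A21, A22, A31, A32)@0.0182@0.3596
pCID(A21|B; A11, A22, A31, A32)@0.0257@0.7453
pCID(A22|B; A11, A21, A31, A32)@0.0023@0.9610
pCID(A31|B; A11, A21, A22, A32)@0.0156@0.8611
pCID(A32|B; A11, A21, A22, A31)@0.0368@0.7203
CID(B|A11)@0.0273@0.6613
CID(B|A21)@0.0112@0.6394
CID(B|A22)@0.0321@0.2078
CID(B|A31)@0.0127@0.5784
CID(B|A32)@0.0204@0.3686
"
  rows <- strsplit(trimws(strsplit(txt, "\n")[[1]]), "@")
  rows <- rows[lengths(rows) == 3L]
  do.call(rbind, lapply(rows, function(r) {
    sp <- parse_stat_label(r[1L])
    data.frame(response = sp$response, predictor = sp$predictor,
               conditioning = paste(sp$conditioning, collapse = ","),
               value = as.numeric(r[2L]), p_value = as.numeric(r[3L]),
               stringsAsFactors = FALSE)
  }))
}

replay_engine <- function(df = walkthrough_table()) {
  cidnet:::.table_engine(df)
}
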