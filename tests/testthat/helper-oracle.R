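# Independent quadratic reference for local alignment scores: a plain-R
# Gotoh DP, written without reference to the package implementation. Gap
# of length L costs open + extend * L; gap states may follow any state;
# N in either sequence scores as a mismatch; the empty alignment scores 0.
sw_oracle_score <- function(query, target, match = 2, mismatch = 3,
                            open = 5, extend = 2) {
  q <- strsplit(query, "")[[1L]]
  t <- strsplit(target, "")[[1L]]
  n <- length(q); m <- length(t)
  NEG <- -Inf
  M <- matrix(0, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (q[i] == "N" || t[j] == "N" || q[i] != t[j]) -mismatch else match
      M[i + 1L, j + 1L] <-
        max(0, M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - extend,
                               X[i, j + 1L] - extend,
                               Y[i, j + 1L] - open - extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - extend,
                               X[i + 1L, j] - open - extend,
                               Y[i + 1L, j] - extend)
      if (M[i + 1L, j + 1L] > best) best <- M[i + 1L, j + 1L]
    }
  }
  best
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
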