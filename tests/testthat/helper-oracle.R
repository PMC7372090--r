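# Independent brute-force oracle for affine-gap local alignment, written
# against the scoring definition only (no seeding, no banding, no shared
# code with the package implementation).  A gap of length L scores
# gap_open + L * gap_extend; the empty alignment scores 0.
sw_oracle_score <- function(a, b, match = 2, mismatch = -3,
                            gap_open = -5, gap_extend = -2) {
  m <- nchar(a); n <- nchar(b)
  if (m == 0 || n == 0) return(0)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1) # ends with gap consuming b
  F <- matrix(NEG, m + 1, n + 1) # ends with gap consuming a
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] + gap_open + gap_extend,
                     E[i, j - 1] + gap_extend)
      F[i, j] <- max(H[i - 1, j] + gap_open + gap_extend,
                     F[i - 1, j] + gap_extend)
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
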