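# Independent brute-force sample-entropy oracle: a literal loop over all
# ordered template pairs, written without reference to the package's
# kernel. Ordered pairs in both directions, self-matches excluded,
# Chebyshev distance, inclusive boundary.
sampen_bruteforce <- function(x, m, r_abs) {
  n <- length(x)
  a <- 0L
  b <- 0L
  for (i in seq_len(n - m)) {
    for (j in seq_len(n - m)) {
      if (i == j) next
      dmax <- 0
      for (k in 0:(m - 1)) {
        dk <- abs(x[i + k] - x[j + k])
        if (dk > dmax) dmax <- dk
      }
      if (dmax <= r_abs) {
        b <- b + 1L
        if (abs(x[i + m] - x[j + m]) <= r_abs) a <- a + 1L
      }
    }
  }
  list(se = if (a > 0L && b > 0L) -log(a / b) else NA_real_,
       a_count = a, b_count = b)
}

# Spearman rho by explicit rank formula (no ties), as a hand oracle.
spearman_by_ranks <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
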