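# Independent brute-force oracles. These deliberately share no code with the
# package: the KS oracle walks every list position; the permutation oracle
# enumerates label assignments; the log-rank oracle iterates 2x2 tables; the
# hypergeometric oracle multiplies binomial coefficients directly.

# KS tag enrichment by explicit walk over all n positions.
ks_oracle <- function(tag_ranks, n) {
  t <- length(tag_ranks)
  if (t == n) return(0)
  hits <- 0L
  a <- -Inf
  b <- -Inf
  for (pos in seq_len(n)) {
    if (pos %in% tag_ranks) {
      hits <- hits + 1L
      a <- max(a, hits / t - pos / n)
      b <- max(b, pos / n - (hits - 1L) / t)
    }
  }
  if (a >= b) a else -b
}

# Welch t statistic via stats::t.test (independent of the package's
# vectorized computation).
welch_t_oracle <- function(x, y) {
  unname(stats::t.test(x, y, var.equal = FALSE)$statistic)
}

# Exhaustive two-group permutation p-value: fraction of all C(n, n1) label
# assignments whose |t| is at least the observed |t|.
perm_p_exhaustive <- function(values, n_case) {
  n <- length(values)
  idx <- utils::combn(n, n_case)
  t_obs <- abs(welch_t_oracle(values[seq_len(n_case)],
                              values[-seq_len(n_case)]))
  t_all <- apply(idx, 2L, function(cs) {
    abs(welch_t_oracle(values[cs], values[-cs]))
  })
  mean(t_all >= t_obs - 1e-12)
}

# Exact binomial coefficient by iterative product (each intermediate value
# is itself a binomial coefficient, so doubles stay exact below 2^53).
choose_oracle <- function(n, k) {
  if (k < 0 || k > n) return(0)
  k <- min(k, n - k)
  out <- 1
  for (i in seq_len(k)) out <- out * (n - k + i) / i
  out
}

hyper_point_oracle <- function(k, K, n_draw, N) {
  choose_oracle(K, k) * choose_oracle(N - K, n_draw - k) / choose_oracle(N, n_draw)
}

# Two-group log-rank chi-square by explicit iteration over the 2x2 table at
# each distinct event time.
logrank_oracle <- function(time, event, group) {
  lev <- sort(unique(group))
  stopifnot(length(lev) == 2L)
  g1 <- group == lev[1L]
  o1 <- 0; e1 <- 0; v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# Small helper: named ranking vector for a universe laid out 1..n.
make_ranking <- function(ranks, genes = paste0("G", seq_along(ranks))) {
  stats::setNames(as.integer(ranks), genes)
}

tmpfile <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
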