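# Independent oracles, deliberately written along different routes than the
# package implementation.

# BH step-up, straight from the definition: sort ascending, p_(i) * m / i,
# cumulative minimum from the largest rank down, cap at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Upper-tail hypergeometric by direct log-binomial summation.
oracle_hyper_tail <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  i <- max(k, max(0L, n + K - N)):hi
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Upper-tail hypergeometric by exhaustive enumeration of all draws (tiny N).
oracle_hyper_enum <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are the successes
  mean(hits >= k)
}

# Empirical survival function: proportion of subjects surviving past t.
oracle_empirical_surv <- function(time, t) {
  mean(time > t)
}

# Two-group log-rank by explicit observed-minus-expected tabulation over
# distinct event times.
oracle_logrank <- function(time, event, group) {
  group <- as.character(group)
  lv <- sort(unique(group))
  stopifnot(length(lv) == 2L)
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == lv[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == lv[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

# A tiny deterministic proteome for digestion/mapping round trips.
tiny_proteome <- function(n = 6, seed = 42) {
  generate_proteome(n, seed, n_frag_range = c(5L, 9L))
}
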