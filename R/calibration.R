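#' Type-I error of the per-feature Welch test under the null
#'
#' Simulates a matrix of null features (both groups drawn from the same
#' normal distribution), runs [differential_test()] and reports the fraction
#' of raw p values below `alpha`. Each feature is an independent replicate
#' of the test.
#'
#' @param n_features Number of null features (replicates).
#' @param n_per_group Samples per group.
#' @param alpha Nominal level.
#' @param seed Seed.
#' @return List with `rate`, `n_features`, `alpha`, and the 3-sigma binomial
#'   `bound` around `alpha`.
#' @export
calibrate_welch_type1 <- function(n_features = 2000L, n_per_group = 4L,
                                  alpha = 0.05, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_group
  vals <- matrix(stats::rnorm(n_features * n), nrow = n_features,
                 dimnames = list(sprintf("f%05d", seq_len(n_features)),
                                 sprintf("s%02d", seq_len(n))))
  grp <- stats::setNames(rep(c("A", "B"), each = n_per_group), colnames(vals))
  res <- differential_test(vals, grp, "A", "B")
  rate <- mean(res$p < alpha, na.rm = TRUE)
  list(rate = rate, n_features = n_features, alpha = alpha,
       bound = 3 * sqrt(alpha * (1 - alpha) / n_features))
}

#' Type-I error of the log-rank test under the null
#'
#' Replicated two-arm cohorts with identical survival distributions
#' (exponential times, label-independent censoring); reports the rejection
#' rate of [logrank_test()] at `alpha`.
#'
#' @param n_reps Number of replicate cohorts.
#' @param n_per_arm Samples per arm.
#' @param censor_rate Fraction censored.
#' @param alpha Nominal level.
#' @param seed Seed.
#' @return List with `rate`, `n_reps`, `alpha`, and the 3-sigma binomial
#'   `bound` around `alpha`.
#' @export
calibrate_logrank_type1 <- function(n_reps = 1000L, n_per_arm = 30L,
                                    censor_rate = 0.2, alpha = 0.05, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_arm
  arm <- rep(c("a", "b"), each = n_per_arm)
  p <- vapply(seq_len(n_reps), function(r) {
    time <- stats::rexp(n)
    event <- rep(1L, n)
    n_cens <- floor(censor_rate * n)
    if (n_cens > 0L) {
      idx <- sample(n, n_cens)
      time[idx] <- stats::runif(n_cens) * time[idx]
      event[idx] <- 0L
    }
    logrank_test(time, event, arm)$p_value
  }, numeric(1))
  list(rate = mean(p < alpha), n_reps = n_reps, alpha = alpha,
       bound = 3 * sqrt(alpha * (1 - alpha) / n_reps))
}
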