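test_that("signature score is the log2 geometric mean over present genes", {
  m <- rbind(g1 = c(s1 = 2, s2 = 5), g2 = c(s1 = 4, s2 = 5))
  sc <- signature_score(m, c("g1", "g2"))
  expect_equal(unname(sc["s1"]), 3)      # sqrt(4 * 16) = 8 on the linear scale
  expect_equal(unname(sc["s2"]), 5)      # all-equal profile returns that value
  # gene-order permutation invariance and missing-gene logging
  sc2 <- signature_score(m, c("g2", "gX", "g1"))
  expect_equal(as.numeric(sc2), as.numeric(sc))
  expect_equal(attr(sc2, "missing_genes"), "gX")
  expect_error(signature_score(m, "gX"), "none of the")
  expect_error(signature_score(m - 10, "g1"), "negative")
})

test_that("density dichotomization splits a bimodal mixture near the valley", {
  set.seed(123)
  x <- c(rnorm(200, 0), rnorm(200, 6))
  d <- density_dichotomize(x)
  expect_equal(d$method, "density_valley")
  expect_gt(d$threshold, 2)
  expect_lt(d$threshold, 4)
  expect_lt(abs(mean(d$stratum == "high") - 0.5), 0.10)
  # unimodal falls back to the median
  set.seed(124)
  u <- rnorm(300)
  du <- density_dichotomize(u)
  expect_equal(du$method, "median")
  expect_equal(du$threshold, stats::median(u))
  # exact translation equivariance
  ds <- density_dichotomize(x + 7.5)
  expect_equal(ds$threshold, d$threshold + 7.5, tolerance = 1e-9)
  expect_error(density_dichotomize(rep(1, 50)), "identical")
  expect_error(density_dichotomize(rnorm(5)), "at least 10")
})

test_that("Kaplan-Meier estimate is the product limit", {
  k <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(k$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  none <- km_estimate(c(2, 4, 7), c(0, 0, 0))
  expect_true(all(none$surv == 1))
  # censoring shrinks later risk sets without a step
  cns <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(cns$surv[cns$time == 1], 2 / 3, tolerance = 1e-12)
  expect_equal(cns$surv[cns$time == 3], 2 / 3 * (1 - 1 / 1), tolerance = 1e-12)
  # with no censoring KM equals the empirical survival function
  set.seed(41)
  t <- rexp(60)
  k2 <- km_estimate(t, rep(1, 60))
  for (i in seq_len(nrow(k2))) {
    expect_equal(k2$surv[i], oracle_empirical_surv(t, k2$time[i]), tolerance = 1e-12)
  }
  expect_true(all(diff(k2$surv) <= 0))
  expect_true(all(k2$surv >= 0 & k2$surv <= 1))
})

test_that("log-rank agrees with the hand O-E tabulation and is label-symmetric", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 1, 0, 1)
  grp <- c("a", "b", "a", "b", "a", "b")
  lr <- logrank_test(time, event, grp)
  ora <- oracle_logrank(time, event, grp)
  expect_equal(lr$statistic, ora$chisq, tolerance = 1e-10)
  expect_equal(lr$p_value, ora$p, tolerance = 1e-10)
  swapped <- logrank_test(time, event, ifelse(grp == "a", "b", "a"))
  expect_equal(swapped$statistic, lr$statistic, tolerance = 1e-12)
  expect_error(logrank_test(time, event, rep("a", 6)), "exactly 2 strata")
  # random cohorts: implementation vs oracle
  set.seed(17)
  for (i in 1:5) {
    t <- rexp(40); e <- rbinom(40, 1, 0.8); g <- rep(c("x", "y"), 20)
    expect_equal(logrank_test(t, e, g)$statistic, oracle_logrank(t, e, g)$chisq,
                 tolerance = 1e-8)
  }
})

test_that("Cox partial-likelihood fit matches coxph and recovers planted effects", {
  sim <- simulate_survival(n = 300, beta = 0.5, censor_rate = 0.25, seed = 61)
  fit <- cox_hr(sim$time, sim$event, sim$covariate)
  ref <- survival::coxph(survival::Surv(time, event) ~ covariate, data = sim,
                         ties = "breslow")
  expect_equal(fit$coef, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$se, unname(sqrt(vcov(ref)[1, 1])), tolerance = 1e-6)
  expect_true(fit$converged)
  # beta recovery across a grid, within 3 standard errors
  for (b in c(0, 0.35, 0.7)) {
    s <- simulate_survival(n = 500, beta = b, censor_rate = 0.2, seed = 70 + round(100 * b))
    f <- cox_hr(s$time, s$event, s$covariate)
    expect_lt(abs(f$coef - b), 3 * f$se)
  }
  # null simulation: negligible bias across replicates
  set.seed(83)
  betas <- vapply(1:30, function(i) {
    s <- simulate_survival(n = 150, beta = 0, censor_rate = 0.2, seed = 800 + i)
    cox_hr(s$time, s$event, s$covariate)$coef
  }, numeric(1))
  expect_lt(abs(mean(betas)), 3 * sd(betas) / sqrt(length(betas)))
  # time-unit rescaling leaves the hazard ratio unchanged
  f1 <- cox_hr(sim$time, sim$event, sim$covariate)
  f2 <- cox_hr(sim$time * 365, sim$event, sim$covariate)
  expect_equal(f1$hr, f2$hr, tolerance = 1e-8)
})

test_that("degenerate Cox fits are flagged, not returned silently", {
  # perfect separation: all events in the high-covariate half
  time <- c(1, 2, 3, 4, 10, 11, 12, 13)
  event <- c(1, 1, 1, 1, 0, 0, 0, 0)
  x <- c(5, 5, 5, 5, -5, -5, -5, -5)
  fit <- cox_hr(time, event, x)
  expect_false(fit$converged)
  expect_false(is.na(fit$flag))
  expect_error(cox_hr(time, event, rep(1, 8)), "constant covariate")
  expect_error(cox_hr(time, rep(0, 8), x), "no events")
})

test_that("group score comparisons share the Welch code path with the differential test", {
  set.seed(29)
  a <- rnorm(10); b <- rnorm(10) + 1.5
  cmp <- compare_scores(list(primary = a, metastasis = b))
  # bit-for-bit agreement with differential_test on the same numbers
  vals <- matrix(c(a, b), nrow = 1, dimnames = list("f", sprintf("s%02d", 1:20)))
  grp <- stats::setNames(rep(c("primary", "metastasis"), each = 10), colnames(vals))
  res <- differential_test(vals, grp, "primary", "metastasis")
  expect_identical(cmp$p_value, res$p)
  expect_identical(cmp$difference, res$log2fc)
  # identical groups and exact shifts
  same <- compare_scores(list(x = a, y = a))
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  shift <- compare_scores(list(x = a, y = a + 2))
  expect_equal(shift$difference, 2, tolerance = 1e-12)
  expect_error(compare_scores(list(x = a, y = 1)), "fewer than 2")
})

test_that("survival-based trimming ranks hazard-carrying genes to the top", {
  set.seed(55)
  n <- 300; n_genes <- 40
  vals <- matrix(rnorm(n_genes * n), nrow = n_genes,
                 dimnames = list(sprintf("g%02d", 1:n_genes), sprintf("p%03d", 1:n)))
  hazard_genes <- sprintf("g%02d", 1:5)
  lp <- colSums(vals[hazard_genes, ]) * 0.8
  time <- rexp(n) / exp(lp)
  event <- rbinom(n, 1, 0.8)
  trimmed <- trim_by_survival(vals, time, event, rownames(vals), k = 20)
  expect_length(trimmed, 20L)
  expect_true(all(hazard_genes %in% trimmed))
  expect_true(all(trimmed %in% rownames(vals)))
  # k = |genes| is the identity as a set
  all_g <- trim_by_survival(vals, time, event, rownames(vals), k = n_genes)
  expect_setequal(as.character(all_g), rownames(vals))
  expect_error(trim_by_survival(vals, time, event, rownames(vals), k = 99),
               "k must be in")
})
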