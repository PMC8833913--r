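make_matrix <- function(n_feat, n_per_group, seed = 1, shift = 0) {
  set.seed(seed)
  n <- 2 * n_per_group
  vals <- matrix(rnorm(n_feat * n), nrow = n_feat,
                 dimnames = list(sprintf("f%03d", seq_len(n_feat)),
                                 sprintf("s%02d", seq_len(n))))
  vals[, (n_per_group + 1):n] <- vals[, (n_per_group + 1):n] + shift
  grp <- stats::setNames(rep(c("A", "B"), each = n_per_group), colnames(vals))
  list(values = vals, group_of = grp)
}

test_that("log2 fold change is the exact difference of group means", {
  set.seed(2)
  a <- matrix(rnorm(20 * 4), nrow = 20)
  vals <- cbind(a, a + 2.0)  # group B is group A shifted by 2 log2 units
  dimnames(vals) <- list(sprintf("f%03d", 1:20), sprintf("s%02d", 1:8))
  grp <- stats::setNames(rep(c("A", "B"), each = 4), colnames(vals))
  res <- differential_test(vals, grp, "A", "B")
  expect_equal(res$log2fc, rep(2.0, 20), tolerance = 1e-12)
  # identical groups: fc 0, p = 1
  v <- matrix(rep(c(1, 2, 3, 4), 2), nrow = 1,
              dimnames = list("f1", sprintf("s%d", 1:8)))
  g <- stats::setNames(rep(c("A", "B"), each = 4), colnames(v))
  r0 <- differential_test(v, g, "A", "B")
  expect_equal(r0$log2fc, 0)
  expect_equal(r0$p, 1, tolerance = 1e-12)
})

test_that("BH adjustment matches the hand step-up formula", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(oracle_bh(p), rep(0.04, 4))
  set.seed(9)
  for (i in 1:5) {
    pv <- runif(50)^2
    expect_equal(stats::p.adjust(pv, "BH"), oracle_bh(pv), tolerance = 1e-12)
  }
  # permutation of feature order leaves per-feature results invariant
  m <- make_matrix(30, 4, seed = 5, shift = 0.5)
  res <- differential_test(m$values, m$group_of, "A", "B")
  perm <- sample(nrow(m$values))
  res_p <- differential_test(m$values[perm, ], m$group_of, "A", "B")
  expect_equal(res_p[match(res$feature_id, res_p$feature_id), "fdr"], res$fdr)
})

test_that("features without two usable samples per group are excluded from BH", {
  m <- make_matrix(10, 3, seed = 7)
  m$values[1, 4:6] <- NA  # group B unusable for f001
  res <- differential_test(m$values, m$group_of, "A", "B")
  expect_true(is.na(res$p[1]) && is.na(res$fdr[1]))
  expect_equal(attr(res, "n_untestable"), 1L)
  expect_equal(sum(!is.na(res$fdr)), 9L)
})

test_that("threshold calls use strict inequalities on both axes", {
  res <- data.frame(
    feature_id = c("up", "boundary_fc", "down", "boundary_fdr", "ns"),
    log2fc = c(2.1, 2.0, -1.0, 2.5, 0.1),
    fdr = c(0.005, 0.005, 0.04, 0.01, 0.5),
    stringsAsFactors = FALSE
  )
  rna <- apply_thresholds(res, threshold_spec(4, 0.01))
  expect_setequal(rna$up, "up")           # log2fc exactly log2(4) = 2 excluded
  prot <- apply_thresholds(res, threshold_spec(1.5, 0.05))
  expect_true("down" %in% prot$down)      # |-1.0| > log2(1.5)
  # idempotent and order independent
  res_shuf <- res[sample(nrow(res)), ]
  prot2 <- apply_thresholds(res_shuf, threshold_spec(1.5, 0.05))
  expect_setequal(prot2$up, prot$up)
  expect_setequal(prot2$down, prot$down)
  expect_error(threshold_spec(1, 0.05), "must be > 1")
  expect_error(threshold_spec(2, 1), "must be in")
})

test_that("four-way concordance assigns each feature to exactly one region", {
  cv <- concordance_venn4(
    rna_up = c("u1", "b1"), rna_down = c("d1", "cd1", "cd2"),
    prot_up = c("b1", "pu1"), prot_down = c("cd1", "cd2", "pd1")
  )
  expect_setequal(cv$concordant_down, c("cd1", "cd2"))
  reg <- stats::setNames(cv$assignment$region, cv$assignment$feature_id)
  expect_equal(unname(reg["pd1"]), "prot_down_only")  # protein-only-down pattern
  expect_equal(unname(reg["b1"]), "concordant_up")
  expect_equal(sum(cv$counts),
               length(unique(c("u1", "b1", "d1", "cd1", "cd2", "pu1", "pd1"))))
  expect_error(concordance_venn4("x", "x", "y", character()), "both rna_up and rna_down")
})

test_that("the Welch test is calibrated under the null and BH controls FDR when spiked", {
  cal <- calibrate_welch_type1(n_features = 1000, n_per_group = 4, seed = 21)
  expect_lt(abs(cal$rate - cal$alpha), cal$bound)
  # spiked simulation: FDP of BH discoveries stays near the nominal level
  fdps <- vapply(1:4, function(r) {
    m <- make_matrix(800, 4, seed = 100 + r)
    truth <- sample(rownames(m$values), 120)
    m$values[truth, m$group_of == "B"] <- m$values[truth, m$group_of == "B"] + 3
    res <- differential_test(m$values, m$group_of, "A", "B")
    disc <- res$feature_id[res$fdr < 0.05]
    if (length(disc)) mean(!disc %in% truth) else 0
  }, numeric(1))
  expect_lt(mean(fdps), 0.10)
})
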