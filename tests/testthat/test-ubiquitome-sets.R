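test_that("venn counts partition the union", {
  v <- venn_counts(c("p1", "p2"), c("p2", "p3"))
  expect_equal(c(v$unique_a, v$shared, v$unique_b), c(1L, 1L, 1L))
  ident <- venn_counts(c("a", "b"), c("b", "a"))
  expect_equal(c(ident$unique_a, ident$shared, ident$unique_b), c(0L, 2L, 0L))
  set.seed(3)
  a <- sample(letters, 15)
  b <- sample(letters, 12)
  v2 <- venn_counts(a, b)
  expect_equal(v2$unique_a + v2$shared + v2$unique_b, length(union(a, b)))
})

test_that("generator can target the published peptide totals", {
  ks <- simulate_key_sets(n_a = 3840, n_b = 7042, n_shared = 3169, seed = 5)
  v <- venn_counts(ks$set_a, ks$set_b)
  expect_equal(v$unique_a, 671L)
  expect_equal(v$shared, 3169L)
  expect_equal(v$unique_b, 3873L)
  expect_true(all(grepl("@", ks$set_a)))
})

test_that("condition-unique calling is strict absence within the MG132 stratum", {
  ev <- data.frame(
    sample = c("c1", "c1", "v1", "v1", "v2", "v0"),
    condition = c("Ctrl", "Ctrl", "VHL", "VHL", "VHL", "VHL"),
    mg132 = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    key = c("k2", "k9", "k1", "k2", "k1", "k7"),
    stringsAsFactors = FALSE
  )
  expect_setequal(unique_to_condition(ev, "VHL", "Ctrl"), "k1")
  expect_setequal(unique_to_condition(ev, "VHL", "Ctrl", require_mg132 = FALSE), "k7")
  expect_length(unique_to_condition(ev, "Ctrl", "Ctrl"), 0L)
  expect_error(unique_to_condition(ev, "VHL", "Mock"), "unknown condition")
  # enlarging the reference never grows the unique set
  ev2 <- rbind(ev, data.frame(sample = "c2", condition = "Ctrl", mg132 = TRUE,
                              key = "k1", stringsAsFactors = FALSE))
  expect_true(all(unique_to_condition(ev2, "VHL", "Ctrl") %in%
                    unique_to_condition(ev, "VHL", "Ctrl")))
})

test_that("protein collapse counts each protein once and keeps ambiguous matches", {
  ann <- data.frame(
    key = c("pepA@3", "pepB@5", "pepC@2", "pepC@2"),
    protein_id = c("P1", "P1", "X", "Y"),
    stringsAsFactors = FALSE
  )
  expect_setequal(collapse_to_proteins(c("pepA@3", "pepB@5"), ann), "P1")
  both <- collapse_to_proteins("pepC@2", ann)
  expect_setequal(as.character(both), c("X", "Y"))
  un <- collapse_to_proteins(c("pepA@3", "missing@1"), ann)
  expect_equal(attr(un, "unmapped"), "missing@1")
})

test_that("collapse of digest-derived keys recovers the source protein set", {
  prots <- tiny_proteome(n = 5, seed = 12)
  # restrict to proteins with at least one non-terminal K to plant a site on
  has_k <- vapply(prots, function(s) {
    ks <- which(strsplit(s, "")[[1]] == "K")
    any(ks < nchar(s))
  }, logical(1))
  prots <- prots[has_k]
  keys <- character()
  for (id in names(prots)) {
    ks <- which(strsplit(prots[[id]], "")[[1]] == "K")
    ks <- ks[ks < nchar(prots[[id]])]
    pos <- ks[1]
    d <- tryptic_digest(prots[[id]], 0, blocked_positions = pos)
    row <- d[d$start <= pos & pos <= d$start + nchar(d$peptide) - 1L, ]
    keys <- c(keys, peptidoform_key(peptidoform(row$peptide, pos - row$start + 1L)))
  }
  ann <- map_keys_to_proteins(keys, prots)
  expect_setequal(as.character(collapse_to_proteins(keys, ann)), names(prots))
})

test_that("hypergeometric overlap matches exhaustive enumeration and tail summation", {
  r <- interactor_overlap(paste0("c", 1:4), paste0("c", 1:5), universe_size = 10)
  expect_equal(r$n_overlap, 4L)
  expect_equal(r$p_value, 5 / 210, tolerance = 1e-12)
  expect_equal(r$p_value, oracle_hyper_enum(4, 5, 4, 10), tolerance = 1e-12)
  # zero overlap at minimum possible overlap has p = 1
  r0 <- interactor_overlap(c("a1", "a2"), c("b1", "b2"), universe_size = 50)
  expect_equal(r0$p_value, 1)
  # published configuration vs independent tail sum
  p_pkg <- hypergeom_upper(63, 219, 2026, 20000)
  p_ora <- oracle_hyper_tail(63, 219, 2026, 20000)
  expect_lt(abs(p_pkg - p_ora) / p_ora, 1e-10)
  # p is non-increasing in k
  ps <- vapply(0:10, hypergeom_upper, numeric(1), K = 20, n = 30, N = 100)
  expect_true(all(diff(ps) <= 0))
  expect_error(interactor_overlap(letters[1:10], letters[5:15], universe_size = 12),
               "smaller than")
})
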