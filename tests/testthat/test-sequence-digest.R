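test_that("modified-peptide dialects parse and normalize identically", {
  cases <- list(
    list(text = "LAPVYQK[gg]LLER", bare = "LAPVYQKLLER", mods = 7L),
    list(text = "GHTPLDLTCSTK^ub^VK", bare = "GHTPLDLTCSTKVK", mods = 12L),
    list(text = "PEPTIDEK", bare = "PEPTIDEK", mods = integer())
  )
  for (cs in cases) {
    pf <- parse_peptidoform(cs$text)
    expect_equal(pf$bare_sequence, cs$bare)
    expect_equal(pf$mod_positions, cs$mods)
  }
  # same peptidoform in all three dialects
  variants <- c("LAPVYQK[gg]LLER", "LAPVYQK(gl)LLER", "LAPVYQK^ub^LLER")
  keys <- vapply(variants, function(v) peptidoform_key(parse_peptidoform(v)),
                 character(1))
  expect_length(unique(keys), 1L)
  # separate-columns form agrees with the inline dialects
  expect_equal(peptidoform_key(peptidoform("LAPVYQKLLER", 7L)), unname(keys[1]))
})

test_that("parser rejects malformed and mislocated modifications", {
  expect_error(parse_peptidoform("PEPK[ggLLER"), "unbalanced")
  expect_error(parse_peptidoform("PEPK[ox]LLER"), "unknown modification tag")
  expect_error(parse_peptidoform("PEPA[gg]LLER"), "position 4")
  expect_error(parse_peptidoform("[gg]PEPK"), "before any residue")
  expect_error(peptidoform("PEPTIDE", 3L), "non-K residue")
  expect_error(peptidoform("PEP", 9L), "outside peptide")
})

test_that("render/parse round-trips across dialects on random peptidoforms", {
  set.seed(11)
  aa <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], character(0))
  for (i in 1:25) {
    len <- sample(7:25, 1)
    sq <- sample(aa, len, replace = TRUE)
    kpos <- which(sq == "K")
    n_mod <- sample(0:min(2, length(kpos)), 1)
    mods <- sort(kpos[sample.int(length(kpos), n_mod)])
    pf <- peptidoform(paste(sq, collapse = ""), mods)
    for (d in c("gg", "gl", "ub")) {
      back <- parse_peptidoform(render_peptidoform(pf, d))
      expect_equal(back$bare_sequence, pf$bare_sequence)
      expect_equal(back$mod_positions, pf$mod_positions)
    }
  }
})

test_that("tryptic digestion follows the cleave-after-K/R-not-before-P rule", {
  d <- tryptic_digest("AKRPKG", max_missed = 0)
  expect_equal(d$peptide, c("AK", "RPK", "G"))
  expect_equal(d$start, c(1L, 3L, 6L))
  expect_equal(d$missed, c(0L, 0L, 0L))
  # a diGly-blocked K is not cleaved and counts as internal
  b <- tryptic_digest("AKRG", max_missed = 0, blocked_positions = 2L)
  expect_equal(b$peptide, c("AKR", "G"))
  expect_equal(b$start, c(1L, 4L))
  expect_error(tryptic_digest("", 0), "empty")
  expect_error(tryptic_digest("AKRG", 0, blocked_positions = 3L), "must be K")
})

test_that("zero-missed peptides tile the protein; missed peptides concatenate adjacent ones", {
  prots <- tiny_proteome()
  for (p in prots) {
    d0 <- tryptic_digest(p, max_missed = 0)
    expect_equal(paste(d0$peptide, collapse = ""), p)
    expect_equal(d0$start, cumsum(c(1L, utils::head(nchar(d0$peptide), -1))))
    d1 <- tryptic_digest(p, max_missed = 1)
    m1 <- d1[d1$missed == 1L, ]
    for (i in seq_len(nrow(m1))) {
      j <- match(m1$start[i], d0$start)
      expect_equal(m1$peptide[i], paste0(d0$peptide[j], d0$peptide[j + 1]))
    }
  }
})

test_that("published ubiquitinated peptides map to their published sites", {
  fx <- load_site_fixture_proteome()
  ann <- map_peptide_to_protein("LAPVYQK[gg]LLER", fx)
  expect_equal(ann$protein_id, "TGFBI")
  expect_equal(ann$site_pos, 676L)
  expect_false(ann$ambiguous)
  expect_equal(map_peptide_to_protein("YGCEGPSHGGLPGASSEK[gg]GR", fx)$site_pos, 72L)
  expect_equal(map_peptide_to_protein("GHTPLDLTCSTK^ub^VK", fx)$site_pos, 741L)
})

test_that("mapping reports substring offsets, ambiguity, and empty results", {
  ann <- map_peptide_to_protein(peptidoform("GCKD", 3L), c(P1 = "AGCKDE"))
  expect_equal(ann$peptide_start, 2L)
  expect_equal(ann$site_pos, 4L)
  expect_false(ann$ambiguous)
  # two loci -> two annotations, both flagged ambiguous
  amb <- map_peptide_to_protein(peptidoform("ACKD", 3L),
                                c(P1 = "ACKDWACKDY", P2 = "MMMM"))
  expect_equal(nrow(amb), 2L)
  expect_true(all(amb$ambiguous))
  expect_equal(amb$site_pos, c(3L, 8L))
  # unmatched is an empty result, not an error
  none <- map_peptide_to_protein(peptidoform("WWWWK", 5L), c(P1 = "ACKDE"))
  expect_equal(nrow(none), 0L)
})

test_that("digest-attach-map round trip recovers every eligible K position", {
  prots <- tiny_proteome(n = 4, seed = 99)
  for (id in names(prots)) {
    sq <- prots[[id]]
    ks <- which(strsplit(sq, "")[[1]] == "K")
    ks <- ks[ks < nchar(sq)]
    for (pos in ks) {
      d <- tryptic_digest(sq, max_missed = 0, blocked_positions = pos)
      row <- d[d$start <= pos & pos <= d$start + nchar(d$peptide) - 1L, ]
      pf <- peptidoform(row$peptide, pos - row$start + 1L)
      ann <- map_peptide_to_protein(pf, prots)
      hit <- ann[ann$protein_id == id & ann$peptide_start == row$start, ]
      expect_equal(hit$site_pos, pos)
    }
  }
})

test_that("peptide length summary counts bare-sequence lengths", {
  s <- peptide_length_summary(c("AAAAAAA", "AAAAAAAA"))
  expect_equal(s$counts, c("7" = 1L, "8" = 1L))
  expect_equal(s$min, 7L)
  expect_equal(s$max, 8L)
  expect_true(is.na(peptide_length_summary(character())$min))
  # the three published peptides: lengths 11, 20, 14
  pfs <- lapply(c("LAPVYQK[gg]LLER", "YGCEGPSHGGLPGASSEK[gg]GR",
                  "GHTPLDLTCSTK^ub^VK"), parse_peptidoform)
  s3 <- peptide_length_summary(pfs)
  expect_equal(s3$min, 11L)
  expect_equal(s3$max, 20L)
  expect_equal(sum(s3$counts), 3L)
})
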