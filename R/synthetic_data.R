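# Derived per-stream seeds: one global seed, one fixed offset per output
# stream, so adding a new stream never perturbs existing draws.
.derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + 131 * sum(utf8ToInt(stream))) %% 2147483646) + 1L
}

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Study configuration for the synthetic generator
#'
#' Defaults encode the emulated study conditions: a two-condition cell-line
#' contrast (control vs VHL-restored) with 4 replicates per condition, 30
#' true substrates downregulated by 1.5 log2 units at the protein level only,
#' 40 transcription-factor-driven genes downregulated at both the RNA and
#' protein level, MG132 boosting ubiquitinated-peptide detection 10-fold, a
#' 200-patient tumor/normal cohort overexpressing substrates by 1.5 log2
#' units, and survival hazard rising with the substrate signature score
#' (log-HR 0.7 per unit, 20% censoring).
#'
#' @param n_proteins Proteome size.
#' @param n_true_substrates Number of ground-truth substrates.
#' @param n_hif_targets Number of transcriptionally driven genes
#'   (concordant RNA+protein downregulation; the substrates themselves are
#'   RNA-silent, the post-translational pattern).
#' @param protein_effect Log2 downregulation of substrates in the restored
#'   condition's proteome.
#' @param rna_effect Log2 downregulation of the transcriptionally driven
#'   genes (applied at both RNA and protein level).
#' @param reps_per_condition Replicate samples per condition per omics layer.
#' @param noise_sd Replicate noise SD (log2) for the cell-line matrices.
#' @param ub_background_rate Fraction of eligible lysine sites carrying
#'   background (condition-independent) ubiquitination.
#' @param mg132_boost Detection multiplier under proteasome inhibition;
#'   untreated files carry ~1/boost as many events.
#' @param n_patients Cohort size (each patient contributes a tumor and a
#'   matched normal sample).
#' @param tumor_effect Log2 tumor-vs-normal overexpression of substrates.
#' @param tumor_hetero SD of the per-patient substrate-program activity
#'   (log2), shared across all substrate genes of a tumor; this is what makes
#'   the signature score vary between patients and couples it to hazard.
#' @param clinical_noise_sd Per-sample noise SD (log2) in the cohort matrix.
#' @param survival_beta Log hazard ratio per unit signature score.
#' @param censor_rate Fraction of patients censored.
#' @param interactor_frac Fraction of substrates included in the interactor
#'   list.
#' @param n_interactors Total interactor-list size (substrate members plus
#'   decoys).
#' @param seed Global seed; every stream derives from it.
#' @return List of class `"study_config"`.
#' @export
study_config <- function(n_proteins = 400L,
                         n_true_substrates = 30L,
                         n_hif_targets = 40L,
                         protein_effect = 1.5,
                         rna_effect = 2.5,
                         reps_per_condition = 4L,
                         noise_sd = 0.25,
                         ub_background_rate = 0.10,
                         mg132_boost = 10,
                         n_patients = 200L,
                         tumor_effect = 1.5,
                         tumor_hetero = 0.5,
                         clinical_noise_sd = 0.5,
                         survival_beta = 0.7,
                         censor_rate = 0.2,
                         interactor_frac = 0.5,
                         n_interactors = 60L,
                         seed = 1L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    n_true_substrates = as.integer(n_true_substrates),
    n_hif_targets = as.integer(n_hif_targets),
    protein_effect = protein_effect, rna_effect = rna_effect,
    reps_per_condition = as.integer(reps_per_condition),
    noise_sd = noise_sd, ub_background_rate = ub_background_rate,
    mg132_boost = mg132_boost, n_patients = as.integer(n_patients),
    tumor_effect = tumor_effect, tumor_hetero = tumor_hetero,
    clinical_noise_sd = clinical_noise_sd,
    survival_beta = survival_beta, censor_rate = censor_rate,
    interactor_frac = interactor_frac, n_interactors = as.integer(n_interactors),
    seed = as.integer(seed)
  )
  rates <- c("ub_background_rate", "censor_rate", "interactor_frac")
  for (r in rates) {
    if (!is.finite(cfg[[r]]) || cfg[[r]] < 0 || cfg[[r]] > 1) {
      stop("study_config: ", r, " must be in [0, 1]")
    }
  }
  effects <- c("protein_effect", "rna_effect", "tumor_effect", "tumor_hetero",
               "survival_beta", "noise_sd", "clinical_noise_sd", "mg132_boost")
  for (e in effects) {
    if (!is.finite(cfg[[e]])) stop("study_config: ", e, " must be finite")
  }
  counts <- c("n_proteins", "n_true_substrates", "n_hif_targets",
              "reps_per_condition", "n_patients", "n_interactors")
  for (ct in counts) {
    if (is.na(cfg[[ct]]) || cfg[[ct]] < 0) stop("study_config: ", ct, " must be >= 0")
  }
  if (cfg$n_proteins < 1L) stop("study_config: n_proteins must be >= 1")
  if (cfg$reps_per_condition < 2L) stop("study_config: need >= 2 replicates per condition")
  if (cfg$n_true_substrates + cfg$n_hif_targets > cfg$n_proteins) {
    stop("study_config: substrates plus driven genes exceed the proteome size")
  }
  if (cfg$mg132_boost < 1) stop("study_config: mg132_boost must be >= 1")
  structure(cfg, class = "study_config")
}

#' Generate a random tryptic-structured proteome
#'
#' Sequences are built fragment-wise: each fragment has a non-K/R interior
#' (first residue never proline, so the preceding cleavage is not
#' suppressed) and a terminal K or R. Fragment lengths are uniform on
#' `frag_len_range`, so zero-missed tryptic peptides sit mostly in the 7-31
#' residue band once one missed cleavage is allowed.
#'
#' @param n Number of proteins.
#' @param seed Seed.
#' @param frag_len_range Min/max fragment length (default 6-14).
#' @param n_frag_range Min/max fragments per protein (default 25-45).
#' @return Named character vector, IDs `PROT0001`... -> sequence.
#' @export
generate_proteome <- function(n, seed, frag_len_range = c(6L, 14L),
                              n_frag_range = c(25L, 45L)) {
  stopifnot(n >= 1L)
  set.seed(seed)
  interior <- setdiff(.AA20, c("K", "R"))
  no_p <- setdiff(interior, "P")
  seqs <- vapply(seq_len(n), function(i) {
    nf <- sample(n_frag_range[1]:n_frag_range[2], 1L)
    frags <- vapply(seq_len(nf), function(j) {
      len <- sample(frag_len_range[1]:frag_len_range[2], 1L)
      body <- c(sample(no_p, 1L), sample(interior, len - 2L, replace = TRUE))
      paste0(paste(body, collapse = ""), sample(c("K", "R"), 1L))
    }, character(1))
    paste(frags, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("PROT%04d", seq_len(n))
  validate_proteome(seqs)
  seqs
}

# The fully tryptic peptide covering a blocked (diGly-modified) K: digest
# with the site blocked and take the peptide containing it.
.peptide_for_site <- function(sequence, pos) {
  dg <- tryptic_digest(sequence, max_missed = 0L, blocked_positions = pos)
  hit <- dg[dg$start <= pos & pos <= dg$start + nchar(dg$peptide) - 1L, , drop = FALSE]
  stopifnot(nrow(hit) == 1L)
  peptidoform(hit$peptide[1], pos - hit$start[1] + 1L)
}

# K positions eligible as ubiquitination sites: fragment-terminal lysines
# that are not the protein C-terminus (a modified terminal K would merge
# nothing and leave the remnant on a peptide C-terminus).
.eligible_k_sites <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  k <- which(chars == "K")
  k[k < length(chars)]
}

#' Generate a complete synthetic study
#'
#' Produces every input the pipeline consumes, plus ground-truth bookkeeping:
#' a proteome FASTA, peptidoform observations per condition and MG132
#' stratum, cell-line proteome and RNA matrices, a paired tumor/normal
#' clinical matrix with survival, and an interactor list. Substrates carry
#' planted ubiquitination sites observed essentially only in the restored
#' condition (MG132-treated stratum); without MG132 the background events are
#' thinned by `1/mg132_boost` and planted events are lost to degradation.
#'
#' @param config A [study_config()].
#' @return List of class `"study_bundle"`: `proteome`, `ub_events`
#'   (data.frame `sample`, `condition`, `mg132`, `key`), `proteome_matrix`
#'   and `rna_matrix` (each `values` + `group_of`), `clinical` (`values` +
#'   `group_of`), `survival` (data.frame `sample_id`, `time`, `event`),
#'   `interactors`, `truth` (substrates, planted sites with peptidoform keys,
#'   driven genes), `config`.
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  proteome <- generate_proteome(cfg$n_proteins, .derive_seed(cfg$seed, "proteome"))
  ids <- names(proteome)

  set.seed(.derive_seed(cfg$seed, "roles"))
  substrates <- sort(sample(ids, cfg$n_true_substrates))
  hif_targets <- sort(sample(setdiff(ids, substrates), cfg$n_hif_targets))

  # planted substrate sites (1-2 per substrate) and their peptidoforms
  set.seed(.derive_seed(cfg$seed, "sites"))
  site_rows <- lapply(substrates, function(p) {
    elig <- .eligible_k_sites(proteome[[p]])
    stopifnot(length(elig) >= 1L)
    pos <- sort(sample(elig, min(length(elig), sample(1:2, 1L))))
    data.frame(protein_id = p, site_pos = pos,
               key = vapply(pos, function(s) {
                 peptidoform_key(.peptide_for_site(proteome[[p]], s))
               }, character(1)),
               stringsAsFactors = FALSE)
  })
  planted <- do.call(rbind, site_rows)

  # background ubiquitination pool over eligible sites of all proteins
  set.seed(.derive_seed(cfg$seed, "ub"))
  all_sites <- do.call(rbind, lapply(ids, function(p) {
    data.frame(protein_id = p, site_pos = .eligible_k_sites(proteome[[p]]),
               stringsAsFactors = FALSE)
  }))
  planted_id <- paste(planted$protein_id, planted$site_pos)
  pool <- all_sites[!paste(all_sites$protein_id, all_sites$site_pos) %in% planted_id, ]
  n_bg <- round(cfg$ub_background_rate * nrow(pool))
  bg <- pool[sample(nrow(pool), n_bg), , drop = FALSE]
  bg_keys <- vapply(seq_len(nrow(bg)), function(i) {
    peptidoform_key(.peptide_for_site(proteome[[bg$protein_id[i]]], bg$site_pos[i]))
  }, character(1))
  bg_keys <- unique(bg_keys)
  grp <- sample(c("shared", "ctrl", "vhl"), length(bg_keys), replace = TRUE,
                prob = c(0.70, 0.15, 0.15))
  keys_by_cond <- list(
    Ctrl = c(bg_keys[grp != "vhl"]),
    VHL  = c(bg_keys[grp != "ctrl"], planted$key)
  )

  # observation table: each condition-level event seen in >=1 replicate
  rep_names <- function(cond, mg) {
    sprintf("%s_%s_r%d", cond, if (mg) "MG" else "noMG", seq_len(cfg$reps_per_condition))
  }
  obs_rows <- list()
  for (cond in c("Ctrl", "VHL")) {
    keys <- unique(keys_by_cond[[cond]])
    smp <- rep_names(cond, TRUE)
    seen <- matrix(stats::runif(length(keys) * length(smp)) < 0.7,
                   nrow = length(keys))
    none <- which(rowSums(seen) == 0L)
    if (length(none)) seen[cbind(none, sample(length(smp), length(none), replace = TRUE))] <- TRUE
    idx <- which(seen, arr.ind = TRUE)
    obs_rows[[paste0(cond, "_MG")]] <- data.frame(
      sample = smp[idx[, 2]], condition = cond, mg132 = TRUE,
      key = keys[idx[, 1]], stringsAsFactors = FALSE
    )
    # untreated stratum: background only, thinned 1/mg132_boost
    bg_only <- setdiff(keys, planted$key)
    n_keep <- max(1L, round(length(bg_only) / cfg$mg132_boost))
    keep <- sample(bg_only, min(n_keep, length(bg_only)))
    smp0 <- rep_names(cond, FALSE)
    obs_rows[[paste0(cond, "_noMG")]] <- data.frame(
      sample = sample(smp0, length(keep), replace = TRUE), condition = cond,
      mg132 = FALSE, key = keep, stringsAsFactors = FALSE
    )
  }
  ub_events <- do.call(rbind, obs_rows)
  rownames(ub_events) <- NULL

  # cell-line omics: log2 matrices with Gaussian replicate noise
  mk_cell_matrix <- function(stream, effect_of) {
    set.seed(.derive_seed(cfg$seed, stream))
    smp <- c(sprintf("Ctrl_r%d", seq_len(cfg$reps_per_condition)),
             sprintf("VHL_r%d", seq_len(cfg$reps_per_condition)))
    grp_of <- stats::setNames(rep(c("Ctrl", "VHL"), each = cfg$reps_per_condition), smp)
    base <- stats::runif(cfg$n_proteins, 5, 10)
    vals <- matrix(stats::rnorm(cfg$n_proteins * length(smp), sd = cfg$noise_sd),
                   nrow = cfg$n_proteins, dimnames = list(ids, smp))
    vals <- vals + base
    eff <- effect_of(ids)
    vals[, grp_of == "VHL"] <- vals[, grp_of == "VHL"] + eff
    list(values = pmax(vals, 0), group_of = grp_of)
  }
  proteome_matrix <- mk_cell_matrix("prot_matrix", function(f) {
    ifelse(f %in% substrates, -cfg$protein_effect,
           ifelse(f %in% hif_targets, -cfg$rna_effect, 0))
  })
  rna_matrix <- mk_cell_matrix("rna_matrix", function(f) {
    ifelse(f %in% hif_targets, -cfg$rna_effect, 0)
  })

  # clinical cohort: paired tumor/normal, substrates overexpressed in tumors
  set.seed(.derive_seed(cfg$seed, "clinical"))
  t_smp <- sprintf("T%03d", seq_len(cfg$n_patients))
  n_smp <- sprintf("N%03d", seq_len(cfg$n_patients))
  smp <- c(t_smp, n_smp)
  grp_of <- stats::setNames(rep(c("tumor", "normal"), each = cfg$n_patients), smp)
  base <- stats::runif(cfg$n_proteins, 5, 10)
  cvals <- matrix(stats::rnorm(cfg$n_proteins * length(smp), sd = cfg$clinical_noise_sd),
                  nrow = cfg$n_proteins, dimnames = list(ids, smp))
  cvals <- cvals + base
  cvals[ids %in% substrates, grp_of == "tumor"] <-
    cvals[ids %in% substrates, grp_of == "tumor"] + cfg$tumor_effect
  # per-patient substrate-program activity, shared across substrate genes:
  # the source of between-patient signature-score variation
  activity <- stats::rnorm(cfg$n_patients, sd = cfg$tumor_hetero)
  cvals[ids %in% substrates, t_smp] <-
    sweep(cvals[ids %in% substrates, t_smp, drop = FALSE], 2L, activity, `+`)
  cvals <- pmax(cvals, 0)

  # survival: exponential times with hazard tied to the substrate signature
  score <- signature_score(cvals[, t_smp, drop = FALSE], substrates)
  surv <- simulate_survival(
    n = cfg$n_patients, beta = cfg$survival_beta,
    covariate = score - mean(score), censor_rate = cfg$censor_rate,
    seed = .derive_seed(cfg$seed, "survival")
  )
  surv$sample_id <- t_smp

  # interactor list: a fraction of substrates plus decoys
  set.seed(.derive_seed(cfg$seed, "interactors"))
  n_sub_in <- min(cfg$n_true_substrates, ceiling(cfg$interactor_frac * cfg$n_true_substrates))
  n_decoy <- min(max(0L, cfg$n_interactors - n_sub_in),
                 cfg$n_proteins - cfg$n_true_substrates)
  interactors <- sort(c(sample(substrates, n_sub_in),
                        sample(setdiff(ids, substrates), n_decoy)))

  structure(
    list(
      proteome = proteome, ub_events = ub_events,
      proteome_matrix = proteome_matrix, rna_matrix = rna_matrix,
      clinical = list(values = cvals, group_of = grp_of),
      survival = surv[, c("sample_id", "time", "event")],
      interactors = interactors,
      truth = list(substrates = substrates, sites = planted,
                   hif_targets = hif_targets),
      config = cfg
    ),
    class = "study_bundle"
  )
}

#' Simulate survival with an exponential baseline
#'
#' Event times are exponential with per-sample hazard
#' `exp(beta * covariate)`; an exact fraction `censor_rate` of samples is
#' censored uniformly before its event time.
#'
#' @param n Cohort size.
#' @param beta True log hazard ratio per unit covariate.
#' @param covariate Per-sample covariate (default standard normal draws).
#' @param censor_rate Fraction censored.
#' @param seed Seed.
#' @return `data.frame` with `sample_id`, `time`, `event`, `covariate`.
#' @export
simulate_survival <- function(n, beta, covariate = NULL, censor_rate = 0.2, seed = 1L) {
  set.seed(seed)
  if (is.null(covariate)) covariate <- stats::rnorm(n)
  stopifnot(length(covariate) == n, censor_rate >= 0, censor_rate < 1)
  time <- stats::rexp(n) / exp(beta * covariate)
  event <- rep(1L, n)
  n_cens <- floor(censor_rate * n)
  if (n_cens > 0L) {
    idx <- sample(n, n_cens)
    time[idx] <- stats::runif(n_cens) * time[idx]
    event[idx] <- 0L
  }
  data.frame(sample_id = sprintf("S%04d", seq_len(n)), time = time,
             event = event, covariate = covariate, stringsAsFactors = FALSE)
}

#' Simulate two peptidoform key sets with targeted Venn totals
#'
#' Generates `n_a + n_b - n_shared` distinct tryptic-like peptidoform keys
#' (random sequence with one internal modified K, terminal K/R) and assigns
#' them so that set A has `n_a` members, set B has `n_b`, and exactly
#' `n_shared` are common.
#'
#' @param n_a,n_b,n_shared Target totals; `n_shared` must not exceed either.
#' @param seed Seed.
#' @return List with character vectors `set_a`, `set_b`.
#' @export
simulate_key_sets <- function(n_a, n_b, n_shared, seed = 1L) {
  stopifnot(n_shared <= n_a, n_shared <= n_b)
  set.seed(seed)
  n_total <- n_a + n_b - n_shared
  interior <- setdiff(.AA20, c("K", "R"))
  keys <- character(0)
  while (length(keys) < n_total) {
    need <- n_total - length(keys)
    fresh <- vapply(seq_len(need), function(i) {
      len <- sample(7:25, 1L)
      body <- sample(interior, len - 2L, replace = TRUE)
      kpos <- sample(2:(len - 1L), 1L)
      sq <- c(body[seq_len(kpos - 1L)], "K", body[seq(kpos, len - 2L)],
              sample(c("K", "R"), 1L))
      peptidoform_key(peptidoform(paste(sq, collapse = ""), kpos))
    }, character(1))
    keys <- unique(c(keys, fresh))
  }
  shared <- keys[seq_len(n_shared)]
  a_only <- keys[n_shared + seq_len(n_a - n_shared)]
  b_only <- keys[n_a + seq_len(n_b - n_shared)]
  list(set_a = c(shared, a_only), set_b = c(shared, b_only))
}

#' Write a study bundle to disk
#'
#' Emits exactly the formats the pipeline reads: proteome FASTA, peptidoform
#' TSV, matrix + group TSVs per omics layer, survival TSV, interactor list
#' and ground truth JSON. Writes are deterministic (byte-identical for a
#' fixed bundle).
#'
#' @param bundle A [generate_study()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_proteome(bundle$proteome, p("proteome.fasta"))
  ev <- bundle$ub_events
  ev$peptidoform <- vapply(ev$key, function(k) {
    render_peptidoform(peptidoform_from_key(k), "gg")
  }, character(1), USE.NAMES = FALSE)
  ev$mg132 <- as.integer(ev$mg132)
  utils::write.table(ev[, c("sample", "condition", "mg132", "peptidoform")],
                     p("ub_events.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  wm <- function(m, stem) {
    tab <- data.frame(feature_id = rownames(m$values), m$values,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, p(paste0(stem, "_matrix.tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample = names(m$group_of), group = unname(m$group_of)),
      p(paste0(stem, "_groups.tsv")), sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  wm(bundle$proteome_matrix, "proteome")
  wm(bundle$rna_matrix, "rna")
  wm(bundle$clinical, "clinical")
  utils::write.table(bundle$survival, p("survival.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(bundle$interactors, p("interactors.txt"))
  jsonlite::write_json(
    list(substrates = bundle$truth$substrates,
         sites = bundle$truth$sites,
         hif_targets = bundle$truth$hif_targets,
         config = unclass(bundle$config)),
    p("ground_truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
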