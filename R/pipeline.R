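#' Run the substrate-nomination pipeline end-to-end
#'
#' Executes the full funnel on a study bundle: condition-unique
#' ubiquitination calling (MG132-treated stratum, untreated reported as QC),
#' peptide-to-protein site mapping, interactor-overlap enrichment, two-group
#' differential statistics on the proteome/RNA/clinical matrices with the
#' standard threshold filters, the triple-intersection nomination, and
#' signature scoring with density-peak survival stratification over the
#' nominated set. When the bundle carries ground truth, nomination
#' sensitivity and false-discovery proportion are evaluated against it.
#'
#' @param bundle A [generate_study()] bundle (or a structurally identical
#'   list built from files).
#' @param target,reference Condition labels of the restored and control
#'   condition (defaults `"VHL"`, `"Ctrl"`).
#' @param rna_spec RNA differential filter (default fold 4, FDR 0.01).
#' @param prot_spec Proteome differential filter (default fold 1.5, FDR 0.05).
#' @param clinical_min_log2fc,clinical_max_adj_p Cohort tumor-up filter
#'   (defaults log2fc > 1, BH-adjusted p < 0.05, strict).
#' @param trim_k Signature size for survival-based trimming (default 20).
#' @param universe_size Hypergeometric universe for the interactor overlap;
#'   defaults to the number of proteins in the bundle's proteome.
#' @param out_dir Optional directory: stage TSV/JSON outputs plus the
#'   manifest are written there.
#' @return Manifest list: stage `counts` (the funnel), `venn`, `overlap`,
#'   `candidates`, `down_and_ub`, `signature` (threshold, strata, log-rank,
#'   Cox, trimmed signature), `evaluation` (when truth is present),
#'   `parameters`, `seed`.
#' @export
run_pipeline <- function(bundle,
                         target = "VHL", reference = "Ctrl",
                         rna_spec = threshold_spec(4, 0.01),
                         prot_spec = threshold_spec(1.5, 0.05),
                         clinical_min_log2fc = 1, clinical_max_adj_p = 0.05,
                         trim_k = 20L,
                         universe_size = NULL,
                         out_dir = NULL) {
  stopifnot(is.list(bundle), !is.null(bundle$proteome), !is.null(bundle$ub_events))
  if (is.null(universe_size)) universe_size <- length(bundle$proteome)

  # ubiquitome: condition totals, unique set, proteins
  ev <- bundle$ub_events
  keys_ref <- unique(ev$key[ev$condition == reference & ev$mg132])
  keys_tgt <- unique(ev$key[ev$condition == target & ev$mg132])
  vn <- venn_counts(keys_ref, keys_tgt)
  uniq_keys <- unique_to_condition(ev, target, reference, require_mg132 = TRUE)
  uniq_keys_untreated <- if (any(!ev$mg132)) {
    unique_to_condition(ev, target, reference, require_mg132 = FALSE)
  } else character()
  site_map <- map_keys_to_proteins(uniq_keys, bundle$proteome)
  ub_proteins <- collapse_to_proteins(uniq_keys, site_map)
  overlap <- if (length(bundle$interactors)) {
    interactor_overlap(ub_proteins, bundle$interactors, universe_size)
  } else NULL

  # differential layers
  prot_res <- differential_test(bundle$proteome_matrix$values,
                                bundle$proteome_matrix$group_of,
                                reference, target)
  prot_calls <- apply_thresholds(prot_res, prot_spec)
  rna_calls <- NULL
  venn4 <- NULL
  if (!is.null(bundle$rna_matrix)) {
    rna_res <- differential_test(bundle$rna_matrix$values,
                                 bundle$rna_matrix$group_of,
                                 reference, target)
    rna_calls <- apply_thresholds(rna_res, rna_spec)
    venn4 <- concordance_venn4(rna_calls$up, rna_calls$down,
                               prot_calls$up, prot_calls$down)
  }

  # clinical tumor-up list
  clin_res <- differential_test(bundle$clinical$values, bundle$clinical$group_of,
                                "normal", "tumor")
  keep <- !is.na(clin_res$log2fc) & !is.na(clin_res$fdr) &
    clin_res$log2fc > clinical_min_log2fc & clin_res$fdr < clinical_max_adj_p
  clinical_up <- data.frame(protein_id = clin_res$feature_id[keep],
                            clinical_log2fc = clin_res$log2fc[keep],
                            clinical_adj_p = clin_res$fdr[keep],
                            stringsAsFactors = FALSE)

  nom <- nominate(ub_proteins, prot_calls$down, clinical_up,
                  cell_stats = prot_res, site_map = site_map)
  candidates <- nom$candidates

  # signature scoring and survival over the nominated set
  signature <- NULL
  if (nrow(candidates) >= 1L && !is.null(bundle$survival) && nrow(bundle$survival)) {
    tumor_cols <- names(bundle$clinical$group_of)[bundle$clinical$group_of == "tumor"]
    score <- signature_score(bundle$clinical$values[, tumor_cols, drop = FALSE],
                             candidates$protein_id)
    surv <- bundle$survival[match(tumor_cols, bundle$survival$sample_id), , drop = FALSE]
    ok <- !is.na(surv$time)
    score <- score[ok]; surv <- surv[ok, , drop = FALSE]
    signature <- list(n_samples = nrow(surv))
    if (nrow(surv) >= 10L && max(score) > min(score)) {
      dich <- density_dichotomize(score)
      lr <- logrank_test(surv$time, surv$event, dich$stratum)
      cox_score <- cox_hr(surv$time, surv$event, score)
      cox_strat <- cox_hr(surv$time, surv$event, as.integer(dich$stratum == "high"))
      k_use <- min(as.integer(trim_k), nrow(candidates))
      trimmed <- trim_by_survival(bundle$clinical$values[, tumor_cols[ok], drop = FALSE],
                                  surv$time, surv$event, candidates$protein_id,
                                  k = k_use)
      signature <- list(
        n_samples = nrow(surv),
        threshold = dich$threshold, dichotomize_method = dich$method,
        n_high = sum(dich$stratum == "high"), n_low = sum(dich$stratum == "low"),
        logrank = lr, cox_score = cox_score, cox_stratum = cox_strat,
        trimmed_signature = as.character(trimmed)
      )
    }
  }

  counts <- c(
    peptides_reference = length(keys_ref),
    peptides_target = length(keys_tgt),
    unique_to_target = length(uniq_keys),
    unique_to_target_untreated = length(uniq_keys_untreated),
    unmapped_keys = length(attr(site_map, "unmapped")),
    ub_proteins = length(ub_proteins),
    proteome_down = length(prot_calls$down),
    down_and_ub = length(nom$down_and_ub),
    clinical_up = nrow(clinical_up),
    nominated = nrow(candidates)
  )

  evaluation <- NULL
  if (!is.null(bundle$truth)) {
    truth <- bundle$truth$substrates
    hit <- intersect(candidates$protein_id, truth)
    evaluation <- list(
      n_true_substrates = length(truth),
      sensitivity = if (length(truth)) length(hit) / length(truth) else NA_real_,
      fdp = if (nrow(candidates)) 1 - length(hit) / nrow(candidates) else 0
    )
  }

  manifest <- list(
    seed = if (!is.null(bundle$config)) bundle$config$seed else NA_integer_,
    parameters = list(
      target = target, reference = reference,
      rna_min_abs_fold = rna_spec$min_abs_fold, rna_max_fdr = rna_spec$max_fdr,
      prot_min_abs_fold = prot_spec$min_abs_fold, prot_max_fdr = prot_spec$max_fdr,
      clinical_min_log2fc = clinical_min_log2fc,
      clinical_max_adj_p = clinical_max_adj_p,
      trim_k = trim_k, universe_size = universe_size
    ),
    counts = as.list(counts),
    venn = list(unique_reference = vn$unique_a, shared = vn$shared,
                unique_target = vn$unique_b),
    venn4_counts = if (!is.null(venn4)) as.list(venn4$counts) else NULL,
    overlap = if (!is.null(overlap)) {
      list(n_overlap = overlap$n_overlap, p_value = overlap$p_value)
    } else NULL,
    down_and_ub = nom$down_and_ub,
    candidates = candidates,
    signature = signature,
    evaluation = evaluation
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_candidates(candidates, file.path(out_dir, "candidates.tsv"))
    writeLines(nom$down_and_ub, file.path(out_dir, "down_and_ub.txt"))
    utils::write.table(site_map, file.path(out_dir, "site_annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_differential(prot_res, prot_spec, file.path(out_dir, "proteome_differential.tsv"))
    mjson <- manifest
    mjson$candidates <- NULL
    jsonlite::write_json(mjson, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  manifest
}

#' Render a human-readable pipeline report
#'
#' Funnel table, Venn counts, interactor-overlap and survival statistics as
#' text lines, plus the same content as a JSON string that round-trips
#' through [jsonlite::fromJSON()].
#'
#' @param manifest A [run_pipeline()] manifest.
#' @return List with `text` (character vector of report lines) and `json`
#'   (single JSON string).
#' @export
emit_report <- function(manifest) {
  stopifnot(is.list(manifest), !is.null(manifest$counts))
  cnt <- manifest$counts
  lines <- c(
    "== substrate nomination report ==",
    sprintf("peptides: reference %d | target %d | unique-to-target %d",
            cnt$peptides_reference, cnt$peptides_target, cnt$unique_to_target),
    sprintf("funnel: ub proteins %d -> down+ub %d -> nominated %d",
            cnt$ub_proteins, cnt$down_and_ub, cnt$nominated)
  )
  if (!is.null(manifest$overlap)) {
    lines <- c(lines, sprintf("interactor overlap: %d proteins, p = %.3g",
                              manifest$overlap$n_overlap, manifest$overlap$p_value))
  }
  if (!is.null(manifest$signature) && !is.null(manifest$signature$logrank)) {
    s <- manifest$signature
    lines <- c(lines, sprintf(
      "survival: threshold %.3f (%s), high/low %d/%d, log-rank p = %.3g, Cox HR = %.3f (p = %.3g)",
      s$threshold, s$dichotomize_method, s$n_high, s$n_low,
      s$logrank$p_value, s$cox_score$hr, s$cox_score$p_value
    ))
  }
  if (!is.null(manifest$evaluation)) {
    lines <- c(lines, sprintf("vs ground truth: sensitivity %.3f, FDP %.3f",
                              manifest$evaluation$sensitivity,
                              manifest$evaluation$fdp))
  }
  payload <- manifest
  payload$candidates <- NULL
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  list(text = lines, json = as.character(json))
}
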