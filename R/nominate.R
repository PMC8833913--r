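#' Nominate substrate candidates by triple intersection
#'
#' The headline integration: proteins that are (i) uniquely ubiquitinated in
#' the test condition, (ii) significantly downregulated in the test-condition
#' proteome, and (iii) upregulated in tumors of the clinical cohort. The
#' intermediate down-and-ubiquitinated set is a first-class output.
#'
#' @param ub_proteins Character vector: proteins with condition-unique
#'   ubiquitination (from [collapse_to_proteins()]).
#' @param proteome_down Character vector: proteome down-calls (from
#'   [apply_thresholds()]).
#' @param clinical_up `data.frame` with columns `protein_id`,
#'   `clinical_log2fc`, `clinical_adj_p` (tumor vs normal); duplicate IDs are
#'   an error.
#' @param cell_stats Optional [differential_test()] output for the cell-line
#'   proteome; when given, `cell_log2fc`/`cell_fdr` provenance columns are
#'   filled.
#' @param site_map Optional [map_keys_to_proteins()] output; when given, each
#'   candidate row carries its ubiquitination sites (comma-separated
#'   `ub_sites`).
#' @return List with `candidates` (a candidate table sorted by
#'   `clinical_log2fc` descending, ties by `protein_id`) and `down_and_ub`
#'   (the intermediate set, sorted).
#' @examples
#' nominate(c("A", "B", "C"), c("B", "C", "D"),
#'          data.frame(protein_id = c("C", "E"),
#'                     clinical_log2fc = c(2, 1.5), clinical_adj_p = c(1e-5, 1e-3)))
#' @export
nominate <- function(ub_proteins, proteome_down, clinical_up,
                     cell_stats = NULL, site_map = NULL) {
  stopifnot(all(c("protein_id", "clinical_log2fc", "clinical_adj_p") %in% names(clinical_up)))
  dup <- unique(clinical_up$protein_id[duplicated(clinical_up$protein_id)])
  if (length(dup)) {
    stop("nominate: duplicate protein IDs in clinical list: ",
         paste(dup, collapse = ", "))
  }
  ub_proteins <- unique(as.character(ub_proteins))
  proteome_down <- unique(as.character(proteome_down))
  down_and_ub <- sort(intersect(ub_proteins, proteome_down))
  keep <- clinical_up$protein_id %in% down_and_ub
  tab <- clinical_up[keep, c("protein_id", "clinical_log2fc", "clinical_adj_p"),
                     drop = FALSE]
  tab$cell_log2fc <- rep(NA_real_, nrow(tab))
  tab$cell_fdr <- rep(NA_real_, nrow(tab))
  if (!is.null(cell_stats) && nrow(tab)) {
    idx <- match(tab$protein_id, cell_stats$feature_id)
    tab$cell_log2fc <- cell_stats$log2fc[idx]
    tab$cell_fdr <- cell_stats$fdr[idx]
  }
  tab$ub_sites <- rep(NA_character_, nrow(tab))
  if (!is.null(site_map) && nrow(tab)) {
    tab$ub_sites <- vapply(tab$protein_id, function(p) {
      s <- sort(unique(site_map$site_pos[site_map$protein_id == p & !is.na(site_map$site_pos)]))
      if (length(s)) paste(s, collapse = ",") else NA_character_
    }, character(1))
  }
  rownames(tab) <- NULL
  list(candidates = rank_candidates(tab, "clinical_log2fc"),
       down_and_ub = down_and_ub)
}

#' Rank a candidate table
#'
#' Stable sort: descending for fold-change keys, ascending for p-value keys;
#' ties broken lexicographically by `protein_id` for determinism.
#'
#' @param table Candidate `data.frame` (needs `protein_id` plus the chosen
#'   key column).
#' @param key One of `"clinical_log2fc"`, `"clinical_adj_p"`, `"cell_log2fc"`.
#' @return The re-ordered table, row names reset.
#' @export
rank_candidates <- function(table, key = "clinical_log2fc") {
  allowed <- c("clinical_log2fc", "clinical_adj_p", "cell_log2fc")
  if (!key %in% allowed) {
    stop("rank_candidates: unknown key '", key, "' (allowed: ",
         paste(allowed, collapse = ", "), ")")
  }
  if (!key %in% names(table)) stop("rank_candidates: table lacks column '", key, "'")
  descending <- key %in% c("clinical_log2fc", "cell_log2fc")
  v <- table[[key]]
  ord <- order(if (descending) -v else v, table$protein_id, method = "radix")
  out <- table[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load the packaged 57-candidate table
#'
#' The published candidate list (57 proteins downregulated and ubiquitinated
#' upon VHL restoration in 786-O and upregulated in CPTAC ccRCC tumors),
#' transcribed verbatim with its printed tumor/normal log2 fold changes and
#' BH-adjusted p values, in the printed ranking. The stated cohort filter
#' (log2 fold change > 1, adjusted p < 0.05) is documentation of how the list
#' was built, not an invariant of the printed values: the validator enforces
#' structural integrity only (see [validate_candidate_table()]).
#'
#' @return Candidate `data.frame` with columns `protein_id`,
#'   `clinical_log2fc`, `clinical_adj_p` (cell-line provenance columns are
#'   not part of the published table).
#' @export
load_candidate_fixture <- function() {
  path <- system.file("extdata", "candidate_table_57.tsv", package = "ubinom",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_candidate_table(tab)
  tab
}

#' Validate a candidate table
#'
#' Structural checks: required columns, no duplicate IDs, finite fold
#' changes, adjusted p values in (0, 1]. Violations are reported together,
#' naming the offending rows.
#'
#' @param table Candidate `data.frame`.
#' @return `table`, invisibly.
#' @export
validate_candidate_table <- function(table) {
  need <- c("protein_id", "clinical_log2fc", "clinical_adj_p")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("candidate table: missing columns: ", paste(miss, collapse = ", "))
  }
  probs <- character()
  dup <- unique(table$protein_id[duplicated(table$protein_id)])
  if (length(dup)) probs <- c(probs, paste0("duplicate IDs: ", paste(dup, collapse = ", ")))
  bad_fc <- table$protein_id[!is.finite(table$clinical_log2fc)]
  if (length(bad_fc)) probs <- c(probs, paste0("non-finite log2fc: ", paste(bad_fc, collapse = ", ")))
  bad_p <- table$protein_id[!is.finite(table$clinical_adj_p) |
                              table$clinical_adj_p <= 0 | table$clinical_adj_p > 1]
  if (length(bad_p)) probs <- c(probs, paste0("adjusted p outside (0,1]: ", paste(bad_p, collapse = ", ")))
  if (length(probs)) stop("candidate table invalid: ", paste(probs, collapse = "; "))
  invisible(table)
}

#' Write a candidate table
#' @param candidates Candidate `data.frame` (e.g. from [nominate()]).
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
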