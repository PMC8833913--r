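# Shared Welch two-sample helper. Both the per-feature differential test and
# the signature-score group comparisons go through this single code path so
# the two surfaces agree bit-for-bit on identical inputs.
.welch_two_sample <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    return(list(diff = NA_real_, statistic = NA_real_, p = NA_real_,
                n_x = length(x), n_y = length(y)))
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # t.test errors on constant data; identical constants are a clean null
    d <- mean(y) - mean(x)
    return(list(diff = d, statistic = if (d == 0) 0 else Inf,
                p = if (d == 0) 1 else 0, n_x = length(x), n_y = length(y)))
  }
  tt <- stats::t.test(y, x, var.equal = FALSE)
  list(diff = mean(y) - mean(x), statistic = unname(tt$statistic),
       p = tt$p.value, n_x = length(x), n_y = length(y))
}

#' Read a log2 omics matrix with group labels
#'
#' Matrix TSV: first column feature IDs, remaining columns samples. The
#' companion groups TSV maps `sample` to `group`.
#'
#' @param matrix_path Feature x sample TSV of log2 abundances.
#' @param groups_path TSV with columns `sample`, `group`.
#' @return List with `values` (numeric matrix, features x samples) and
#'   `group_of` (named character vector over samples).
#' @export
read_omics_matrix <- function(matrix_path, groups_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  feats <- as.character(tab[[1]])
  if (anyDuplicated(feats)) {
    stop("read_omics_matrix: duplicate feature IDs: ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- feats
  if (anyDuplicated(colnames(vals))) stop("read_omics_matrix: duplicate sample IDs")
  g <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "group") %in% names(g)))
  miss <- setdiff(colnames(vals), g$sample)
  if (length(miss)) {
    stop("read_omics_matrix: samples without a group label: ",
         paste(miss, collapse = ", "))
  }
  group_of <- stats::setNames(as.character(g$group), g$sample)[colnames(vals)]
  list(values = vals, group_of = group_of)
}

#' Per-feature two-group differential test
#'
#' Welch two-sample t test on log2 values, feature by feature, with the log2
#' fold change defined as `mean(group B) - mean(group A)` and
#' Benjamini-Hochberg adjustment across all testable features. Features with
#' fewer than two usable samples in either group are reported with `NA`
#' statistics and excluded from the BH adjustment (their count is in the
#' `"n_untestable"` attribute).
#'
#' @param values Numeric matrix, features x samples, log2 scale. Missing
#'   values are allowed and handled pairwise-complete per feature.
#' @param group_of Named character vector mapping each column of `values` to
#'   its group label.
#' @param group_a,group_b Labels of the reference (A) and test (B) group.
#' @return `data.frame` with columns `feature_id`, `log2fc`, `p`, `fdr`,
#'   `n_a`, `n_b`, in the row order of `values`.
#' @export
differential_test <- function(values, group_of, group_a, group_b) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  if (is.null(names(group_of))) names(group_of) <- colnames(values)
  for (lab in c(group_a, group_b)) {
    if (!lab %in% group_of) stop("differential_test: no samples in group '", lab, "'")
  }
  cols_a <- names(group_of)[group_of == group_a]
  cols_b <- names(group_of)[group_of == group_b]
  res <- lapply(rownames(values), function(f) {
    .welch_two_sample(values[f, cols_a], values[f, cols_b])
  })
  out <- data.frame(
    feature_id = rownames(values),
    log2fc = vapply(res, `[[`, numeric(1), "diff"),
    p = vapply(res, `[[`, numeric(1), "p"),
    fdr = NA_real_,
    n_a = vapply(res, `[[`, integer(1), "n_x"),
    n_b = vapply(res, `[[`, integer(1), "n_y"),
    stringsAsFactors = FALSE
  )
  testable <- !is.na(out$p)
  out$fdr[testable] <- stats::p.adjust(out$p[testable], method = "BH")
  attr(out, "n_untestable") <- sum(!testable)
  out
}

#' Threshold specification for differential calls
#'
#' @param min_abs_fold Linear-scale fold-change bound (> 1); calls require
#'   `|log2fc| > log2(min_abs_fold)`, strictly.
#' @param max_fdr BH-adjusted FDR bound in (0, 1); calls require
#'   `fdr < max_fdr`, strictly.
#' @return List of class `"threshold_spec"`.
#' @examples
#' threshold_spec(4, 0.01)    # the RNA filter
#' threshold_spec(1.5, 0.05)  # the protein filter
#' @export
threshold_spec <- function(min_abs_fold, max_fdr) {
  stopifnot(is.numeric(min_abs_fold), length(min_abs_fold) == 1L,
            is.numeric(max_fdr), length(max_fdr) == 1L)
  if (!(min_abs_fold > 1)) stop("threshold_spec: min_abs_fold must be > 1")
  if (!(max_fdr > 0 && max_fdr < 1)) stop("threshold_spec: max_fdr must be in (0, 1)")
  structure(list(min_abs_fold = min_abs_fold, max_fdr = max_fdr),
            class = "threshold_spec")
}

#' Apply fold-change and FDR thresholds
#'
#' Strict inequalities on both axes: up-calls satisfy
#' `log2fc > log2(min_abs_fold)` and `fdr < max_fdr`; down-calls are the
#' mirror image. Features with `NA` statistics are never called.
#'
#' @param results Output of [differential_test()] (columns `feature_id`,
#'   `log2fc`, `fdr`).
#' @param spec A [threshold_spec()].
#' @return List with character vectors `up` and `down`, plus `call` (a vector
#'   over all features: `"up"`, `"down"` or `"ns"`).
#' @export
apply_thresholds <- function(results, spec) {
  stopifnot(inherits(spec, "threshold_spec"),
            all(c("feature_id", "log2fc", "fdr") %in% names(results)))
  lfc_bound <- log2(spec$min_abs_fold)
  ok <- !is.na(results$log2fc) & !is.na(results$fdr) & results$fdr < spec$max_fdr
  up <- ok & results$log2fc > lfc_bound
  down <- ok & results$log2fc < -lfc_bound
  call <- ifelse(up, "up", ifelse(down, "down", "ns"))
  list(up = results$feature_id[up], down = results$feature_id[down],
       call = stats::setNames(call, results$feature_id))
}

#' Four-way mRNA/protein concordance classification
#'
#' Assigns every feature occurring in any of the four call sets to exactly
#' one region of the four-set diagram (RNA up/down x protein up/down and
#' their single-omics margins). The concordant-down set (down at both the
#' RNA and the protein level) is returned explicitly.
#'
#' @param rna_up,rna_down,prot_up,prot_down Character vectors of feature IDs;
#'   `rna_up`/`rna_down` must be disjoint, likewise `prot_up`/`prot_down`.
#' @return List with `assignment` (data.frame `feature_id`, `region`),
#'   `counts` (named integer vector over occupied regions) and
#'   `concordant_down`.
#' @export
concordance_venn4 <- function(rna_up, rna_down, prot_up, prot_down) {
  rna_up <- unique(as.character(rna_up)); rna_down <- unique(as.character(rna_down))
  prot_up <- unique(as.character(prot_up)); prot_down <- unique(as.character(prot_down))
  if (length(intersect(rna_up, rna_down))) {
    stop("concordance_venn4: features in both rna_up and rna_down: ",
         paste(intersect(rna_up, rna_down), collapse = ", "))
  }
  if (length(intersect(prot_up, prot_down))) {
    stop("concordance_venn4: features in both prot_up and prot_down: ",
         paste(intersect(prot_up, prot_down), collapse = ", "))
  }
  all_feats <- union(union(rna_up, rna_down), union(prot_up, prot_down))
  rna_state <- ifelse(all_feats %in% rna_up, "rna_up",
                      ifelse(all_feats %in% rna_down, "rna_down", NA))
  prot_state <- ifelse(all_feats %in% prot_up, "prot_up",
                       ifelse(all_feats %in% prot_down, "prot_down", NA))
  region <- ifelse(
    is.na(rna_state), paste0(prot_state, "_only"),
    ifelse(is.na(prot_state), paste0(rna_state, "_only"),
           paste(rna_state, prot_state, sep = "."))
  )
  region[region == "rna_down.prot_down"] <- "concordant_down"
  region[region == "rna_up.prot_up"] <- "concordant_up"
  assignment <- data.frame(feature_id = all_feats, region = region,
                           stringsAsFactors = FALSE)
  counts <- table(assignment$region)
  list(
    assignment = assignment,
    counts = stats::setNames(as.integer(counts), names(counts)),
    concordant_down = assignment$feature_id[assignment$region == "concordant_down"]
  )
}

#' Write a differential result table
#'
#' TSV schema `feature_id, log2fc, p, fdr, call`.
#'
#' @param results Output of [differential_test()].
#' @param spec A [threshold_spec()] used to derive the `call` column.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_differential <- function(results, spec, path) {
  calls <- apply_thresholds(results, spec)
  out <- results[, c("feature_id", "log2fc", "p", "fdr")]
  out$call <- unname(calls$call[out$feature_id])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
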