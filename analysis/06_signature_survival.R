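#!/usr/bin/env Rscript
# Prognostic value of the nominated signature in the simulated cohort:
# geometric-mean scores on tumor samples, density-peak dichotomization,
# Kaplan-Meier / log-rank / Cox comparisons of the strata, tumor-vs-normal
# score comparison, and survival-based trimming to 20 genes.
# Run after 05_nominate.R.

suppressPackageStartupMessages(library(ubinom))

cm <- read_omics_matrix("results/study/clinical_matrix.tsv",
                        "results/study/clinical_groups.tsv")
surv <- read.delim("results/study/survival.tsv")
genes <- read.delim("results/candidates.tsv")$protein_id
stopifnot(length(genes) >= 1)

tumor_cols <- names(cm$group_of)[cm$group_of == "tumor"]
normal_cols <- names(cm$group_of)[cm$group_of == "normal"]
score_t <- signature_score(cm$values[, tumor_cols], genes)
score_n <- signature_score(cm$values[, normal_cols], genes)

cmp <- compare_scores(list(normal = score_n, tumor = score_t))
message(sprintf("tumor vs normal signature score: +%.2f log2 (p = %.3g)",
                cmp$difference, cmp$p_value))

d <- density_dichotomize(score_t)
message(sprintf("dichotomization: threshold %.3f (%s), %d high / %d low",
                d$threshold, d$method, sum(d$stratum == "high"),
                sum(d$stratum == "low")))

surv <- surv[match(tumor_cols, surv$sample_id), ]
lr <- logrank_test(surv$time, surv$event, d$stratum)
cox_s <- cox_hr(surv$time, surv$event, score_t)
cox_g <- cox_hr(surv$time, surv$event, as.integer(d$stratum == "high"))
message(sprintf("log-rank high vs low: chi2 = %.2f, p = %.3g", lr$statistic, lr$p_value))
message(sprintf("Cox per score unit: HR %.2f (p = %.3g); high vs low: HR %.2f (p = %.3g)",
                cox_s$hr, cox_s$p_value, cox_g$hr, cox_g$p_value))

km_hi <- km_estimate(surv$time[d$stratum == "high"], surv$event[d$stratum == "high"])
km_lo <- km_estimate(surv$time[d$stratum == "low"], surv$event[d$stratum == "low"])
km_hi$stratum <- "high"; km_lo$stratum <- "low"
write.table(rbind(km_hi, km_lo), "results/km_curves.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

k <- min(20L, length(genes))
trimmed <- trim_by_survival(cm$values[, tumor_cols], surv$time, surv$event,
                            genes, k = k)
writeLines(trimmed, "results/trimmed_signature.txt")
message(sprintf("trimmed signature: %d of %d genes kept (results/trimmed_signature.txt)",
                k, length(genes)))

jsonlite::write_json(
  list(threshold = d$threshold, method = d$method,
       logrank = lr, cox_score = cox_s, cox_stratum = cox_g,
       tumor_vs_normal = as.list(cmp[1, ])),
  "results/signature_survival.json", auto_unbox = TRUE, digits = NA
)
message("wrote results/signature_survival.json")
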