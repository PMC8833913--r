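#!/usr/bin/env Rscript
# Two-group differential statistics on the simulated cell-line matrices with
# the standard filters (RNA: fold > 4, FDR < 0.01; protein: fold > 1.5,
# FDR < 0.05) and the four-way mRNA/protein concordance classification.
# Run after 01_simulate_study.R.

suppressPackageStartupMessages(library(ubinom))

pm <- read_omics_matrix("results/study/proteome_matrix.tsv",
                        "results/study/proteome_groups.tsv")
rm_ <- read_omics_matrix("results/study/rna_matrix.tsv",
                         "results/study/rna_groups.tsv")

prot_res <- differential_test(pm$values, pm$group_of, "Ctrl", "VHL")
rna_res <- differential_test(rm_$values, rm_$group_of, "Ctrl", "VHL")
prot_spec <- threshold_spec(1.5, 0.05)
rna_spec <- threshold_spec(4, 0.01)
write_differential(prot_res, prot_spec, "results/proteome_differential.tsv")
write_differential(rna_res, rna_spec, "results/rna_differential.tsv")

prot <- apply_thresholds(prot_res, prot_spec)
rna <- apply_thresholds(rna_res, rna_spec)
message(sprintf("protein calls: %d up, %d down of %d features",
                length(prot$up), length(prot$down), nrow(prot_res)))
message(sprintf("RNA calls: %d up, %d down of %d features",
                length(rna$up), length(rna$down), nrow(rna_res)))

cv <- concordance_venn4(rna$up, rna$down, prot$up, prot$down)
for (r in names(cv$counts)) message(sprintf("  %-18s %d", r, cv$counts[[r]]))
message(sprintf("concordant-down (RNA and protein): %d; protein-only-down: %d",
                length(cv$concordant_down),
                sum(cv$assignment$region == "prot_down_only")))
write.table(cv$assignment, "results/concordance_regions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
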