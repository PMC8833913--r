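#!/usr/bin/env Rscript
# The headline triple intersection: proteins uniquely ubiquitinated upon VHL
# restoration AND downregulated in the restored proteome AND overexpressed in
# tumors, ranked by tumor/normal fold change. Also validates the packaged
# published 57-candidate table. Run after 01_simulate_study.R.

suppressPackageStartupMessages(library(ubinom))

bundle_dir <- "results/study"
proteome <- read_proteome(file.path(bundle_dir, "proteome.fasta"))
events <- read_ub_events(file.path(bundle_dir, "ub_events.tsv"))
pm <- read_omics_matrix(file.path(bundle_dir, "proteome_matrix.tsv"),
                        file.path(bundle_dir, "proteome_groups.tsv"))
cm <- read_omics_matrix(file.path(bundle_dir, "clinical_matrix.tsv"),
                        file.path(bundle_dir, "clinical_groups.tsv"))

uniq <- unique_to_condition(events, "VHL", "Ctrl", require_mg132 = TRUE)
site_map <- map_keys_to_proteins(uniq, proteome)
ub_prot <- collapse_to_proteins(uniq, site_map)

prot_res <- differential_test(pm$values, pm$group_of, "Ctrl", "VHL")
prot_down <- apply_thresholds(prot_res, threshold_spec(1.5, 0.05))$down

clin_res <- differential_test(cm$values, cm$group_of, "normal", "tumor")
keep <- !is.na(clin_res$fdr) & clin_res$log2fc > 1 & clin_res$fdr < 0.05
clinical_up <- data.frame(protein_id = clin_res$feature_id[keep],
                          clinical_log2fc = clin_res$log2fc[keep],
                          clinical_adj_p = clin_res$fdr[keep])

nom <- nominate(ub_prot, prot_down, clinical_up,
                cell_stats = prot_res, site_map = site_map)
write_candidates(nom$candidates, "results/candidates.tsv")
writeLines(nom$down_and_ub, "results/down_and_ub.txt")
message(sprintf("funnel: %d ubiquitinated -> %d down+ub -> %d nominated",
                length(ub_prot), length(nom$down_and_ub), nrow(nom$candidates)))

truth <- jsonlite::fromJSON(file.path(bundle_dir, "ground_truth.json"))
hit <- intersect(nom$candidates$protein_id, truth$substrates)
message(sprintf("vs ground truth: sensitivity %.2f, FDP %.2f",
                length(hit) / length(truth$substrates),
                1 - length(hit) / max(1, nrow(nom$candidates))))

tab <- load_candidate_fixture()
top <- rank_candidates(tab, "clinical_log2fc")
message(sprintf("published table: %d rows; top candidate %s (log2FC %.2f)",
                nrow(tab), top$protein_id[1], top$clinical_log2fc[1]))
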