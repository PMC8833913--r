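#!/usr/bin/env Rscript
# Condition-level set logic on the simulated ubiquitome: Venn partition of
# the two MG132-treated peptide sets, collapse of the condition-unique set to
# proteins, and the hypergeometric overlap with the interactor list.
# Run after 01_simulate_study.R.

suppressPackageStartupMessages(library(ubinom))

proteome <- read_proteome("results/study/proteome.fasta")
events <- read_ub_events("results/study/ub_events.tsv")
interactors <- readLines("results/study/interactors.txt")

keys_ctrl <- unique(events$key[events$condition == "Ctrl" & events$mg132])
keys_vhl <- unique(events$key[events$condition == "VHL" & events$mg132])
v <- venn_counts(keys_ctrl, keys_vhl)
message(sprintf("venn: %d Ctrl-only | %d shared | %d VHL-only",
                v$unique_a, v$shared, v$unique_b))

uniq <- unique_to_condition(events, "VHL", "Ctrl", require_mg132 = TRUE)
site_map <- map_keys_to_proteins(uniq, proteome)
ub_prot <- collapse_to_proteins(uniq, site_map)
ov <- interactor_overlap(ub_prot, interactors, universe_size = length(proteome))
message(sprintf("%d VHL-unique proteins; overlap with %d interactors: %d (p = %.3g)",
                length(ub_prot), ov$n_set_b, ov$n_overlap, ov$p_value))

jsonlite::write_json(
  list(venn = list(unique_ctrl = v$unique_a, shared = v$shared,
                   unique_vhl = v$unique_b),
       ub_proteins = as.character(ub_prot),
       overlap = list(n_overlap = ov$n_overlap, p_value = ov$p_value,
                      universe = ov$n_universe)),
  "results/ubiquitome_sets.json", auto_unbox = TRUE, digits = NA
)
message("wrote results/ubiquitome_sets.json")
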