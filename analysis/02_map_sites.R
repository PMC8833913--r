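#!/usr/bin/env Rscript
# Map the condition-unique ubiquitinated peptides of the simulated study onto
# protein coordinates, summarize peptide lengths, and reproduce the published
# worked examples (TGFBI K676; NFKB2 K72 and K741) on the packaged fixture.
# Run after 01_simulate_study.R.

suppressPackageStartupMessages(library(ubinom))

proteome <- read_proteome("results/study/proteome.fasta")
events <- read_ub_events("results/study/ub_events.tsv")

uniq <- unique_to_condition(events, "VHL", "Ctrl", require_mg132 = TRUE)
site_map <- map_keys_to_proteins(uniq, proteome)
dir.create("results", showWarnings = FALSE)
write.table(site_map, "results/site_annotations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

lens <- peptide_length_summary(vapply(strsplit(uniq, "@"), `[[`, "", 1))
message(sprintf("%d peptides unique to VHL map to %d proteins (%d unmapped)",
                length(uniq), length(unique(site_map$protein_id)),
                length(attr(site_map, "unmapped"))))
message(sprintf("peptide lengths %d-%d; %.0f%% within the tryptic 7-31 band",
                lens$min, lens$max,
                100 * mean(rep(as.integer(names(lens$counts)), lens$counts) %in% 7:31)))

fx <- load_site_fixture_proteome()
for (pep in c("LAPVYQK^ub^LLER", "YGCEGPSHGGLPGASSEK^ub^GR", "GHTPLDLTCSTK^ub^VK")) {
  ann <- map_peptide_to_protein(pep, fx)
  message(sprintf("%s -> %s K%d", pep, ann$protein_id[1], ann$site_pos[1]))
}
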