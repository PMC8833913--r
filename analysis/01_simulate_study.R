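#!/usr/bin/env Rscript
# Simulate the default two-condition multi-omics study (VHL-restoration
# contrast, 200-patient cohort) and write every pipeline input under
# results/study/. Pass a seed as the first argument (default 1).

suppressPackageStartupMessages(library(ubinom))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L

cfg <- study_config(seed = seed)
bundle <- generate_study(cfg)
write_study(bundle, "results/study")

ev <- bundle$ub_events
for (cond in c("Ctrl", "VHL")) {
  n_on <- length(unique(ev$key[ev$condition == cond & ev$mg132]))
  n_off <- length(unique(ev$key[ev$condition == cond & !ev$mg132]))
  message(sprintf("%s: %d ubiquitinated peptides with MG132, %d without",
                  cond, n_on, n_off))
}
message(sprintf("planted %d sites on %d true substrates; %d proteins total",
                nrow(bundle$truth$sites), length(bundle$truth$substrates),
                cfg$n_proteins))
message("study written to results/study/")
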