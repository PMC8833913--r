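Package: ubinom
Title: Multi-Omics Nomination of E3 Ubiquitin Ligase Substrates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for nominating E3 ubiquitin ligase substrates
    (modelled on VHL restoration in clear cell renal cell carcinoma cells)
    from diGly-remnant ubiquitome, quantitative proteome, transcriptome and
    clinical cohort data. Implements modified-peptide (K-epsilon-GG) parsing,
    in-silico tryptic digestion, peptide-to-protein site mapping,
    condition-unique ubiquitination calling with hypergeometric
    interactor-overlap testing, threshold-based two-group differential
    statistics with Benjamini-Hochberg control, the
    ubiquitinated-and-downregulated-and-tumor-up triple intersection with
    candidate ranking, geometric-mean signature scoring with density-peak
    survival stratification (Kaplan-Meier, log-rank, single-covariate Cox
    partial likelihood), and a seeded synthetic-study generator with
    ground-truth bookkeeping for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
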