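# ubinom

Multi-omics nomination of E3 ubiquitin ligase substrates, modelled on VHL
restoration in clear cell renal cell carcinoma (ccRCC) cells.

Restoring a ubiquitin ligase in cells that have lost it leaves a composite
fingerprint on its direct substrates: new ubiquitination marks detectable as
diGly (K-ε-GG) remnant peptides when the proteasome is blocked with MG132,
a drop in protein abundance without a matching mRNA change, and — for a
tumor suppressor's substrates — overexpression in tumors. `ubinom` turns
that reasoning into a tested pipeline for computational biologists working
with ubiquitome + proteome + transcriptome + clinical cohort data:

* modified-peptide parsing (`K[gg]`, `K(gl)`, `K^ub^` dialects), in-silico
  tryptic digestion (cleave after K/R, not before P, not at a modified K),
  and peptide-to-protein site mapping in 1-based residue coordinates
  (`LAPVYQK^ub^LLER` → TGFBI K676);
* condition-unique ubiquitination calling per MG132 stratum, Venn
  partitions, and upper-tail hypergeometric enrichment
  P(X ≥ k), X ~ Hypergeom(N, K, n) against an interactor list;
* per-feature Welch t tests on log2 matrices with Benjamini–Hochberg FDR,
  strict threshold filters (RNA |FC| > 4, FDR < 0.01; protein |FC| > 1.5,
  FDR < 0.05), and the four-way mRNA/protein concordance diagram;
* the headline triple intersection (uniquely ubiquitinated ∩ protein-down ∩
  tumor-up), ranked by clinical fold change, with the reference 57-protein
  candidate table packaged as a validated fixture;
* geometric-mean signature scoring (mean of log2 values), density-valley
  dichotomization (Silverman-bandwidth KDE), Kaplan–Meier / log-rank
  comparisons, a hand-implemented single-covariate Cox partial-likelihood
  fit (Newton, Breslow ties), and survival-based signature trimming;
* a fully seeded synthetic-study generator with ground-truth bookkeeping,
  so every statistical claim is checked by parameter recovery.

## Worked example

```r
library(ubinom)

# site mapping of an observed diGly peptide
fx <- load_site_fixture_proteome()
map_peptide_to_protein("LAPVYQK^ub^LLER", fx)
#>   protein_id peptide_start site_pos     peptide ambiguous
#> 1      TGFBI           670      676 LAPVYQKLLER     FALSE

# simulate the default study and run the full funnel
bundle <- generate_study(study_config(seed = 1))
manifest <- run_pipeline(bundle)
cat(emit_report(manifest)$text, sep = "\n")
#> == substrate nomination report ==
#> peptides: reference 575 | target 624 | unique-to-target 162
#> funnel: ub proteins 119 -> down+ub 39 -> nominated 30
#> interactor overlap: 26 proteins, p = 0.0109
#> survival: threshold 8.957 (median), high/low 100/100, log-rank p = 0.000147, Cox HR = 2.265 (p = 1.22e-06)
#> vs ground truth: sensitivity 1.000, FDP 0.000
```

Reading the report: 575 and 624 distinct ubiquitinated peptidoforms were
detected in the control and restored condition (MG132 stratum), 162 of them
only in the restored condition; these collapse to 119 proteins, 39 of which
are also significantly downregulated at the protein level, and 30 of those
are tumor-overexpressed in the simulated cohort — all 30 planted substrates,
with no false nominations. The nominated signature separates the simulated
cohort into survival strata (log-rank p = 1.5e-4) and the Cox hazard ratio
per unit signature score is 2.27.

The same stages are available as numbered drivers under `analysis/`
(`01_simulate_study.R` … `06_signature_survival.R`), each a thin script over
the package functions that prints what it found and writes its tables under
`results/`.

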