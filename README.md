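# tsrval

Validation toolkit for **transcriptome signature reversion (TSR)** in
oncology drug repurposing.

TSR ranks drugs by how strongly their gene-expression perturbation
signature inverts a tumor's differential-expression signature, on the
premise that reverting the disease transcriptome is therapeutic. The
catch: drugs that reduce cell viability — by *any* mechanism — share a
downstream transcriptional program (stress genes up, cell-cycle and
replication genes down), and those same replication genes are
upregulated in most tumors. A reversal score can therefore simply be a
proxy for generic anti-proliferative potency. `tsrval` implements the
full analysis needed to test this: it estimates drug potency, builds
drug and tumor signatures, scores reversal, removes the
viability-driven component from the drug signatures, and measures how
much predictive power survives.

## The models at the core

* **Potency (mnAUC).** Dose-response AUC records (1 = no effect, < 1 =
  sensitivity) are summarized per drug with a crossed random-intercept
  model fitted by REML, `log(auc) ~ 1 + (1|drug) + (1|cell line)`, and
  `mnAUC_i = exp(intercept + drug_BLUP_i)` — the drug's AUC in the
  average cell line. Refit per tumor-type panel and per
  leave-one-tumor-type-out complement.
* **Drug signatures.** Per landmark gene, a linear mixed model of log2
  expression on treatment (DMSO reference; crossed random intercepts
  for cell line and plate), separately for 6 h and 24 h exposure; the
  two timepoints are combined by random-effects REML meta-analysis.
* **Viability correction.** Per gene, log2FC is regressed on
  log(mnAUC) across drugs (OLS); the residual is the corrected
  signature — the part of the drug's effect not explained by its
  anti-proliferative potency.
* **Tumor signatures.** Per tumor type: expression filter
  (mean log2(count+1) >= 6), upper-quartile normalization,
  precision-weighted (voom-style) moderated differential expression,
  BH adjustment; up/down gene sets selected by four scenarios (top 50 /
  100 / 150 most significant, or |log2FC| > 1.5 & adj. p < 0.001).
* **Connectivity.** KS-statistic enrichment of the tumor's up and down
  sets in the drug's ranked signature; `score = ks_up - ks_down`
  (non-zeroing variant; the original variant zeroes same-sign cases).
  Negative scores mean reversal.
* **Validation.** Spearman correlations of score vs in-tumor-type
  mnAUC; exact Wilcoxon signed-rank tests of the per-type correlation
  distributions; nested linear models quantifying R² from the score
  versus R² from potency measured in *other* cell lines.

A synthetic-data generator (`sim_params()`, `simulate_all()`) produces
viability, perturbation and tumor-count bundles with a planted
viability-response program and ground-truth files, so every recovery
claim is testable.

## Worked example

```r
library(tsrval)

cfg <- tsr_config(output_dir = "tsr_demo", seed = 7, simulate = TRUE,
                  sim = list(n_drugs = 25, n_cell_lines_viability = 25,
                             n_tumor_types = 5, cell_lines_per_tumor_type = 5,
                             n_cell_lines_expr = 5, n_genes = 60,
                             n_program_genes = 16, n_tumor_samples_per_arm = 5))
report <- run_pipeline(cfg)
print(report)
```

```
[simulate] 25 drugs, 25 viability cell lines, 60 genes, 5 tumor types
[mnauc] 625 records in -> 25 drugs x 11 subsets out
[drug-sig] 540 experiments in -> 25 drugs x 60 genes out
[correct] 180 gene/timepoint associations, 4500 entries corrected
[tumor-sig] 5 tumor types, 58 genes kept, 898 signature rows
[connectivity] 2000 scores (25 drugs x 20 signatures x 2 states x 2 variants)
[validate] 80 correlation cells, 5 nested-model rows
Signature-reversion validation report

Score-vs-potency rho distributions (signed-rank test of median 0):
 scenario corrected n  median_rho signed_rank_p stars
  fc_adjp     FALSE 5 0.427774580        0.0625
   top100     FALSE 5 0.267359112        0.0625
   top150     FALSE 5 0.267359112        0.0625
    top50     FALSE 5 0.377692308        0.0625
  fc_adjp      TRUE 5 0.100000000        0.3125
   top100      TRUE 5 0.065434969        0.6250
   top150      TRUE 5 0.065434969        0.6250
    top50      TRUE 5 0.003846154        0.3125

Median R2: model 1 (score) 9.16%, model 2 (other cell lines) 86.88%, model 3 increment 0.2383%
```

Reading the output: *before* correction, connectivity scores correlate
positively with in-tumor potency in every selection scenario (reverters
are simply the potent drugs). *After* removing the viability footprint
the correlations collapse toward zero. And potency measured in *other*
cell lines explains ~87% of in-type potency, while adding the
connectivity score on top contributes ~0.24% — the reversal score
carries essentially no tumor-type-specific information beyond generic
potency. (This demo uses a deliberately small simulation; the default
`sim_params()` study — 120 drugs, 10 tumor types, 900 genes — sharpens
the same pattern to ~95% versus ~0.01%.)

Every intermediate table (`mnauc.csv`, `drug_signatures.csv`,
`gene_viability_assoc.csv`, `tumor_stats.csv`,
`connectivity_scores.csv`, `validation_*.csv`, a digest manifest) lands
in `output_dir`; identical config + seed reproduce byte-identical
files. A command-line wrapper with per-stage subcommands lives at
`inst/scripts/tsr_pipeline.R`:

```sh
Rscript inst/scripts/tsr_pipeline.R all --seed 7 --out tsr_demo
```

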