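# prediabgrs

Weighted genetic risk scores for prediabetes phenotypes defined from oral
glucose tolerance tests (OGTT).

## What it is for

Common variants that raise type-2-diabetes risk each carry a small
per-allele effect; summing them into a genetic risk score (GRS) is the
standard way to test whether that burden already shows up in *prediabetic*
states — impaired fasting glycemia (IFG) and impaired glucose tolerance
(IGT). `prediabgrs` is an R package for epidemiologists and statistical
geneticists who want that whole analysis as tested, reusable functions:

* **SNP panel handling** — risk-allele orientation, per-SNP weights
  `w_i = ln(OR_i)`, secretion-restricted sub-panels.
* **Genotype I/O and QC** — tabular or VCF input mapped to risk-allele
  counts, exact Hardy–Weinberg tests, complete-case filtering.
* **Glycemic classification** — ADA cut-offs (fasting ≥ 5.6, 2-h ≥ 7.8,
  diabetes ≥ 7.0 / 11.1 mmol/l) into NGT / isolated IFG / isolated IGT /
  IFG+IGT, plus the composite combined-IGT and prediabetes groups.
* **Metabolic indices** — Matsuda/DeFronzo insulin sensitivity index
  `ISI = 10000 / sqrt(G0·I0·Gmean·Imean)` from five-point OGTT curves,
  HOMA-IR/HOMA-B, median-ISI splits.
* **Risk scores** — simple `ρ'_j = Σ a_ij` and weighted
  `ρ_j = (N/Σw_i)·Σ w_i a_ij`, which lives on the allele-count scale.
* **Association models** — logistic regression with likelihood-ratio
  tests for the score term, Wald CIs for per-allele ORs, the full model
  grid and sex/obesity/insulin-resistance stratified analyses with a
  forest-plot table.
* **Power analysis** — minimum detectable Cohen's d, minimal n, minimum
  detectable per-allele OR.
* **Synthetic cohorts** — a calibrated generator with known ground truth
  (HWE genotypes, liability-based 2-h glucose, configurable effect
  modification) so the pipeline is fully testable without access to any
  real cohort.

## Worked example

```r
library(prediabgrs)

co <- generate_cohort(cohort_config(seed = 1, beta_score = log(1.2)))
built <- build_analysis_table(co$genotypes, co$phenotypes, co$panel)
derive_groups(built$data$category)
#>          NGT ISOLATED_IFG ISOLATED_IGT      IFG_IGT IGT_combined
#>         1037          177          154           72          226
#>  prediabetes        total
#>          403         1440

fit_score_model(built$data, "IGT_combined", "grs_weighted")
#> Logistic model: IGT_combined ~ grs_weighted + sex + age + bmi + isi_matsuda
#>   n = 1440 (226 cases); OR per allele = 1.190 (95% CI 1.101-1.286);
#>   LRT p = 8.099e-06
```

The cohort was generated with a true per-allele OR of 1.2 on the 2-h
glucose liability; the fitted model recovers 1.190 with a CI covering the
truth, and the likelihood-ratio test rejects decisively. Group counts show
the calibrated ~28% prediabetes prevalence (403/1440) after excluding the
2 subjects whose simulated glucose crossed the diabetes cut-offs.

```r
run_stratified_analyses(built$data)$forest[, c("stratum", "n", "or_per_allele", "lrt_p")]
#>     stratum    n or_per_allele        lrt_p
#> 1   overall 1440      1.190316 8.099173e-06
#> 2    female  958      1.197090 4.066128e-04
#> 3      male  482      1.180356 7.039363e-03
#> ...
```

`run_pipeline()` executes the same flow from files (panel TSV, genotype
TSV/VCF, phenotype TSV) and writes the HWE QC report, model grid, forest
table, characteristics table, power table and a run log.

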