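---
title: "Methods: genetic risk scores, OGTT classification, and validation by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic risk scores, OGTT classification, and validation by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prediabgrs)
```

## The scientific question

Dozens of common variants raise the risk of type 2 diabetes, each with a
small per-allele effect. `prediabgrs` asks whether the *summed* burden of
such alleles already predicts **prediabetes** — impaired fasting glycemia
(IFG) and impaired glucose tolerance (IGT) diagnosed from an oral glucose
tolerance test (OGTT) — and whether that genetic signal is confined to
vulnerable subgroups (women, the obese, the insulin resistant).

The pipeline is: SNP panel → risk-allele counts → Hardy–Weinberg QC →
glycemic classification → insulin-sensitivity indices → risk scores →
adjusted logistic models with likelihood-ratio tests → stratified models →
power/sensitivity calculations. Because the motivating cohort data are not
public, the package includes a synthetic-cohort generator with known
ground truth, so every stage — and the pipeline end to end — is testable.

## Risk scores

Each panel SNP is coded as the number of risk alleles $a_{ij} \in
\{0,1,2\}$ for subject $j$. The simple score is $\rho'_j = \sum_i a_{ij}$.
The weighted score multiplies each count by the SNP's effect size
$w_i = \ln \mathrm{OR}_i$ (literature per-allele odds ratio for diabetes)
and rescales back to the allele-count scale:

$$\rho_j = \frac{N}{\sum_i w_i} \sum_i w_i\, a_{ij},$$

so that $\rho_j \in [0, 2N]$ and, when all ORs are equal, $\rho_j =
\rho'_j$ exactly. The normalization constant has no statistical content;
it only makes the weighted score interpretable in "risk alleles". A
secretion-restricted score uses the 7 SNPs acting mainly through insulin
secretion (dropping the FTO and PPARG loci in the default panel) with the
same formula applied to the sub-panel ($N = 7$).

The default panel file ships plausible European-ancestry literature ORs
and allele frequencies as *editable configuration*: they are sensible
defaults, not authoritative estimates, and any re-analysis should supply
its own. The loader requires OR ≥ 1 after orientation to the risk allele
and refuses ambiguous rows rather than silently flipping alleles.

## Glycemic classification

From fasting and 2-h OGTT glucose (mmol/l), with ADA cut-offs applied as
strict thresholds and no rounding:

* diabetes (excluded from all analyses): fasting ≥ 7.0 or 2-h ≥ 11.1;
* IFG flag: fasting ≥ 5.6; IGT flag: 2-h ≥ 7.8;
* the four analysis categories are NGT, isolated IFG, isolated IGT, and
  IFG+IGT.

Two composite groups follow: **combined IGT** (elevated post-load glucose
regardless of fasting glycemia, i.e. isolated IGT plus IFG+IGT) and
**prediabetes** (IFG and/or IGT). Each at-risk group is modelled against
the *remainder of the full non-diabetic cohort*; this comparator
convention is used consistently in the models and in the power
calculations.

## Metabolic indices

The Matsuda/DeFronzo insulin sensitivity index uses the five-point OGTT
(0/30/60/90/120 min):

$$\mathrm{ISI} = \frac{10000}{\sqrt{G_0 \cdot I_0 \cdot \bar G \cdot \bar I}},$$

with glucose in mg/dl and insulin in µU/ml inside the formula and
unweighted means over the five samples. Inputs are taken in SI units and
converted internally (glucose × 18.016; insulin ÷ 6.0, the factor being an
argument since 6.945 is also in circulation). HOMA-IR and HOMA-B use the
standard HOMA1 equations; HOMA-B is undefined at fasting glucose ≤ 3.5
mmol/l and returned as missing with a warning. The insulin-resistance
stratum is defined by a median split of the ISI, with ties at the median
counted as *sensitive* (the "≥ median" side).

## Association models

Outcomes are modelled by maximum-likelihood logistic regression. The score
term is tested by an effect likelihood-ratio test (deviance difference
against the nested model without the score, 1 df), while effect display
uses the Wald per-allele OR with 95% CI — testing and display are
deliberately separated. Right-skewed covariates (ISI, triglycerides,
insulins, HOMA indices) are ln-transformed; this set is configurable. No
multiple-testing correction is applied (one primary hypothesis; α = 0.05
two-sided).

The primary grid crosses {simple, weighted} scores with the four outcomes
under the base adjustment (sex, age, BMI, ln ISI), adds the
secretion-restricted scores for prediabetes, and one extended combined-IGT
model with lipids (LDL, HDL, ln TG — not total cholesterol, which is
collinear with LDL), medication flags and family history. Stratified
analyses refit the combined-IGT model within sex, obesity (BMI ≥ 30
kg/m²) and ISI-median strata, dropping the stratifying covariate from the
adjustment; a stratum with fewer than 10 cases is flagged and skipped
rather than fitted. Quasi-separation is reported as an error (a slope
diverging beyond ±15 on the log-odds scale), never returned silently.

## Power and sensitivity

The minimum detectable standardized difference for group sizes $(n_1,
n_2)$ at two-sided level $\alpha$ and power $1-\beta$ uses the closed
form $d = (z_{1-\alpha/2} + z_{1-\beta})\sqrt{1/n_1 + 1/n_2}$, with an
optional noncentral-t refinement that differs by well under 0.001 at
cohort-scale n. Sample-size inversion (`minimal_n_for_effect`) uses the
noncentral-t power curve, so it agrees with `power.t.test` at 1:1
allocation. The minimum detectable per-allele OR for a logistic model
with a continuous score uses the Hsieh large-sample formula
$\beta^* = (z_{1-\alpha/2}+z_{1-\beta})/\sqrt{nP(1-P)}$ per score SD;
because no analytic formula is exact here, the package's tests
cross-validate it against Monte-Carlo logistic power, requiring simulated
power in [0.75, 0.85] at the returned OR.

## The synthetic cohort: what it emulates and what it does not

Defaults encode the study conditions of a metabolically at-risk European
cohort: n = 1442 with 959 females; age truncated-normal (mean 39, SD 13,
range 18–80); BMI lognormal with its location set so that P(BMI ≥ 30)
equals the 32% obesity target; ~28% prediabetes prevalence. A latent,
unit-variance insulin-resistance variable driven by ln BMI and age
propagates into fasting insulin, the OGTT insulin response, fasting
glucose, and the 2-h glucose liability.

Two design choices matter for interpretation:

1. **The genetic effect enters the 2-h liability only.** Fasting glucose
   carries no score term by default (a config switch adds one for
   robustness testing), mirroring the postload-specific association the
   score is meant to capture.
2. **2-h glucose is generated through a logistic liability**: $G_{120} =
   7.8 + s(\eta + \varepsilon)$ with $\varepsilon$ standard-logistic,
   $\eta$ linear in the centred weighted score, standardized age, ln BMI
   and latent resistance, and $s = 0.7$ mmol/l per liability unit. Hence
   the IGT indicator is exactly Bernoulli(plogis($\eta$)), making
   parameter recovery by logistic regression well-posed. The fitted model
   adjusts for measured ln ISI rather than the latent resistance, which
   (with the diabetes exclusion) attenuates recovered ORs by roughly 1–2%
   on the OR scale — visible in, and tolerated by, the recovery test.

Intercepts are auto-calibrated by bisection: the fasting shift targets the
IFG marginal, the liability intercept the IGT marginal (in the 256:254
proportion of a 396-strong prediabetes group), and a final joint shift on
both liabilities pins the realized prediabetes prevalence among
non-diabetic subjects to the target (an error is raised if it ends more
than 0.02 away). Calibration is deterministic given the seed; an explicit
seed is required and the global RNG stream is restored afterwards.

Intermediate OGTT points (30/60/90) are a rise-and-fall interpolation
between fasting and 2-h values with multiplicative noise, and 2-h insulin
tracks 2-h glucose and resistance; these shapes are heuristics chosen for
physiological plausibility, not estimates from data. Lipids, medication
use (~2% lipid-lowering, ~8% antihypertensive) and family history (48%)
are generated with mild age/resistance dependence for use by the extended
model and the characteristics table.

What the generator does *not* emulate: linkage disequilibrium between
panel SNPs (they sit on distinct loci), family structure, measurement
error in genotyping, non-European allele frequencies, or realistic
ISI magnitudes — with physiologic insulin excursions and the standard
unit conversions the simulated cohort's median ISI is near 5, not the
mid-teens some cohorts report, so ISI-based results should be read on
the rank scale (the median split), not the absolute one. Effect
modification is available as `obese_only` or `resistant_only`; the
resistant rule uses the *latent* resistance median, since the realized
ISI split is partly downstream of the outcome. Passing tests on this
generator shows the machinery is correct and calibrated, not that any
particular real cohort's estimates will be reproduced.

## Numerical and testing choices

* HWE: exact conditional test, two-sided by summing configurations no
  more probable than the observed heterozygote count, computed by
  vectorised log-factorial enumeration (guarded by a `1 + 10^{-12}`
  tie tolerance). The test suite checks exact agreement with an
  independent recurrence-based oracle for every configuration with
  n ≤ 50, and conservativeness (rejection at or below nominal) under the
  null.
* Complete-case policy: subjects missing any panel genotype or required
  phenotype are dropped, with counts logged; no imputation and no
  fractional scores from partial panels.
* Simulation sizes in the test suite (1000 null replicates at n = 1442;
  100 recovery replicates at n = 5000; 100 replicates per
  effect-modification scenario at a stratum-restricted OR of 1.3; 5000
  Monte-Carlo power replicates per configuration) were chosen to put the
  Monte-Carlo standard error well inside each test's acceptance band.
* The effect-modification scenarios use a stratum-restricted per-allele
  OR of 1.3: large enough that the at-risk stratum detects it with high
  power at n ≈ 1442 while the complementary stratum remains null, which
  is the qualitative pattern the scenario is meant to demonstrate.

## Known limitations

Panel ORs are user configuration, not estimates; the min-detectable-OR
formula is a large-sample approximation validated only by simulation; the
generator's covariate effects are stylized (no non-linear age effects, no
sex-specific glycemia differences beyond sampling); and cohort-specific
coefficients from any real study are out of reach by construction — the
package recovers *structure* (directions, calibration, power), not
another cohort's point estimates.
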