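---
title: "Methods: a meta polygenic risk score for CVD among T2D patients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a meta polygenic risk score for CVD among T2D patients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cardiovascular disease (CVD) is the leading cause of death among type 2
diabetes (T2D) patients. Polygenic risk scores (PRS) — weighted sums of risk
alleles with weights estimated from genome-wide association studies — predict
CVD onset in the general population, but their value for *secondary* risk
stratification, i.e. predicting CVD among people who already have T2D, is
less established. `metacvd` implements a complete, testable pipeline for this
question: it combines subtype PRSs for coronary artery disease (CAD),
ischemic stroke (IS) and heart failure (HF) into one meta score, evaluates it
with survival statistics on a T2D cohort derived from coded hospital episode
records, and stratifies the evaluation by T2D onset age.

Because individual-level biobank data are access-restricted, the package
ships a synthetic study generator that reproduces the statistical structure
the analysis relies on. Every downstream stage accepts user-supplied files in
the same plain-text formats.

## The meta-PRS model

Let $Z_{i1}, Z_{i2}, Z_{i3}$ be the standardized CAD, IS and HF scores of
person $i$, $\beta_1,\beta_2,\beta_3$ the coefficients of a Cox regression of
CVD (among T2D patients) on the three standardized scores, and $\rho_{mn}$
the Pearson correlations between the standardized scores. The meta score is

$$
\mathrm{meta}_i \;=\;
\frac{\beta_1 Z_{i1}+\beta_2 Z_{i2}+\beta_3 Z_{i3}}
{\sqrt{\beta_1^2+\beta_2^2+\beta_3^2
 + 2\beta_1\beta_2\rho_{12}+2\beta_1\beta_3\rho_{13}+2\beta_2\beta_3\rho_{23}}}.
$$

The denominator is exactly the standard deviation of the numerator given the
correlation matrix of the components, so the meta score has unit variance by
construction when $\beta$ and $\rho$ describe the sample it is applied to
(`test-metaprs.R` asserts this to within 0.03 at $n = 10{,}000$).

**Joint versus marginal Cox fit.** The phrase "regression coefficients of the
Cox regression models on standardized PRS~CAD~, PRS~IS~, PRS~HF~" is
ambiguous between one joint three-covariate model and three marginal
single-covariate models. `fit_meta()` fits the joint model by default: with
the joint fit, the formula's denominator is exactly the standard deviation of
the joint linear predictor, so the normalization is self-consistent. A
`marginal = TRUE` mode is provided for comparison.

**Training protocol.** Two stages. Stage 1 selects, per subtype, the
candidate weight set with the highest AUC for that subtype's case/control
labels on a cohort free of coded CVD (cases there are interview/self-report
histories without a coded record — emulated by the generator's
`selfreport_frac`). Stage 2 uses stratified five-fold cross-validation on the
T2D cohort: per fold, components are standardized with training-fold
constants, $\beta$ and $\rho$ are estimated on the training four-fifths, and
the stored model is the *mean* of the five per-fold estimates; evaluation
metrics are likewise reported as means over the five held-out fifths. The
same seeded fold assignment is reused for training the combination and for
the reported evaluation.

**Degenerate components.** If the component correlation matrix has condition
number above $10^6$ (e.g. literally identical components), the Cox
information matrix is ridge-stabilized with $\lambda = 10^{-8}$ and a warning
is raised; in the fully collinear limit the meta score reduces to the common
component, which the tests assert.

## Cohort derivation from coded episodes

Disease onsets are derived from episode records carrying ICD9, ICD10 or
OPCS4 codes. Matching is prefix-based after stripping dots (`I21.0` matches
prefix `I21`), the onset of a disease is the earliest matching episode date,
and CVD onset is the earliest of the CAD/IS/HF onsets. The survival cohort
is then built with these rules:

* follow-up runs from T2D onset to the earliest of CVD onset, death, or the
  administrative censor date (default 2021-02-05, configurable);
* a person is an incident case only if CVD onset is **at least one day**
  after T2D onset; people with CVD on or before their T2D onset are excluded
  (a same-day event cannot be incident, and CVD-free status at baseline is
  what stage-1 training assumes) — the count of exclusions is retained on the
  cohort object;
* death strictly before the recorded T2D onset is treated as corrupt input
  (error), not silently dropped;
* `min_follow_up_days` retains people with follow-up of at least that many
  days; the default of 1 keeps the one-day cases, and 31 reproduces a
  ">30 days of follow-up" sensitivity analysis.

## Statistical kernels and numerical choices

* **Cox regression** (`fit_cox`) maximizes the Breslow partial likelihood by
  Newton-Raphson with step-halving; convergence is a maximum
  information-scaled step below $10^{-8}$ within 50 iterations; standard
  errors come from the inverse observed information. Breslow tie handling is
  the default because day-resolution follow-up produces many ties; the choice
  is recorded in the evaluation report. Complete separation is detected by
  coefficient divergence and reported as an error naming the covariate, as
  are constant covariates. The implementation is cross-checked in the test
  suite against both `survival::coxph(ties = "breslow")` and brute-force
  maximization of the written-out partial likelihood on small fixtures.
* **AUC** (`auc`) is the Mann-Whitney statistic (ties count one half) with a
  DeLong 95% CI via pROC; a seeded 2000-replicate bootstrap is available.
  The published analyses report single AUCs rather than time-dependent ones,
  so the AUC here is computed on the binary event indicator over full
  follow-up — a documented limitation, since follow-up length varies.
* **Kaplan-Meier** curves come from `survival::survfit`.
* **Quantile incidence** bins people by score rank (stable ties), reports
  per-bin event proportions, and the top-over-bottom fold ratio (infinite if
  the bottom rate is zero). Incidence is cumulative events over persons for
  the full follow-up, matching baseline-table-style proportions; person-year
  rates are deliberately not the default.
* **Calibration** converts the Breslow baseline to absolute risk at the
  median follow-up time, $1-\exp(-H_0(t^*))^{\exp(lp)}$, tabulates predicted
  versus observed incidence per decile and reports a logistic recalibration
  slope; people censored before $t^*$ without an event are excluded from the
  observed side, and a constant score yields a flagged single-bin table.

## Evaluation and stratification

`evaluate_models()` reports, per model and fold (means across folds as the
headline): HR per SD from a Cox model adjusted for age at T2D onset, sex and
ten principal components; AUC of the score alone; AUC of the score plus the
baseline covariates (a Cox linear predictor refit on the training fold);
decile incidence; the adjusted top-versus-bottom-decile HR; and extreme
decile Kaplan-Meier curves.

`stratify()` splits the cohort at 55 years of onset age. High-PRS and
high-clinical-risk groups are the top 20% of each score over the full T2D
cohort — the published Methods and figure use 20% for the risk groups while
the Results narrative says "decile"; the 20% definition is the default here
and the fraction is configurable. Among CVD cases per onset group it reports
the proportions in {high PRS only, high clinical only, both, neither}
(summing to 100%), per-group adjusted HR per SD and AUC, and the absolute
risk reduction ARR — reported as the absolute early-versus-late incidence
difference within the high-PRS stratum and within the remainder, plus their
ratio, since only "the differences in CVD incidence rate" between onset
groups and a fold comparison are specified.

The clinical risk model is a Cox fit on age at T2D onset, sex, BMI, current
smoking, hypertension, total cholesterol, LDL-C, HDL-C, triglycerides,
lipid-lowering medication and glucose — the overlap of the Framingham and
Pooled-Cohort-Equation variable lists with a typical biobank covariate table
— always refit on training folds.

## What the generator emulates — and what it does not

`simulate_study()` produces, deterministically per seed:

* **Genotypes**: independent biallelic variants, EAF uniform on
  `maf_range` (default 0.01-0.5), dosages Binomial(2, EAF); an optional
  block-LD mode (blocks of size $B$ sharing a latent haplotype indicator
  copied with probability $\sqrt r$) exists to exercise
  clumping+thresholding, not to model realistic LD maps. Strand-ambiguous
  allele pairs are not generated, as in post-QC imputation panels.
* **Genetic architecture**: per-variant effect triplets from a trivariate
  normal with covariance
  $\mathrm{diag}(\sqrt{h^2})\,\rho_g\,\mathrm{diag}(\sqrt{h^2})/m$, rescaled
  so each subtype's genetic-score variance equals $h^2_k$ exactly. Defaults
  $h^2 = (0.50, 0.25, 0.30)$ are midpoints of reported heritability ranges
  for CAD (40-60%), IS (16-40%) and HF (26-34%); $\rho_g$ off-diagonals
  (0.5/0.6/0.5) reflect the strong genetic correlations reported across the
  three subtypes.
* **GWAS summary statistics**: observed per-allele beta = true beta + noise
  with variance $1/(N \cdot 2p(1-p))$, the standard approximation for a
  standardized phenotype; no case-control ascertainment modeling. Default
  $N$ = (550k, 520k, 977k), the scale of the largest published subtype GWAS.
* **Cohort**: T2D onset age normal (mean 61.7, SD 7 — placing 17% of onsets
  at or below 55, matching published baseline tables), truncated to 30-80;
  calendar onset = birth date (uniform 1937-1966 birth cohort) + onset age,
  clamped to the records-coverage window starting 1994-04-01 — so
  early-onset patients accrue longer follow-up, the mechanism behind
  onset-age incidence contrasts, and onsets predating coverage surface at
  the coverage start exactly as first-coded episodes do in registry data.
  Subtype events are exponential with log-hazard
  $\log(\lambda_0) + \beta_{g,k} G_k + \beta_{clin}^T x$; the clinical
  linear predictor is centered so `baseline_hazard_rate` (default 0.0105
  events/person-year, calibrated once to give roughly the 19% cumulative CVD
  incidence reported for real T2D cohorts) is an average person's hazard.
  Default genetic effect log(1.3) per SD per subtype, plus an early-onset
  increment log(1.51/1.23) matching the published early/late HR contrast.
  Clinical effects default to baseline-table hazard ratios (male sex 1.53,
  age 1.04/year, hypertension 1.37, smoking 1.27, ...). Deaths are
  independent exponential (0.012/year) and the death registry is truncated
  at the censor date.
* **Coded records**: every simulated diagnosis is emitted as an episode with
  a concrete dotted code sampled from the configured prefix list;
  `selfreport_frac` (default 0.2) of subtype diagnoses are withheld from the
  coded records and logged as self-report only (the stage-1 labels);
  `prevalent_cvd_frac` (default 0.02) of people receive a CVD code on or
  before T2D onset to exercise the exclusion rule.

Not modeled, deliberately: realistic LD maps, ascertainment bias,
relatedness, genotyping error, population structure (the ten "principal
components" are standard-normal adjustment columns), competing-risk
structure beyond independent death, and seasonality/administrative patterns
in episode dates. Passing tests therefore demonstrate correctness of the
*pipeline* under the stated generative assumptions, not performance on real
biobank data; in particular absolute AUC/HR levels on real data depend on
GWAS power and LD, which the generator only caricatures. The exponential
baseline hazard is a modeling choice (the distribution of real follow-up
times is not specified by the analyses this package reproduces).

## Problem sizes used by the test suite

Unit tests run at $n$ of a few hundred to a few thousand with 25-300
variants. The end-to-end property checks use what a single desk machine
handles comfortably: 20 seeded replicates at $n = 20{,}000$, $m = 2{,}000$
for hazard-ratio recovery (the cross-validated CI must cover the simulated
HR of 1.3 in at least 17 of 20), and one $n = 20{,}000$ study for the
qualitative reproduction checks (meta at least matches the best single
component; early-onset AUC exceeds late-onset; adding the meta score never
degrades the clinical model by more than 0.005 AUC). The acceptance script
runs the default-scale study ($n = 21{,}092$, $m = 2{,}000$).

## Known limitations

* AUCs ignore follow-up time (see above); no time-dependent ROC.
* No competing-risks cumulative incidence; death is censoring.
* The per-fold CI of the cross-validated HR uses the mean per-fold standard
  error, which is conservative (per-fold test sets are a fifth of the data).
* Scores standardized on training folds assume fold-stable score
  distributions; with very small cohorts the standardization constants are
  noisy.
* P+T is the only weight-construction method implemented; Bayesian shrinkage
  weight sets are accepted as external files with a method tag.
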