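# metacvd

Genomic risk prediction of cardiovascular disease (CVD) **among type 2
diabetes (T2D) patients**: a tested, reusable R implementation of a
meta-polygenic-risk-score analysis driven by coded hospital-episode records
and survival statistics, together with a synthetic study generator so every
stage runs and is testable without access-restricted biobank data.

## Who this is for

Statistical geneticists and epidemiologists who want to

* combine subtype polygenic risk scores (coronary artery disease, ischemic
  stroke, heart failure) into one variance-normalized **meta-PRS** for CVD,
* evaluate it on a T2D survival cohort (Cox hazard ratios per SD, ROC/AUC
  with DeLong CIs, decile incidence, Kaplan–Meier contrasts, calibration)
  under five-fold cross-validation, and
* stratify the evaluation by T2D onset age (≤55 vs >55 years) and sex,
  including absolute-risk-reduction contrasts for high-PRS groups.

## The model

With standardized subtype scores $Z_{i1}, Z_{i2}, Z_{i3}$, Cox coefficients
$\beta_k$ of CVD on the three scores among T2D patients, and pairwise
Pearson correlations $\rho_{mn}$ of the scores:

$$
\mathrm{meta\text{-}PRS}_i=
\frac{\beta_1 Z_{i1}+\beta_2 Z_{i2}+\beta_3 Z_{i3}}
{\sqrt{\beta_1^2+\beta_2^2+\beta_3^2
+2\beta_1\beta_2\rho_{12}+2\beta_1\beta_3\rho_{13}+2\beta_2\beta_3\rho_{23}}}
$$

The denominator is the standard deviation of the numerator, so the meta
score has unit variance by construction. $\beta$ and $\rho$ are estimated by
five-fold cross-validation and stored as the means over folds; all reported
performance is the mean over the held-out fifths. See the methods vignette
(`vignettes/meta-prs-methods.Rmd`) for the full model, ascertainment rules,
numerical choices and generator assumptions.

## Worked example

```r
library(metacvd)

cfg    <- sim_config(n_individuals = 6000, n_variants = 500, seed = 42)
bundle <- simulate_study(cfg)          # genotypes, GWAS sumstats, episodes,
                                       # deaths, covariates, self-reports
res <- run_metaprs_study(bundle, candidates = "gwas", seed = 7)

print(res$meta_model)
print(res$evaluation)
print(res$stratified)
```

which prints (exact numbers for these seeds):

```
meta-PRS combination model (means over 5 folds)
  beta:  CAD=0.0601, IS=0.1150, HF=0.1281
  rho (off-diagonal):  0.492 0.571 0.510
  denominator: 0.2527

Cross-validated evaluation (5 folds, 10-quantile incidence)
  meta           HR/SD 1.283 (1.119-1.471)  AUC 0.572 (0.530-0.615)  AUC+baseline 0.531  top/bottom fold 2.06
  CAD            HR/SD 1.215 (1.060-1.393)  AUC 0.562 (0.519-0.605)  AUC+baseline 0.516  top/bottom fold 1.47
  IS             HR/SD 1.218 (1.064-1.394)  AUC 0.559 (0.517-0.601)  AUC+baseline 0.517  top/bottom fold 1.74
  HF             HR/SD 1.247 (1.087-1.429)  AUC 0.563 (0.520-0.607)  AUC+baseline 0.520  top/bottom fold 1.98
  clinical       HR/SD 1.374 (1.058-1.783)  AUC 0.517 (0.475-0.560)  AUC+baseline 0.517  top/bottom fold 1.11
  meta+clinical  HR/SD 1.530 (1.259-1.859)  AUC 0.557 (0.515-0.599)  AUC+baseline 0.557  top/bottom fold 1.62

Stratified report (onset-age cut 55, top 20%)
  early onset: n=1003, cases=236, HR/SD 1.468, AUC 0.617
    % of cases high PRS only 28.81 / high clinical only 0.00 / both 0.42 / neither 70.76
  late onset: n=4877, cases=837, HR/SD 1.237, AUC 0.561
    % of cases high PRS only 18.64 / high clinical only 20.55 / both 6.33 / neither 54.48
  ARR high-PRS 0.1408 vs remaining 0.0455 (ratio 3.09)
```

Reading the output: the meta score is associated with CVD at HR 1.28 per SD
and beats every single-subtype component on AUC; the top decile of the meta
score has about twice the CVD incidence of the bottom decile; the score is
clearly more discriminative among early-onset (≤55) patients (AUC 0.617 vs
0.561, HR 1.47 vs 1.24), where high *clinical* risk identifies almost no
cases; and the early-vs-late incidence gap is about three times larger in
the high-PRS group than in the remainder.

The building blocks are exported individually — `simulate_genotypes()`,
`derive_onsets()`, `build_cohort()`, `harmonize()`/`score()`,
`clump_threshold()`, `fit_cox()`, `auc()`, `km_curve()`,
`quantile_incidence()`, `select_best()`, `fit_meta()`/`apply_meta()`,
`fit_clinical_model()`, `evaluate_models()`, `calibrate()`, `stratify()` —
and accept user-supplied files in the documented plain-text formats
(dosage/variant/sumstats/weights TSV, episodes/deaths CSV, code lists YAML).

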