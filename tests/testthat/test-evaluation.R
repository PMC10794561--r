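# shared moderate simulated study for evaluation-level tests
eval_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_individuals = 6000, n_variants = 300, seed = 19,
                        gwas_n = c(1e6, 1e6, 1e6))
      b <- simulate_study(cfg)
      on <- derive_onsets(b$episodes, cfg$code_maps)
      ch <- build_cohort(on, b$deaths, b$covariates, cfg$censor_date)
      cache <<- list(bundle = b, cohort = ch)
    }
    cache
  }
})

test_that("the clinical model needs its covariates and rejects constants", {
  d <- eval_bundle()
  ch <- d$cohort
  ch$glucose <- NULL
  expect_error(fit_clinical_model(ch), "glucose")

  ch2 <- d$cohort[d$cohort$sex == 1, ]
  expect_error(fit_clinical_model(ch2), "constant covariate: sex")
})

test_that("simulated clinical effects are recovered within their CI", {
  hb <- list(genetic = c(0, 0, 0), genetic_early = 0,
             clinical = c(smoking = log(1.3)))
  cfg <- sim_config(n_individuals = 10000, n_variants = 40, seed = 29,
                    hazard_betas = hb, selfreport_frac = 0,
                    prevalent_cvd_frac = 0)
  b <- simulate_study(cfg)
  ch <- build_cohort(derive_onsets(b$episodes, cfg$code_maps), b$deaths,
                     b$covariates, cfg$censor_date)
  cm <- fit_clinical_model(ch)
  f <- cm$fit
  expect_gt(log(1.3), f$ci_lower["smoking"])
  expect_lt(log(1.3), f$ci_upper["smoking"])
  # null covariates: CIs cover zero for most coefficients
  others <- setdiff(names(f$coef), "smoking")
  covered <- sum(f$ci_lower[others] < 0 & f$ci_upper[others] > 0)
  expect_gte(covered, length(others) - 1)
})

test_that("a score independent of outcome evaluates as null", {
  d <- eval_bundle()
  ch <- d$cohort
  set.seed(2)
  noise <- rnorm(nrow(ch))
  folds <- make_folds(ch$event, 5, seed = 3)
  rep <- evaluate_models(list(noise = noise), ch, folds)
  m <- rep$models$noise
  expect_gt(m$hr_ci[2], 1)
  expect_lt(m$hr_ci[1], 1)
  expect_lt(abs(m$auc - 0.5), 0.03)
  # decile fold on the null stays within the binomial envelope of 1
  p0 <- mean(ch$event)
  se_bin <- sqrt(p0 * (1 - p0) / (nrow(ch) / 10))
  expect_lt(abs(m$decile_rates[10] - m$decile_rates[1]), 2 * 3 * se_bin)
})

test_that("headline values are the means of the per-fold values", {
  d <- eval_bundle()
  ch <- d$cohort
  g <- d$bundle$true_scores[match(ch$person_id,
                                  rownames(d$bundle$true_scores)), 1]
  folds <- make_folds(ch$event, 5, seed = 5)
  rep <- evaluate_models(list(g = g), ch, folds,
                         clinical_covars = clinical_covariates(),
                         combine_with_clinical = "g")
  for (m in rep$models) {
    expect_equal(m$auc, mean(m$per_fold$auc), tolerance = 1e-12)
    expect_equal(m$hr, exp(mean(log(m$per_fold$hr))), tolerance = 1e-12)
    expect_true(all(m$per_fold$hr_lo <= m$per_fold$hr &
                      m$per_fold$hr <= m$per_fold$hr_hi))
  }
})

test_that("adding a true score to the clinical baseline never hurts AUC", {
  d <- eval_bundle()
  ch <- d$cohort
  g <- rowMeans(d$bundle$true_scores)[match(ch$person_id,
                                            rownames(d$bundle$true_scores))]
  folds <- make_folds(ch$event, 5, seed = 7)
  rep <- evaluate_models(list(g = unname(g)), ch, folds,
                         clinical_covars = clinical_covariates(),
                         combine_with_clinical = "g")
  expect_gte(rep$models[["g+clinical"]]$auc,
             rep$models[["clinical"]]$auc - 0.01)
  # and the nested property for the adjustment covariates: adding the score
  # to them cannot do worse than the covariates alone
  folds <- make_folds(ch$event, 5, seed = 7)
  adj_only <- vapply(1:5, function(f) {
    train <- folds != f
    x <- as.matrix(ch[, c("age_t2d_onset", "sex", paste0("PC", 1:10))])
    fit <- fit_cox(ch$follow_up_days[train], ch$event[train],
                   x[train, , drop = FALSE])
    auc(drop(x[!train, ] %*% fit$coef), ch$event[!train])$auc
  }, numeric(1))
  expect_gte(rep$models$g$auc_baseline, mean(adj_only) - 0.01)
})

test_that("decile incidence ignores the Cox adjustment covariates", {
  d <- eval_bundle()
  ch <- d$cohort
  set.seed(11)
  s <- rnorm(nrow(ch))
  folds <- make_folds(ch$event, 5, seed = 9)
  r1 <- evaluate_models(list(s = s), ch, folds)
  r2 <- evaluate_models(list(s = s), ch, folds,
                        adjust_covars = c("age_t2d_onset", "sex"))
  expect_equal(r1$models$s$decile_rates, r2$models$s$decile_rates)
})

test_that("calibration is near-nominal for a well-specified score", {
  d <- eval_bundle()
  ch <- d$cohort
  g <- rowMeans(d$bundle$true_scores)[match(ch$person_id,
                                            rownames(d$bundle$true_scores))]
  cal <- calibrate(unname(g), ch)
  expect_false(cal$degenerate)
  expect_equal(nrow(cal$table), 10)
  expect_true(cal$slope > 0.7 && cal$slope < 1.3)
  # artificially doubled risk shows a slope below 1
  pred_doubled <- calibrate(unname(g) * 2, ch)
  expect_lt(pred_doubled$slope, cal$slope + 0.05)

  flat <- calibrate(rep(0.5, nrow(ch)), ch)
  expect_true(flat$degenerate)
  expect_equal(nrow(flat$table), 1)
})

test_that("stratified proportions partition the cases of each onset group", {
  d <- eval_bundle()
  ch <- d$cohort
  set.seed(13)
  rep <- stratify(rnorm(nrow(ch)), rnorm(nrow(ch)), ch)
  for (g in rep$by_group) {
    expect_equal(sum(g$proportions), 100, tolerance = 1e-9)
  }
  expect_error(stratify(rnorm(nrow(ch)), rnorm(nrow(ch)), ch, age_cut = 5),
               "empty onset-age group")
})

test_that("identical incidence in both onset groups gives zero ARR", {
  n <- 4000
  ch <- data.frame(person_id = sprintf("P%04d", 1:n),
                   follow_up_days = rep(1000, n),
                   event = rep(c(1, 0, 0, 0), n / 4),
                   age_t2d_onset = rep(c(50, 60), each = n / 2),
                   sex = rep(0:1, n / 2))
  for (k in 1:10) ch[[paste0("PC", k)]] <- rnorm(n)
  s <- rep(seq(0, 1, length.out = n / 2), 2)  # same score distribution
  rep <- stratify(s, rev(s), ch)
  expect_equal(unname(rep$arr["high_prs"]), 0, tolerance = 1e-12)
  expect_equal(unname(rep$arr["remaining"]), 0, tolerance = 1e-12)
})

test_that("an interaction makes the PRS more predictive in early onset", {
  hb <- default_hazard_betas()
  hb$genetic_early <- log(1.8)   # strong interaction for a clear contrast
  cfg <- sim_config(n_individuals = 8000, n_variants = 200, seed = 37,
                    hazard_betas = hb, gwas_n = c(1e6, 1e6, 1e6))
  b <- simulate_study(cfg)
  ch <- build_cohort(derive_onsets(b$episodes, cfg$code_maps), b$deaths,
                     b$covariates, cfg$censor_date)
  g <- rowMeans(b$true_scores)[match(ch$person_id, rownames(b$true_scores))]
  clin <- fit_clinical_model(ch)
  rep <- stratify(unname(g), unname(clin$scores), ch)
  expect_gt(rep$by_group$early$auc, rep$by_group$late$auc)
  expect_gt(rep$by_group$early$hr, rep$by_group$late$hr)
})
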