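#' Clinical covariates used by the baseline risk model
#'
#' Age at T2D onset, sex, BMI, current smoking, hypertension, total
#' cholesterol, LDL-C, HDL-C, triglycerides, lipid-lowering medication and
#' glucose: the overlap between classic CVD risk equations and a typical
#' biobank covariate table.
#' @return Character vector of column names.
#' @export
clinical_covariates <- function() {
  c("age_t2d_onset", "sex", "bmi", "smoking", "hypertension",
    "tc", "ldl", "hdl", "tg", "lipid_med", "glucose")
}

#' Fit the clinical-only Cox risk model
#'
#' @param cohort A `survival_cohort` (training split).
#' @param covars Clinical covariate column names
#'   (default [clinical_covariates()]).
#' @return List with `fit` (a `cox_fit`), `scores` (linear predictor on
#'   the training data, named by person id) and `predict(newdata)`
#'   returning the linear predictor for new rows.
#' @export
fit_clinical_model <- function(cohort, covars = clinical_covariates()) {
  missing_cols <- setdiff(covars, names(cohort))
  if (length(missing_cols)) {
    stop(sprintf("missing clinical covariate column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  x <- as.matrix(cohort[, covars, drop = FALSE])
  fit <- fit_cox(cohort$follow_up_days, cohort$event, x)
  lp <- drop(x %*% fit$coef)
  names(lp) <- cohort$person_id
  predict_fun <- function(newdata) {
    drop(as.matrix(newdata[, covars, drop = FALSE]) %*% fit$coef)
  }
  list(fit = fit, scores = lp, predict = predict_fun, covars = covars)
}

#' Cross-validated evaluation of risk scores
#'
#' For every model and every fold, evaluates on the held-out fifth:
#' hazard ratio per SD from a Cox model adjusted for `adjust_covars`
#' (score standardized by the training-fold SD), AUC of the score alone,
#' AUC of the score plus baseline covariates (linear predictor of a Cox
#' model refit on the training fold), decile incidence with the
#' top-over-bottom fold ratio, the adjusted top-vs-bottom-decile HR, and
#' Kaplan-Meier curves for the extreme deciles. Headline values are the
#' arithmetic means over folds; all per-fold values are retained.
#'
#' When `clinical_covars` is non-NULL two further models are evaluated:
#' `clinical` (Cox linear predictor of the clinical covariates, refit per
#' training fold) and `<combine_with_clinical>+clinical` (score plus
#' clinical covariates, refit per training fold).
#'
#' @param scores Named list of numeric score vectors aligned with the
#'   cohort rows (or named by person id).
#' @param cohort A `survival_cohort`.
#' @param folds Fold assignment from [fit_meta()] / [make_folds()].
#' @param adjust_covars Adjustment covariates for the Cox models (default
#'   age at T2D onset, sex and the first 10 principal components).
#' @param clinical_covars Clinical covariate names, or NULL to skip the
#'   clinical and combined models.
#' @param combine_with_clinical Which score to combine with the clinical
#'   covariates (default the first score).
#' @param q Number of quantile groups for incidence (default 10 deciles).
#' @return Object of class `eval_report`: per model, a list with
#'   `per_fold` (data frame of fold-level HR, CI, AUCs, fold ratio),
#'   `hr`, `hr_ci`, `auc`, `auc_ci`, `auc_baseline`, `decile_rates`
#'   (fold-mean), `decile_fold`, `top_bottom_hr`, `km_top`, `km_bottom`.
#' @export
evaluate_models <- function(scores, cohort, folds,
                            adjust_covars = c("age_t2d_onset", "sex",
                                              paste0("PC", 1:10)),
                            clinical_covars = NULL,
                            combine_with_clinical = names(scores)[1],
                            q = 10L) {
  stopifnot(is.list(scores), length(scores) >= 1)
  n <- nrow(cohort)
  scores <- lapply(scores, function(s) {
    if (!is.null(names(s))) s <- s[match(cohort$person_id, names(s))]
    if (length(s) != n || anyNA(s)) {
      stop("each score must cover every cohort person", call. = FALSE)
    }
    as.numeric(s)
  })
  missing_adj <- setdiff(adjust_covars, names(cohort))
  if (length(missing_adj)) {
    stop(sprintf("missing adjustment covariate(s): %s",
                 paste(missing_adj, collapse = ", ")), call. = FALSE)
  }
  k <- max(folds)
  tt <- cohort$follow_up_days
  ev <- cohort$event
  adj <- as.matrix(cohort[, adjust_covars, drop = FALSE])

  eval_score_fold <- function(s_all, f, refit_baseline = TRUE) {
    test <- folds == f
    train <- !test
    if (sum(test) < 10L) stop("test fold with fewer than 10 people",
                              call. = FALSE)
    m_tr <- mean(s_all[train]); sd_tr <- stats::sd(s_all[train])
    if (sd_tr == 0) stop("constant score in a training fold", call. = FALSE)
    z_test <- (s_all[test] - m_tr) / sd_tr

    cfit <- fit_cox(tt[test], ev[test],
                    cbind(score = z_test, adj[test, , drop = FALSE]))
    hr_row <- c(coef = unname(cfit$coef["score"]),
                se = unname(cfit$se["score"]))

    a1 <- auc(s_all[test], ev[test])
    a2 <- if (refit_baseline) {
      bfit <- fit_cox(tt[train], ev[train],
                      cbind(score = (s_all[train] - m_tr) / sd_tr,
                            adj[train, , drop = FALSE]))
      lp_test <- drop(cbind(z_test, adj[test, , drop = FALSE]) %*% bfit$coef)
      auc(lp_test, ev[test])
    } else {
      a1
    }

    qi <- quantile_incidence(s_all[test], ev[test], q = q)
    dec <- as.integer(cut(rank(s_all[test], ties.method = "first"),
                          breaks = round(seq(0, sum(test), length.out = q + 1)),
                          labels = FALSE))
    tb <- dec %in% c(1L, q)
    tb_hr <- tryCatch({
      fit_cox(tt[test][tb], ev[test][tb],
              cbind(top = as.numeric(dec[tb] == q),
                    adj[test, , drop = FALSE][tb, , drop = FALSE]))$coef["top"]
    }, error = function(e) NA_real_)

    list(hr = exp(hr_row["coef"]),
         hr_lo = exp(hr_row["coef"] - 1.96 * hr_row["se"]),
         hr_hi = exp(hr_row["coef"] + 1.96 * hr_row["se"]),
         se = hr_row["se"],
         auc = a1$auc, auc_lo = a1$ci_lower, auc_hi = a1$ci_upper,
         auc_baseline = a2$auc,
         auc_baseline_lo = a2$ci_lower, auc_baseline_hi = a2$ci_upper,
         rates = qi$rates, fold_ratio = qi$fold,
         top_bottom_hr = exp(unname(tb_hr)),
         km_top = km_curve(tt[test][dec == q], ev[test][dec == q]),
         km_bottom = km_curve(tt[test][dec == 1L], ev[test][dec == 1L]))
  }

  model_scores <- scores
  if (!is.null(clinical_covars)) {
    clin_by_fold <- lapply(seq_len(k), function(f) {
      train <- folds != f
      cm <- fit_clinical_model(cohort[train, , drop = FALSE],
                               covars = clinical_covars)
      cm$predict(cohort)
    })
    combo_by_fold <- NULL
    if (!is.null(combine_with_clinical) &&
        combine_with_clinical %in% names(scores)) {
      s0 <- scores[[combine_with_clinical]]
      combo_by_fold <- lapply(seq_len(k), function(f) {
        train <- folds != f
        m_tr <- mean(s0[train]); sd_tr <- stats::sd(s0[train])
        x <- cbind(score = (s0 - m_tr) / sd_tr,
                   as.matrix(cohort[, clinical_covars, drop = FALSE]))
        fit <- fit_cox(tt[train], ev[train], x[train, , drop = FALSE])
        drop(x %*% fit$coef)
      })
    }
  }

  out <- list()
  for (nm in names(model_scores)) {
    rows <- lapply(seq_len(k), function(f) eval_score_fold(model_scores[[nm]], f))
    out[[nm]] <- summarize_folds(rows)
  }
  if (!is.null(clinical_covars)) {
    rows <- lapply(seq_len(k), function(f)
      eval_score_fold(clin_by_fold[[f]], f, refit_baseline = FALSE))
    out[["clinical"]] <- summarize_folds(rows)
    if (!is.null(combo_by_fold)) {
      rows <- lapply(seq_len(k), function(f)
        eval_score_fold(combo_by_fold[[f]], f, refit_baseline = FALSE))
      out[[paste0(combine_with_clinical, "+clinical")]] <- summarize_folds(rows)
    }
  }
  structure(list(models = out, n_folds = k, q = q,
                 adjust_covars = adjust_covars, ties = "breslow"),
            class = "eval_report")
}

summarize_folds <- function(rows) {
  num <- function(field) vapply(rows, function(r) as.numeric(r[[field]]), numeric(1))
  per_fold <- data.frame(
    hr = num("hr"), hr_lo = num("hr_lo"), hr_hi = num("hr_hi"), se = num("se"),
    auc = num("auc"), auc_lo = num("auc_lo"), auc_hi = num("auc_hi"),
    auc_baseline = num("auc_baseline"),
    fold_ratio = num("fold_ratio"),
    top_bottom_hr = num("top_bottom_hr")
  )
  rates <- do.call(rbind, lapply(rows, `[[`, "rates"))
  mean_log_hr <- mean(log(per_fold$hr))
  mean_se <- mean(per_fold$se)
  list(
    per_fold = per_fold,
    hr = exp(mean_log_hr),
    hr_ci = exp(mean_log_hr + c(-1.96, 1.96) * mean_se),
    auc = mean(per_fold$auc),
    auc_ci = c(mean(per_fold$auc_lo), mean(per_fold$auc_hi)),
    auc_baseline = mean(per_fold$auc_baseline),
    decile_rates = colMeans(rates),
    decile_fold = incidence_fold(mean(rates[, ncol(rates)]), mean(rates[, 1])),
    top_bottom_hr = mean(per_fold$top_bottom_hr, na.rm = TRUE),
    km_top = rows[[1]]$km_top,
    km_bottom = rows[[1]]$km_bottom
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Cross-validated evaluation (%d folds, %d-quantile incidence)\n",
              x$n_folds, x$q))
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat(sprintf(
      "  %-14s HR/SD %.3f (%.3f-%.3f)  AUC %.3f (%.3f-%.3f)  AUC+baseline %.3f  top/bottom fold %.2f\n",
      nm, m$hr, m$hr_ci[1], m$hr_ci[2],
      m$auc, m$auc_ci[1], m$auc_ci[2], m$auc_baseline, m$decile_fold))
  }
  invisible(x)
}

#' Calibration of a risk score against observed incidence
#'
#' Fits a Cox model on the score, converts the Breslow baseline to a
#' predicted absolute risk at `t_star` (default: median follow-up),
#' `1 - exp(-H0(t*))^exp(lp)`, and tabulates mean predicted risk versus
#' observed incidence per decile of predicted risk. The calibration slope
#' and intercept come from logistic recalibration of the observed
#' event-by-t* indicator on the logit of predicted risk; people censored
#' before `t_star` without an event are excluded from the observed side.
#'
#' @param scores Numeric risk score aligned with the cohort.
#' @param cohort A `survival_cohort`.
#' @param t_star Evaluation horizon in days (default median follow-up).
#' @param n_bins Number of predicted-risk bins (default 10).
#' @return List with `table` (bin, n, mean_predicted, observed),
#'   `slope`, `intercept`, `t_star`, and `degenerate` (TRUE when the score
#'   is constant and only a single bin exists).
#' @export
calibrate <- function(scores, cohort, t_star = NULL, n_bins = 10L) {
  tt <- cohort$follow_up_days
  ev <- cohort$event
  if (is.null(t_star)) t_star <- stats::median(tt)
  if (stats::sd(scores) == 0) {
    obs_keep <- !(tt < t_star & ev == 0)
    return(list(table = data.frame(bin = 1L, n = sum(obs_keep),
                                   mean_predicted = NA_real_,
                                   observed = mean(ev[obs_keep] == 1 &
                                                     tt[obs_keep] <= t_star)),
                slope = NA_real_, intercept = NA_real_, t_star = t_star,
                degenerate = TRUE))
  }
  fit <- fit_cox(tt, ev, cbind(score = as.numeric(scores)))
  bh <- baseline_hazard(fit)
  last_event <- max(bh$time)
  if (t_star > last_event) {
    warning("t_star beyond the last event time; using the last event time")
    t_star <- last_event
  }
  H0 <- max(c(0, bh$hazard[bh$time <= t_star]))
  pred <- 1 - exp(-H0 * exp(fit$.lp))

  keep <- !(tt < t_star & ev == 0)  # censored before horizon: unknown status
  obs <- as.integer(ev == 1 & tt <= t_star)
  bins <- as.integer(cut(rank(pred, ties.method = "first"),
                         breaks = round(seq(0, length(pred), length.out = n_bins + 1)),
                         labels = FALSE))
  tab <- data.frame(
    bin = seq_len(n_bins),
    n = as.integer(tabulate(bins[keep], n_bins)),
    mean_predicted = as.numeric(tapply(pred[keep], factor(bins[keep],
                                                          levels = seq_len(n_bins)), mean)),
    observed = as.numeric(tapply(obs[keep], factor(bins[keep],
                                                   levels = seq_len(n_bins)), mean))
  )
  eps <- 1e-12
  lp_logit <- stats::qlogis(pmin(pmax(pred[keep], eps), 1 - eps))
  glm_fit <- stats::glm(obs[keep] ~ lp_logit, family = stats::binomial())
  list(table = tab,
       slope = unname(stats::coef(glm_fit)[2]),
       intercept = unname(stats::coef(glm_fit)[1]),
       t_star = t_star,
       degenerate = FALSE)
}

#' Onset-age and sex stratified risk report
#'
#' Splits the cohort into early (onset age <= `age_cut`) and late onset
#' groups. High-PRS and high-clinical-risk groups are the top
#' `top_fraction` of each score over the full cohort. Among CVD cases in
#' each onset group, reports the percentage in {high PRS only, high
#' clinical only, both, neither} (summing to 100 within a group), the
#' adjusted HR per SD and the AUC of the PRS per group, the absolute risk
#' reduction ARR = |incidence_early - incidence_late| within the high-PRS
#' stratum and within the remainder, their ratio, and sex-stratified
#' HR/AUC.
#'
#' @param scores Meta-PRS values aligned with the cohort.
#' @param clinical_scores Clinical risk scores aligned with the cohort.
#' @param cohort A `survival_cohort`.
#' @param age_cut Onset-age cut in years (default 55).
#' @param top_fraction High-risk fraction (default 0.20).
#' @param adjust_covars Adjustment covariates for the per-group Cox models.
#' @return Object of class `stratified_report`.
#' @export
stratify <- function(scores, clinical_scores, cohort, age_cut = 55,
                     top_fraction = 0.20,
                     adjust_covars = c("age_t2d_onset", "sex",
                                       paste0("PC", 1:10))) {
  n <- nrow(cohort)
  stopifnot(length(scores) == n, length(clinical_scores) == n)
  ev <- cohort$event
  tt <- cohort$follow_up_days
  age <- cohort$age_t2d_onset
  adj <- as.matrix(cohort[, intersect(adjust_covars, names(cohort)),
                          drop = FALSE])

  thr_prs <- stats::quantile(scores, 1 - top_fraction, names = FALSE)
  thr_clin <- stats::quantile(clinical_scores, 1 - top_fraction, names = FALSE)
  high_prs <- scores > thr_prs
  high_clin <- clinical_scores > thr_clin

  groups <- list(early = age <= age_cut, late = age > age_cut)
  if (any(vapply(groups, sum, numeric(1)) == 0)) {
    stop("empty onset-age group", call. = FALSE)
  }

  group_summary <- function(g) {
    cases <- g & ev == 1
    n_cases <- sum(cases)
    if (n_cases == 0) {
      props <- c(high_prs_only = NA, high_clinical_only = NA,
                 both = NA, neither = NA)
    } else {
      props <- 100 * c(
        high_prs_only = sum(cases & high_prs & !high_clin),
        high_clinical_only = sum(cases & !high_prs & high_clin),
        both = sum(cases & high_prs & high_clin),
        neither = sum(cases & !high_prs & !high_clin)
      ) / n_cases
    }
    z <- (scores[g] - mean(scores[g])) / stats::sd(scores[g])
    hr_fit <- tryCatch(
      fit_cox(tt[g], ev[g], cbind(score = z, adj[g, , drop = FALSE])),
      error = function(e) NULL)
    a <- tryCatch(auc(scores[g], ev[g]), error = function(e) NULL)
    list(n = sum(g), n_cases = n_cases, proportions = props,
         hr = if (!is.null(hr_fit)) exp(unname(hr_fit$coef["score"])) else NA,
         hr_ci = if (!is.null(hr_fit))
           exp(unname(c(hr_fit$ci_lower["score"], hr_fit$ci_upper["score"])))
         else c(NA, NA),
         auc = if (!is.null(a)) a$auc else NA,
         auc_ci = if (!is.null(a)) c(a$ci_lower, a$ci_upper) else c(NA, NA))
  }

  by_group <- lapply(groups, group_summary)

  inc <- function(sel) if (sum(sel) == 0) NA_real_ else mean(ev[sel])
  arr_high <- abs(inc(groups$early & high_prs) - inc(groups$late & high_prs))
  arr_rem <- abs(inc(groups$early & !high_prs) - inc(groups$late & !high_prs))
  arr_ratio <- if (is.na(arr_rem) || arr_rem == 0) Inf else arr_high / arr_rem

  sexes <- list(male = cohort$sex == 1, female = cohort$sex == 0)
  by_sex <- lapply(sexes, function(g) {
    if (sum(g) == 0 || sum(ev[g]) == 0) return(NULL)
    z <- (scores[g] - mean(scores[g])) / stats::sd(scores[g])
    adj_g <- adj[g, setdiff(colnames(adj), "sex"), drop = FALSE]
    hr_fit <- tryCatch(fit_cox(tt[g], ev[g], cbind(score = z, adj_g)),
                       error = function(e) NULL)
    a <- tryCatch(auc(scores[g], ev[g]), error = function(e) NULL)
    list(n = sum(g),
         hr = if (!is.null(hr_fit)) exp(unname(hr_fit$coef["score"])) else NA,
         auc = if (!is.null(a)) a$auc else NA)
  })

  structure(list(age_cut = age_cut, top_fraction = top_fraction,
                 by_group = by_group,
                 arr = c(high_prs = arr_high, remaining = arr_rem),
                 arr_ratio = arr_ratio,
                 by_sex = by_sex),
            class = "stratified_report")
}

#' @export
print.stratified_report <- function(x, ...) {
  cat(sprintf("Stratified report (onset-age cut %g, top %.0f%%)\n",
              x$age_cut, 100 * x$top_fraction))
  for (g in names(x$by_group)) {
    b <- x$by_group[[g]]
    cat(sprintf("  %s onset: n=%d, cases=%d, HR/SD %.3f, AUC %.3f\n",
                g, b$n, b$n_cases, b$hr, b$auc))
    cat(sprintf("    %% of cases high PRS only %.2f / high clinical only %.2f / both %.2f / neither %.2f\n",
                b$proportions[1], b$proportions[2], b$proportions[3],
                b$proportions[4]))
  }
  cat(sprintf("  ARR high-PRS %.4f vs remaining %.4f (ratio %.2f)\n",
              x$arr["high_prs"], x$arr["remaining"], x$arr_ratio))
  invisible(x)
}
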