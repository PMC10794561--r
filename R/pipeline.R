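#' Run the full meta-PRS analysis on a study bundle
#'
#' End-to-end driver: derives disease onsets from the coded episodes,
#' builds the T2D survival cohort, generates or accepts candidate weight
#' sets per CVD subtype, selects the best candidate per subtype on the
#' stage-1 CVD-free / self-report cohort, scores the three components,
#' fits the cross-validated meta-PRS combination, and evaluates all
#' models (meta, the three single-subtype scores, clinical-only and
#' meta+clinical) on the held-out folds, including the onset-age and sex
#' stratified report.
#'
#' @param bundle A `study_bundle` (from [simulate_study()] or assembled
#'   from files in the same shape).
#' @param candidates Per-subtype candidate weight sets: a named list
#'   (CAD/IS/HF) of lists of `weight_set`s; `"gwas"` (default) uses the
#'   full GWAS betas as a single candidate per subtype; `"pt"` builds a
#'   P+T grid over `pt_thresholds`.
#' @param pt_thresholds P-value grid for the P+T candidates.
#' @param n_folds Cross-validation folds (default 5).
#' @param seed Seed for fold assignment.
#' @param min_follow_up_days Cohort inclusion filter (default 1; 31
#'   reproduces a >30-day sensitivity analysis).
#' @param adjust_covars Adjustment covariates for evaluation Cox models.
#' @param clinical_covars Clinical covariates (NULL skips the clinical and
#'   combined models and the stratified report).
#' @param evaluate_single_subtypes Also evaluate CAD/IS/HF components
#'   individually (default TRUE).
#' @param age_cut,top_fraction Stratification parameters.
#' @return List with `onsets`, `cohort`, `selection`, `components`,
#'   `meta_model`, `meta_scores`, `evaluation` (an `eval_report`),
#'   `clinical` (clinical model fit), `stratified` (a
#'   `stratified_report`), `calibration`.
#' @export
run_metaprs_study <- function(bundle,
                              candidates = "gwas",
                              pt_thresholds = c(5e-8, 1e-5, 1e-3),
                              n_folds = 5L,
                              seed = 1L,
                              min_follow_up_days = 1,
                              adjust_covars = c("age_t2d_onset", "sex",
                                                paste0("PC", 1:10)),
                              clinical_covars = clinical_covariates(),
                              evaluate_single_subtypes = TRUE,
                              age_cut = 55,
                              top_fraction = 0.20) {
  cfg <- bundle$config
  subtypes <- c("CAD", "IS", "HF")

  onsets <- derive_onsets(bundle$episodes, cfg$code_maps)
  cohort <- build_cohort(onsets, bundle$deaths, bundle$covariates,
                         censor_date = cfg$censor_date,
                         min_follow_up_days = min_follow_up_days)

  # candidate weight sets per subtype
  cand_sets <- if (is.list(candidates)) {
    candidates
  } else if (identical(candidates, "gwas")) {
    lapply(stats::setNames(subtypes, subtypes), function(k) {
      list(sumstats_weights(bundle$sumstats[[k]],
                            label = paste0("gwas-", k)))
    })
  } else if (identical(candidates, "pt")) {
    lapply(stats::setNames(subtypes, subtypes), function(k) {
      lapply(pt_thresholds, function(pth) {
        clump_threshold(bundle$sumstats[[k]], bundle$genotypes, p_max = pth,
                        label = sprintf("P+T(%g)-%s", pth, k))
      })
    })
  } else {
    stop("candidates must be 'gwas', 'pt' or a named list of weight sets",
         call. = FALSE)
  }

  # score every candidate on all people
  cand_scores <- lapply(subtypes, function(k) {
    lst <- cand_sets[[k]]
    out <- lapply(lst, function(ws) {
      score(bundle$genotypes, harmonize(ws, bundle$variants))
    })
    names(out) <- vapply(lst, function(ws) attr(ws, "label"), character(1))
    out
  })
  names(cand_scores) <- subtypes

  # stage 1: CVD-free on coded records; self-reported history defines cases
  cvd_free <- if ("CVD" %in% names(onsets)) {
    onsets$person_id[is.na(onsets$CVD)]
  } else {
    onsets$person_id
  }
  selection <- lapply(subtypes, function(k) {
    cands <- cand_scores[[k]]
    if (length(cands) == 1L) {
      return(list(label = names(cands)[1], auc = NULL,
                  auc_all = stats::setNames(NA_real_, names(cands))))
    }
    sr <- bundle$self_report
    lab <- as.integer(cvd_free %in% sr$person_id[sr$disease == k])
    if (sum(lab) == 0L || sum(lab) == length(lab)) {
      warning(sprintf(
        "stage-1 labels degenerate for %s; keeping the first candidate", k))
      return(list(label = names(cands)[1], auc = NULL, auc_all = NULL))
    }
    sub <- lapply(cands, function(s) s[match(cvd_free, names(s))])
    select_best(sub, lab)
  })
  names(selection) <- subtypes

  components <- vapply(subtypes, function(k) {
    s <- cand_scores[[k]][[selection[[k]]$label]]
    unname(s[match(cohort$person_id, names(s))])
  }, numeric(nrow(cohort)))
  rownames(components) <- cohort$person_id

  meta <- fit_meta(components, cohort, n_folds = n_folds, seed = seed)
  meta_scores <- apply_meta(meta, components)

  scores <- list(meta = unname(meta_scores))
  if (evaluate_single_subtypes) {
    for (k in subtypes) scores[[k]] <- unname(components[, k])
  }
  evaluation <- evaluate_models(scores, cohort, meta$folds,
                                adjust_covars = adjust_covars,
                                clinical_covars = clinical_covars,
                                combine_with_clinical = "meta")

  clinical <- NULL
  stratified <- NULL
  calibration <- NULL
  if (!is.null(clinical_covars)) {
    clinical <- fit_clinical_model(cohort, covars = clinical_covars)
    stratified <- stratify(unname(meta_scores), unname(clinical$scores),
                           cohort, age_cut = age_cut,
                           top_fraction = top_fraction,
                           adjust_covars = adjust_covars)
    calibration <- calibrate(unname(meta_scores), cohort)
  }

  list(onsets = onsets,
       cohort = cohort,
       selection = selection,
       components = components,
       meta_model = meta,
       meta_scores = meta_scores,
       evaluation = evaluation,
       clinical = clinical,
       stratified = stratified,
       calibration = calibration)
}
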