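#' Default disease code definitions
#'
#' Prefix-based ICD9/ICD10/OPCS4 code lists for type 2 diabetes and the
#' three CVD subtypes. These are synthetic defaults intended for use with
#' the bundled generator; for real data supply the study's own code lists
#' (a data frame or YAML file in the same shape).
#'
#' @return Data frame with columns `disease`, `system`, `prefix`.
#' @export
default_code_definitions <- function() {
  rbind(
    data.frame(disease = "T2D", system = "ICD10", prefix = "E11"),
    data.frame(disease = "T2D", system = "ICD9", prefix = "250"),
    data.frame(disease = "CAD", system = "ICD10", prefix = c("I21", "I22", "I25")),
    data.frame(disease = "CAD", system = "ICD9", prefix = c("410", "412")),
    data.frame(disease = "CAD", system = "OPCS4", prefix = c("K40", "K41", "K45", "K49")),
    data.frame(disease = "IS", system = "ICD10", prefix = "I63"),
    data.frame(disease = "IS", system = "ICD9", prefix = c("433", "434")),
    data.frame(disease = "HF", system = "ICD10", prefix = "I50"),
    data.frame(disease = "HF", system = "ICD9", prefix = "428")
  )
}

#' Read code definitions from a YAML file
#'
#' Expected layout: top-level keys are disease labels, each holding named
#' lists of code prefixes per system, e.g. `CAD: {ICD10: [I21, I22]}`.
#'
#' @param path YAML file path.
#' @return Data frame with columns `disease`, `system`, `prefix`.
#' @export
read_code_definitions <- function(path) {
  y <- yaml::read_yaml(path)
  out <- do.call(rbind, lapply(names(y), function(d) {
    do.call(rbind, lapply(names(y[[d]]), function(s) {
      data.frame(disease = d, system = s,
                 prefix = as.character(unlist(y[[d]][[s]])),
                 stringsAsFactors = FALSE)
    }))
  }))
  validate_code_definitions(out)
  out
}

validate_code_definitions <- function(code_defs) {
  if (!is.data.frame(code_defs) ||
      !all(c("disease", "system", "prefix") %in% names(code_defs))) {
    stop("code definitions need columns disease, system, prefix", call. = FALSE)
  }
  bad_sys <- setdiff(unique(code_defs$system), c("ICD9", "ICD10", "OPCS4"))
  if (length(bad_sys)) {
    stop(sprintf("unknown code system(s): %s", paste(bad_sys, collapse = ", ")),
         call. = FALSE)
  }
  if (any(!nzchar(code_defs$prefix))) {
    stop("empty code prefix in code definitions", call. = FALSE)
  }
  invisible(code_defs)
}

strip_dots <- function(x) gsub(".", "", x, fixed = TRUE)

#' Derive per-person earliest onset dates from coded episodes
#'
#' A person's onset of a disease is the earliest episode date whose code
#' matches any configured prefix for that disease, within the matching code
#' system. Matching is prefix-based after stripping dots, so "I21.0"
#' matches prefix "I21". CVD onset is the earliest across the CAD, IS and
#' HF onsets.
#'
#' @param episodes Data frame with columns `person_id`, `system`
#'   (ICD9/ICD10/OPCS4), `code`, `date` (Date or ISO-8601 strings).
#' @param code_defs Code definitions data frame
#'   (see [default_code_definitions()]).
#' @return Data frame with one row per person appearing in `episodes` that
#'   matched at least one disease, with one Date column per disease plus
#'   `CVD` (earliest of CAD/IS/HF); `NA` where no matching episode exists.
#' @export
derive_onsets <- function(episodes, code_defs = default_code_definitions()) {
  validate_code_definitions(code_defs)
  stopifnot(all(c("person_id", "system", "code", "date") %in% names(episodes)))
  if (nrow(episodes) == 0) {
    out <- data.frame(person_id = character(0))
    for (d in unique(code_defs$disease)) out[[d]] <- as.Date(character(0))
    out$CVD <- as.Date(character(0))
    return(out)
  }
  bad_sys <- setdiff(unique(episodes$system), c("ICD9", "ICD10", "OPCS4"))
  if (length(bad_sys)) {
    stop(sprintf("unknown code system(s) in episodes: %s",
                 paste(bad_sys, collapse = ", ")), call. = FALSE)
  }
  dates <- as_date_strict(episodes$date, "episode date")
  codes <- strip_dots(as.character(episodes$code))

  diseases <- unique(code_defs$disease)
  persons <- sort(unique(as.character(episodes$person_id)))
  out <- data.frame(person_id = persons, stringsAsFactors = FALSE)
  for (d in diseases) {
    defs <- code_defs[code_defs$disease == d, , drop = FALSE]
    hit <- rep(FALSE, nrow(episodes))
    for (i in seq_len(nrow(defs))) {
      hit <- hit | (episodes$system == defs$system[i] &
                      startsWith(codes, strip_dots(defs$prefix[i])))
    }
    onset <- rep(as.Date(NA), length(persons))
    if (any(hit)) {
      agg <- tapply(dates[hit], as.character(episodes$person_id[hit]),
                    min, simplify = TRUE)
      idx <- match(names(agg), persons)
      onset[idx] <- as.Date(as.numeric(agg), origin = "1970-01-01")
    }
    out[[d]] <- onset
  }
  cvd_parts <- intersect(c("CAD", "IS", "HF"), names(out))
  if (length(cvd_parts)) {
    cvd <- do.call(pmin, c(unname(out[cvd_parts]), list(na.rm = TRUE)))
    out$CVD <- as.Date(cvd, origin = "1970-01-01")
  }
  out
}

#' Build the T2D survival cohort
#'
#' Keeps people with a T2D onset; follow-up runs from T2D onset to the
#' earliest of CVD onset, death, or the administrative censor date. A
#' person is a case (event = 1) only if the earliest CVD onset is at least
#' one day after T2D onset and precedes both death and the censor date.
#' People whose CVD onset is on or before their T2D onset (prevalent
#' disease) are excluded; people who die strictly before their recorded
#' T2D onset indicate corrupt input and raise an error.
#'
#' @param onsets Onset table from [derive_onsets()] (must contain `T2D` and
#'   `CVD` columns).
#' @param deaths Data frame `person_id`, `date`, or NULL.
#' @param covariates Data frame keyed by `person_id`; must contain
#'   `age_t2d_onset` unless a `birth_date` column is present, in which case
#'   onset age is computed in fractional years.
#' @param censor_date Administrative censoring date (default 2021-02-05).
#' @param min_follow_up_days Retain only people with follow-up of at least
#'   this many days (default 1; set 31 for a >30-day sensitivity filter).
#' @return Data frame of class `survival_cohort`: `person_id`,
#'   `t2d_onset`, `age_t2d_onset`, `cvd_onset`, `death_date`, `event`,
#'   `follow_up_days`, plus all covariate columns. People excluded for
#'   prevalent CVD are recorded in `attr(, "excluded")`.
#' @export
build_cohort <- function(onsets, deaths = NULL, covariates = NULL,
                         censor_date = as.Date("2021-02-05"),
                         min_follow_up_days = 1) {
  stopifnot(is.data.frame(onsets), "T2D" %in% names(onsets))
  censor_date <- as_date_strict(censor_date, "censor_date")
  cvd <- if ("CVD" %in% names(onsets)) onsets$CVD else as.Date(rep(NA, nrow(onsets)))

  keep <- !is.na(onsets$T2D)
  d <- data.frame(person_id = as.character(onsets$person_id[keep]),
                  t2d_onset = onsets$T2D[keep],
                  cvd_onset = cvd[keep],
                  stringsAsFactors = FALSE)

  d$death_date <- as.Date(rep(NA, nrow(d)))
  if (!is.null(deaths) && nrow(deaths)) {
    idx <- match(d$person_id, as.character(deaths$person_id))
    d$death_date <- as_date_strict(deaths$date, "death date")[idx]
  }
  if (any(!is.na(d$death_date) & d$death_date < d$t2d_onset)) {
    bad <- d$person_id[!is.na(d$death_date) & d$death_date < d$t2d_onset]
    stop(sprintf("death before T2D onset for person(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  if (any(d$t2d_onset >= censor_date)) {
    stop("T2D onset on or after the censor date; check inputs", call. = FALSE)
  }

  excluded <- d[!is.na(d$cvd_onset) & d$cvd_onset <= d$t2d_onset, , drop = FALSE]
  d <- d[is.na(d$cvd_onset) | d$cvd_onset > d$t2d_onset, , drop = FALSE]

  end_censor <- pmin(d$death_date, rep(censor_date, nrow(d)), na.rm = TRUE)
  is_event <- !is.na(d$cvd_onset) & d$cvd_onset <= end_censor
  d$event <- as.integer(is_event)
  end <- as.Date(ifelse(is_event, d$cvd_onset, end_censor), origin = "1970-01-01")
  d$follow_up_days <- as.numeric(end - d$t2d_onset)
  d$cvd_onset[!is_event] <- NA
  if (any(d$follow_up_days <= 0)) {
    stop("internal consistency error: non-positive follow-up computed",
         call. = FALSE)
  }
  d <- d[d$follow_up_days >= min_follow_up_days, , drop = FALSE]

  if (!is.null(covariates)) {
    idx <- match(d$person_id, as.character(covariates$person_id))
    cov <- covariates[idx, setdiff(names(covariates), "person_id"), drop = FALSE]
    if ("birth_date" %in% names(cov)) {
      bd <- as_date_strict(cov$birth_date, "birth date")
      d$age_t2d_onset <- as.numeric(d$t2d_onset - bd) / 365.25
      cov$birth_date <- NULL
      cov$age_t2d_onset <- NULL
    } else if ("age_t2d_onset" %in% names(cov)) {
      d$age_t2d_onset <- cov$age_t2d_onset
      cov$age_t2d_onset <- NULL
    }
    d <- cbind(d, cov)
  }
  rownames(d) <- NULL
  attr(d, "excluded") <- excluded
  attr(d, "censor_date") <- censor_date
  attr(d, "min_follow_up_days") <- min_follow_up_days
  class(d) <- c("survival_cohort", "data.frame")
  d
}

#' Read coded episodes from CSV
#'
#' @param path CSV with columns person_id, system, code, date.
#' @return Data frame with parsed dates.
#' @export
read_episodes <- function(path) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(code = "character"))
  stopifnot(all(c("person_id", "system", "code", "date") %in% names(e)))
  e$date <- as_date_strict(e$date, "episode date")
  e
}
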