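#' Select the best-performing candidate PRS per subtype by AUC
#'
#' Stage-1 of the two-stage training: among candidate scores for one
#' subtype, pick the one with the highest AUC against that subtype's
#' case/control labels. The stage-1 population is CVD-free on coded
#' records; cases are interview/self-report-only disease histories. Ties
#' are broken deterministically by candidate order.
#'
#' @param candidates Named list (one element per candidate) of numeric
#'   score vectors over the same people.
#' @param labels Binary labels (1 = self-reported case) aligned with the
#'   score vectors.
#' @return List with `label` (winning candidate name), `auc` (its
#'   `auc_result`), and `auc_all` (named numeric AUCs of all candidates).
#' @export
select_best <- function(candidates, labels) {
  if (!length(candidates)) stop("no candidate scores supplied", call. = FALSE)
  if (is.null(names(candidates))) {
    names(candidates) <- paste0("candidate", seq_along(candidates))
  }
  aucs <- vapply(candidates, function(s) auc(s, labels)$auc, numeric(1))
  best <- names(candidates)[which.max(aucs)]  # which.max takes first on ties
  list(label = best, auc = auc(candidates[[best]], labels), auc_all = aucs)
}

#' Stratified cross-validation fold assignment
#'
#' Seeded permutation into `k` folds of as-equal-as-possible size,
#' stratified on the event indicator so every fold contains events.
#'
#' @param events Binary event indicator (length n).
#' @param k Number of folds.
#' @param seed Seed.
#' @return Integer vector in 1..k, one entry per person.
#' @export
make_folds <- function(events, k = 5L, seed = 1L) {
  n <- length(events)
  folds <- integer(n)
  with_seed(seed, {
    for (cls in unique(events)) {
      idx <- which(events == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Fit the meta-PRS combination model by five-fold cross-validation
#'
#' For each fold: standardize the three component scores using the
#' training four-fifths (mean/SD), fit one joint Cox model of CVD on the
#' three standardized components, and compute their pairwise Pearson
#' correlations on the training split. The stored coefficients `beta` and
#' correlation matrix `rho` are the means over the five folds, and the
#' combination denominator is
#' `sqrt(b1^2 + b2^2 + b3^2 + 2 b1 b2 rho12 + 2 b1 b3 rho13 + 2 b2 b3 rho23)`
#' - exactly the standard deviation of the numerator `b1 Z1 + b2 Z2 + b3 Z3`
#' when the standardized components have correlation `rho`.
#'
#' Near-collinear components (condition number of the correlation matrix
#' above 1e6) trigger a ridge-stabilized fit (lambda = 1e-8) with a
#' warning. A marginal mode fits three separate single-component Cox
#' models instead of one joint model.
#'
#' @param components Data frame or matrix with columns CAD, IS, HF of raw
#'   component scores, rows aligned with (and named by) cohort person ids,
#'   or with a `person_id` column.
#' @param cohort A `survival_cohort` from [build_cohort()].
#' @param n_folds Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param marginal If TRUE, use three marginal Cox fits for the betas.
#' @return Object of class `meta_model`: `beta`, `rho`, `center`, `scale`
#'   (per-component standardization constants, fold means), `denominator`,
#'   `folds` (per-person assignment), `per_fold` (betas, rhos, centers and
#'   scales of every fold), `seed`, `marginal`.
#' @export
fit_meta <- function(components, cohort, n_folds = 5L, seed = 1L,
                     marginal = FALSE) {
  comp <- align_components(components, cohort$person_id)
  ev <- cohort$event
  tt <- cohort$follow_up_days
  folds <- make_folds(ev, k = n_folds, seed = seed)

  subtypes <- colnames(comp)
  per_fold <- list()
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    if (sum(ev[tr]) < 1L) stop("a training fold has zero events", call. = FALSE)
    ctr <- colMeans(comp[tr, , drop = FALSE])
    scl <- apply(comp[tr, , drop = FALSE], 2, stats::sd)
    if (any(scl == 0)) stop("constant component score in a training fold",
                            call. = FALSE)
    z <- sweep(sweep(comp[tr, , drop = FALSE], 2, ctr), 2, scl, "/")
    rho_f <- stats::cor(z)
    ridge <- 0
    if (kappa(rho_f, exact = TRUE) > 1e6) {
      warning("near-collinear components; using a ridge-stabilized Cox fit")
      ridge <- 1e-8
    }
    if (marginal) {
      beta_f <- vapply(seq_along(subtypes), function(j) {
        fit_cox(tt[tr], ev[tr], z[, j, drop = FALSE], ridge = ridge)$coef
      }, numeric(1))
      names(beta_f) <- subtypes
    } else {
      beta_f <- fit_cox(tt[tr], ev[tr], z, ridge = ridge)$coef
    }
    per_fold[[f]] <- list(beta = beta_f, rho = rho_f, center = ctr, scale = scl)
  }

  beta <- rowMeans(vapply(per_fold, `[[`, numeric(3), "beta"))
  rho <- Reduce(`+`, lapply(per_fold, `[[`, "rho")) / n_folds
  center <- rowMeans(vapply(per_fold, `[[`, numeric(3), "center"))
  scale <- rowMeans(vapply(per_fold, `[[`, numeric(3), "scale"))
  den2 <- drop(t(beta) %*% rho %*% beta)
  if (!is.finite(den2) || den2 <= 0) {
    stop("non-positive combined variance: the beta/rho combination is degenerate",
         call. = FALSE)
  }
  structure(list(beta = beta, rho = rho, center = center, scale = scale,
                 denominator = sqrt(den2), folds = folds,
                 per_fold = per_fold, seed = seed, marginal = marginal,
                 subtypes = subtypes),
            class = "meta_model")
}

align_components <- function(components, person_ids) {
  comp <- as.data.frame(components)
  if ("person_id" %in% names(comp)) {
    rownames(comp) <- comp$person_id
    comp$person_id <- NULL
  }
  comp <- as.matrix(comp)
  if (ncol(comp) != 3L) stop("need exactly three component scores", call. = FALSE)
  if (!is.null(rownames(comp)) && !is.null(person_ids)) {
    idx <- match(as.character(person_ids), rownames(comp))
    if (anyNA(idx)) {
      stop("component scores do not cover every cohort person", call. = FALSE)
    }
    comp <- comp[idx, , drop = FALSE]
  } else if (nrow(comp) != length(person_ids)) {
    stop("component scores do not cover every cohort person", call. = FALSE)
  }
  comp
}

#' @export
print.meta_model <- function(x, ...) {
  cat("meta-PRS combination model (means over", length(x$per_fold), "folds)\n")
  cat("  beta: ", paste(sprintf("%s=%.4f", x$subtypes, x$beta), collapse = ", "), "\n")
  cat("  rho (off-diagonal): ",
      sprintf("%.3f %.3f %.3f", x$rho[1, 2], x$rho[1, 3], x$rho[2, 3]), "\n")
  cat(sprintf("  denominator: %.4f\n", x$denominator))
  invisible(x)
}

#' Apply a meta-PRS model to component scores
#'
#' Standardizes each component with the model's stored constants and
#' returns `(b1 Z1 + b2 Z2 + b3 Z3) / denominator`. People missing any
#' component are dropped with a warning.
#'
#' @param model A `meta_model`.
#' @param components Raw component scores (columns CAD, IS, HF), rows
#'   named by person id or aligned by position.
#' @return Named numeric vector of meta-PRS values.
#' @export
apply_meta <- function(model, components) {
  stopifnot(inherits(model, "meta_model"))
  comp <- as.data.frame(components)
  if ("person_id" %in% names(comp)) {
    rownames(comp) <- comp$person_id
    comp$person_id <- NULL
  }
  comp <- as.matrix(comp)
  if (ncol(comp) != 3L) stop("need exactly three component scores", call. = FALSE)
  miss <- rowSums(!is.finite(comp)) > 0
  if (any(miss)) {
    warning(sprintf("dropping %d person(s) with missing component scores",
                    sum(miss)))
    comp <- comp[!miss, , drop = FALSE]
  }
  z <- sweep(sweep(comp, 2, model$center), 2, model$scale, "/")
  drop(z %*% model$beta) / model$denominator
}

#' Serialize a meta-PRS model to JSON
#'
#' @param model A `meta_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_meta_model <- function(model, path) {
  stopifnot(inherits(model, "meta_model"))
  obj <- list(
    subtypes = model$subtypes,
    beta = as.list(model$beta),
    rho = unname(apply(model$rho, 1, as.numeric, simplify = FALSE)),
    center = as.list(model$center),
    scale = as.list(model$scale),
    denominator = model$denominator,
    seed = model$seed,
    marginal = model$marginal,
    per_fold = lapply(model$per_fold, function(f) {
      list(beta = as.list(f$beta),
           rho = unname(apply(f$rho, 1, as.numeric, simplify = FALSE)),
           center = as.list(f$center), scale = as.list(f$scale))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
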