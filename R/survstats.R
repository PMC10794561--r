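#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson with
#' step-halving. Convergence is declared when the largest
#' information-scaled step is below `tol` (default 1e-8) within `max_iter`
#' iterations. Standard errors come from the inverse observed information.
#' A small ridge penalty can be supplied to stabilize near-collinear
#' designs; it is added to the information diagonal and to the score.
#'
#' Monotone likelihoods (complete separation) are detected by coefficient
#' divergence and reported as an error naming the offending covariate, as
#' are constant covariates.
#'
#' @param time Positive follow-up times.
#' @param status Event indicator (1 event, 0 censored).
#' @param x Covariate matrix (or vector / data frame), one row per person.
#' @param ridge Ridge penalty lambda (default 0).
#' @param tol Convergence tolerance on the Newton step.
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `cox_fit`: coefficients (log-HR per covariate
#'   unit), `se`, 95% CI bounds (on the log scale, exponentiated only for
#'   reporting), Wald `p`, `loglik`, `converged`, `n`, `n_events`, and the
#'   data needed for the Breslow baseline hazard.
#' @export
fit_cox <- function(time, status, x, ridge = 0, tol = 1e-8, max_iter = 50L) {
  x <- as.matrix(as.data.frame(x))
  storage.mode(x) <- "double"
  n <- length(time)
  stopifnot(nrow(x) == n, length(status) == n)
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("all follow-up times must be positive and finite", call. = FALSE)
  }
  status <- as.integer(status)
  if (sum(status) < 1L) stop("no events in the data", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant covariate: %s",
                 paste(colnames(x)[sds == 0], collapse = ", ")), call. = FALSE)
  }

  # sort ascending by time; risk set of t_i = rows i..n after sorting,
  # with ties grouped so every tied event shares the full risk set
  ord <- order(time)
  tt <- time[ord]; dd <- status[ord]; xx <- x[ord, , drop = FALSE]
  first_of_tie <- match(tt, tt)  # index of first row with the same time
  p <- ncol(x)
  beta <- rep(0, p)
  ll_old <- -Inf
  converged <- FALSE

  pl_quantities <- function(beta) {
    lp <- drop(xx %*% beta)
    lp <- lp - max(lp)   # guard overflow; cancels in ratios
    w <- exp(lp)
    S0 <- rev(cumsum(rev(w)))[first_of_tie]
    S1 <- apply(xx * w, 2, function(cl) rev(cumsum(rev(cl))))[first_of_tie, , drop = FALSE]
    ev <- dd == 1L
    ll <- sum(lp[ev] - log(S0[ev]))
    xbar <- S1 / S0
    U <- colSums(xx[ev, , drop = FALSE] - xbar[ev, , drop = FALSE])
    info <- matrix(0, p, p)
    for (a in seq_len(p)) {
      for (b in a:p) {
        S2ab <- rev(cumsum(rev(xx[, a] * xx[, b] * w)))[first_of_tie]
        v <- sum(S2ab[ev] / S0[ev] - xbar[ev, a] * xbar[ev, b])
        info[a, b] <- v
        info[b, a] <- v
      }
    }
    list(ll = ll - ridge / 2 * sum(beta^2),
         U = U - ridge * beta,
         info = info + diag(ridge, p))
  }

  for (it in seq_len(max_iter)) {
    q <- pl_quantities(beta)
    step <- tryCatch(solve(q$info, q$U), error = function(e) NULL)
    if (is.null(step)) {
      stop("singular information matrix; consider a ridge penalty",
           call. = FALSE)
    }
    halves <- 0
    repeat {
      beta_new <- beta + step
      ll_new <- pl_quantities(beta_new)$ll
      if (is.finite(ll_new) && (ll_new >= q$ll - 1e-12 || halves >= 20)) break
      step <- step / 2
      halves <- halves + 1
    }
    beta <- beta_new
    if (any(abs(beta) > 20)) {
      worst <- colnames(x)[which.max(abs(beta))]
      stop(sprintf(
        "monotone partial likelihood (complete separation) for covariate '%s'",
        worst), call. = FALSE)
    }
    if (max(abs(step)) < tol) { converged <- TRUE; ll_old <- ll_new; break }
    ll_old <- ll_new
  }

  q <- pl_quantities(beta)
  vcov <- solve(q$info)
  se <- sqrt(diag(vcov))
  names(beta) <- names(se) <- colnames(x)
  z <- beta / se
  fit <- list(
    coef = beta,
    se = se,
    ci_lower = beta - 1.96 * se,
    ci_upper = beta + 1.96 * se,
    p = 2 * stats::pnorm(-abs(z)),
    loglik = q$ll,
    converged = converged,
    n = n,
    n_events = sum(status),
    vcov = vcov,
    ridge = ridge,
    ties = "breslow",
    .time = time, .status = status, .lp = drop(x %*% beta)
  )
  class(fit) <- "cox_fit"
  fit
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox model (Breslow ties): n = %d, events = %d%s\n",
              x$n, x$n_events,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(coef = x$coef, HR = exp(x$coef), se = x$se,
                    `HR lower` = exp(x$ci_lower), `HR upper` = exp(x$ci_upper),
                    p = signif(x$p, 3), check.names = FALSE)
  print(tab)
  invisible(x)
}

#' Breslow baseline cumulative hazard of a fitted Cox model
#'
#' @param fit A `cox_fit`.
#' @return Data frame `time`, `hazard` (cumulative baseline hazard H0(t)
#'   at each event time).
#' @export
baseline_hazard <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  ord <- order(fit$.time)
  tt <- fit$.time[ord]; dd <- fit$.status[ord]
  w <- exp(fit$.lp[ord] - max(fit$.lp))
  S0 <- rev(cumsum(rev(w)))[match(tt, tt)]
  ev_times <- unique(tt[dd == 1L])
  inc <- vapply(ev_times, function(t0) {
    sum(dd == 1L & tt == t0) / (S0[match(t0, tt)] * exp(max(fit$.lp)))
  }, numeric(1))
  data.frame(time = ev_times, hazard = cumsum(inc))
}

#' AUC with confidence interval
#'
#' Mann-Whitney AUC (ties count one half) with a DeLong 95% CI by default,
#' or a seeded bootstrap. The AUC is the probability that a randomly
#' chosen case outscores a randomly chosen control.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = case, 0 = control); both classes must
#'   be non-empty.
#' @param ci_method "delong" (default) or "bootstrap" (2000 replicates).
#' @param boot_seed Seed for the bootstrap CI.
#' @return Object of class `auc_result`: `auc`, `ci_lower`, `ci_upper`
#'   (clamped to [0, 1]), `n_cases`, `n_controls`, `ci_method`.
#' @export
auc <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                boot_seed = 1L) {
  ci_method <- match.arg(ci_method)
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: one of the classes is empty", call. = FALSE)
  }
  roc <- pROC::roc(response = labels, predictor = as.numeric(scores),
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  a <- as.numeric(pROC::auc(roc))
  ci <- if (ci_method == "delong") {
    suppressWarnings(as.numeric(pROC::ci.auc(roc, method = "delong")))
  } else {
    with_seed(boot_seed, suppressWarnings(as.numeric(
      pROC::ci.auc(roc, method = "bootstrap", boot.n = 2000, progress = "none"))))
  }
  structure(list(auc = a,
                 ci_lower = max(0, ci[1]),
                 ci_upper = min(1, ci[3]),
                 n_cases = n1, n_controls = n0,
                 ci_method = ci_method),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (95%% CI %.4f-%.4f; %d cases, %d controls; %s)\n",
              x$auc, x$ci_lower, x$ci_upper, x$n_cases, x$n_controls,
              x$ci_method))
  invisible(x)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator; right-continuous, starts at 1, steps down only
#' at event times.
#'
#' @param time Positive follow-up times.
#' @param status Event indicator.
#' @return Data frame `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_curve <- function(time, status) {
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, status) ~ 1)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             surv = sf$surv)
}

#' Fold ratio between two incidence rates
#'
#' Top-over-bottom ratio as reported for extreme score quantiles; infinite
#' when the bottom rate is zero.
#'
#' @param rate_top,rate_bottom Incidence proportions.
#' @return Numeric ratio (Inf if `rate_bottom` is 0).
#' @export
incidence_fold <- function(rate_top, rate_bottom) {
  if (rate_bottom == 0) return(Inf)
  rate_top / rate_bottom
}

#' Incidence by score quantile
#'
#' Splits people into `q` near-equal groups by ascending score (ties
#' broken by stable input order) and reports the event proportion in each,
#' plus the top-over-bottom fold ratio.
#'
#' @param scores Numeric scores.
#' @param events Binary event indicator.
#' @param q Number of quantile groups (>= 2).
#' @return List with `rates` (length q, proportion of events per group,
#'   bottom to top), `counts`, `n_per_group`, and `fold`
#'   (rate top / rate bottom, Inf if the bottom rate is 0).
#' @export
quantile_incidence <- function(scores, events, q = 10L) {
  q <- as.integer(q)
  if (q < 2L) stop("q must be at least 2", call. = FALSE)
  n <- length(scores)
  if (n < q) stop("need at least q people", call. = FALSE)
  events <- as.integer(events)
  ord <- order(scores, seq_along(scores))  # stable tie-break
  grp <- rep(seq_len(q), times = diff(round(seq(0, n, length.out = q + 1))))
  counts <- tapply(events[ord], grp, sum)
  sizes <- tabulate(grp, nbins = q)
  rates <- as.numeric(counts) / sizes
  list(rates = rates,
       counts = as.integer(counts),
       n_per_group = sizes,
       fold = incidence_fold(rates[q], rates[1]))
}
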