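# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the package internals.

# Written-out Breslow log partial likelihood, O(n^2).
brute_cox_loglik <- function(beta, time, status, X) {
  X <- as.matrix(X)
  lp <- drop(X %*% beta)
  ll <- 0
  for (i in which(status == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + lp[i] - log(sum(exp(lp[risk])))
  }
  ll
}

# Grid-refined maximization of the brute-force partial likelihood.
brute_cox_mle <- function(time, status, X, lower = -5, upper = 5) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p == 1) {
    grid <- seq(lower, upper, length.out = 2001)
    ll <- vapply(grid, function(b) brute_cox_loglik(b, time, status, X),
                 numeric(1))
    b0 <- grid[which.max(ll)]
    opt <- stats::optimize(function(b) brute_cox_loglik(b, time, status, X),
                           interval = c(b0 - 0.02, b0 + 0.02), maximum = TRUE,
                           tol = 1e-9)
    opt$maximum
  } else {
    opt <- stats::optim(rep(0, p), function(b)
      -brute_cox_loglik(b, time, status, X), method = "Nelder-Mead",
      control = list(reltol = 1e-14, maxit = 5000))
    opt$par
  }
}

# Exhaustive pairwise AUC (ties count one half).
brute_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (a in cases) {
    tot <- tot + sum(a > controls) + 0.5 * sum(a == controls)
  }
  tot / (length(cases) * length(controls))
}

# Greedy clumping oracle operating on the full dosage-correlation matrix.
brute_clump <- function(sumstats, genotypes, p_max, r2_max, window_kb) {
  ss <- sumstats[sumstats$p <= p_max, , drop = FALSE]
  ss <- ss[order(ss$p, ss$chrom, ss$pos, ss$variant_id), , drop = FALSE]
  cmat <- suppressWarnings(stats::cor(genotypes[, ss$variant_id, drop = FALSE]))
  kept <- integer(0)
  for (i in seq_len(nrow(ss))) {
    ok <- TRUE
    for (j in kept) {
      if (ss$chrom[j] == ss$chrom[i] &&
          abs(ss$pos[j] - ss$pos[i]) <= window_kb * 1000 &&
          !is.na(cmat[i, j]) && cmat[i, j]^2 > r2_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  sort(ss$variant_id[kept])
}

# Small configuration used across tests (fast but non-trivial).
tiny_config <- function(...) {
  sim_config(n_individuals = 600, n_variants = 120, seed = 42, ...)
}
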