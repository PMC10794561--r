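#' Simulate a genotype dosage panel
#'
#' Draws independent biallelic variants with effect-allele frequencies
#' uniform on `maf_range` and per-person dosages Binomial(2, EAF). When
#' `ld_block_size` > 1 variants are generated in blocks that share a latent
#' haplotype indicator: each haplotype allele copies the block's latent
#' allele with probability sqrt(`ld_block_r`), giving pairwise dosage
#' correlation close to `ld_block_r` within a block while preserving the
#' marginal allele frequency.
#'
#' Allele pairs are drawn from strand-unambiguous combinations only (no A/T
#' or C/G variants), as typical post-QC imputation panels are.
#'
#' @param config A [sim_config()].
#' @param seed Seed for this step (defaults to `config$seed`).
#' @return List with `dosages` (n x m integer matrix, people in rows) and
#'   `variants` (data frame: variant_id, chrom, pos, ref, alt, eaf, block).
#'   The counted (dosage) allele is `alt`.
#' @export
simulate_genotypes <- function(config, seed = config$seed) {
  validate_sim_config(config)
  n <- config$n_individuals
  m <- config$n_variants
  with_seed(seed, {
    b_size <- config$ld_block_size
    block <- rep(seq_len(ceiling(m / b_size)), each = b_size)[seq_len(m)]
    # one EAF per block so correlated variants share a frequency
    block_eaf <- stats::runif(max(block), config$maf_range[1], config$maf_range[2])
    eaf <- block_eaf[block]

    # unambiguous ref/alt pairs
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(r) {
      sample(setdiff(bases, c(r, allele_complement(r))), 1L)
    }, character(1))

    if (b_size == 1L || config$ld_block_r == 0) {
      dos <- matrix(stats::rbinom(n * m, 2L, rep(eaf, each = n)), n, m)
    } else {
      c_copy <- sqrt(config$ld_block_r)
      dos <- matrix(0L, n, m)
      for (b in seq_len(max(block))) {
        idx <- which(block == b)
        p <- block_eaf[b]
        for (h in 1:2) {
          latent <- stats::rbinom(n, 1L, p)
          for (j in idx) {
            take <- stats::runif(n) < c_copy
            hap <- ifelse(take, latent, stats::rbinom(n, 1L, p))
            dos[, j] <- dos[, j] + hap
          }
        }
      }
    }
    storage.mode(dos) <- "integer"
    ids <- sprintf("snp%05d", seq_len(m))
    rownames(dos) <- sprintf("P%06d", seq_len(n))
    colnames(dos) <- ids
    variants <- data.frame(
      variant_id = ids,
      chrom = "1",
      pos = seq_len(m) * 5000L,
      ref = unname(ref),
      alt = unname(alt),
      eaf = eaf,
      block = block,
      stringsAsFactors = FALSE
    )
    list(dosages = dos, variants = variants)
  })
}

#' Simulate correlated per-variant effects and GWAS summary statistics
#'
#' Per-variant effect triplets (CAD, IS, HF) are drawn from a zero-mean
#' trivariate normal with covariance `diag(sqrt(h2)) rho_g diag(sqrt(h2)) / m`
#' on the standardized-dosage scale, then each subtype's effect vector is
#' rescaled so that the variance of its genetic score (sum of effect times
#' standardized dosage over independent variants) equals `h2[k]` exactly.
#' Observed GWAS effects are the true per-allele effects plus normal noise
#' with variance 1 / (gwas_n[k] * 2 * EAF * (1 - EAF)); standard errors and
#' two-sided normal p-values are consistent with that noise model.
#'
#' @param config A [sim_config()].
#' @param variants Variant table from [simulate_genotypes()].
#' @param seed Seed for this step.
#' @return List with `true_effects` (m x 3 matrix, standardized-dosage
#'   scale, columns CAD/IS/HF) and `sumstats`, a named list of three data
#'   frames (variant_id, chrom, pos, effect_allele, other_allele, eaf,
#'   beta, se, p) with per-allele betas.
#' @export
simulate_effects_and_sumstats <- function(config, variants, seed = config$seed) {
  validate_sim_config(config)
  m <- nrow(variants)
  h2 <- as.numeric(config$h2)
  rho <- config$rho_g
  subtypes <- c("CAD", "IS", "HF")
  with_seed(seed, {
    sigma <- diag(sqrt(h2)) %*% rho %*% diag(sqrt(h2)) / m
    b <- rmvnorm0(m, sigma)
    for (k in 1:3) {
      ss <- sum(b[, k]^2)
      b[, k] <- if (h2[k] > 0 && ss > 0) b[, k] * sqrt(h2[k] / ss) else 0
    }
    dimnames(b) <- list(variants$variant_id, subtypes)

    sd_dos <- sqrt(2 * variants$eaf * (1 - variants$eaf))
    sumstats <- lapply(seq_len(3L), function(k) {
      se <- sqrt(1 / (as.numeric(config$gwas_n[k]) * sd_dos^2))
      beta_true_allele <- b[, k] / sd_dos
      beta_hat <- beta_true_allele + stats::rnorm(m, 0, se)
      data.frame(
        variant_id = variants$variant_id,
        chrom = variants$chrom,
        pos = variants$pos,
        effect_allele = variants$alt,
        other_allele = variants$ref,
        eaf = variants$eaf,
        beta = beta_hat,
        se = se,
        p = 2 * stats::pnorm(-abs(beta_hat / se)),
        stringsAsFactors = FALSE
      )
    })
    names(sumstats) <- subtypes
    list(true_effects = b, sumstats = sumstats)
  })
}

# True genetic scores (n x 3) on the standardized-dosage scale.
true_genetic_scores <- function(dosages, true_effects, variants) {
  p <- variants$eaf
  sd_dos <- sqrt(2 * p * (1 - p))
  # (D - 2p)/sd %*% b  ==  D %*% (b/sd) - const
  w <- true_effects / sd_dos
  raw <- dosages %*% w
  sweep(raw, 2, colSums(2 * p * w), "-")
}

#' Simulate the T2D cohort: episodes, deaths and covariates
#'
#' Every simulated person is a T2D patient. Onset age is normal (truncated
#' to 30-80 years); the calendar onset date is the birth date (uniform over
#' a 1937-1966 birth cohort) plus the onset age, clamped to the configured
#' coverage window, so that earlier-onset patients accrue longer follow-up
#' as they do in an enrolled cohort with registry linkage. After T2D onset, each CVD subtype's event time is exponential
#' with log-hazard `log(baseline) + beta_gk * G_k + clinical effects`,
#' where `G_k` is the standardized true genetic score of subtype k and the
#' clinical linear predictor is centered at its cohort mean so that
#' `baseline_hazard_rate` is the per-subtype hazard for an average person.
#' `hazard_betas$genetic_early` adds to the genetic log-HR for people with
#' onset age at or below `interaction_age`, creating a genuine
#' PRS-by-onset-age interaction when nonzero. Deaths are independent
#' exponential; episodes occurring after a person's death are not emitted.
#'
#' A configurable fraction of subtype diagnoses is withheld from the coded
#' episodes and recorded in a separate self-report table (interview-only
#' history), and a small fraction of people receives a CVD code on or
#' before T2D onset (prevalent disease) to exercise downstream exclusion.
#'
#' @param config A [sim_config()].
#' @param genotypes Dosage matrix from [simulate_genotypes()] (complete,
#'   pre-missingness).
#' @param true_effects m x 3 effect matrix from
#'   [simulate_effects_and_sumstats()].
#' @param variants Variant table (for allele frequencies).
#' @param seed Seed for this step.
#' @return List with `episodes` (person_id, system, code, date), `deaths`
#'   (person_id, date), `covariates` (one row per person), `self_report`
#'   (person_id, disease), and `true_scores` (n x 3 standardized genetic
#'   scores used in the hazard).
#' @export
simulate_cohort <- function(config, genotypes, true_effects, variants,
                            seed = config$seed) {
  validate_sim_config(config)
  n <- nrow(genotypes)
  subtypes <- c("CAD", "IS", "HF")
  for (d in c("T2D", subtypes)) {
    if (!any(config$code_maps$disease == d)) {
      stop(sprintf("no codes configured for disease '%s'", d), call. = FALSE)
    }
  }
  g_raw <- true_genetic_scores(genotypes, true_effects, variants)
  g <- apply(g_raw, 2, function(x) {
    s <- stats::sd(x)
    if (s > 0) (x - mean(x)) / s else rep(0, length(x))
  })

  with_seed(seed, {
    ids <- rownames(genotypes)
    mu <- config$t2d_onset_mean_sd[1]
    sdv <- config$t2d_onset_mean_sd[2]
    age <- stats::rnorm(n, mu, sdv)
    while (any(bad <- age < 30 | age > 80)) {
      age[bad] <- stats::rnorm(sum(bad), mu, sdv)
    }
    # calendar onset follows from birth cohort + onset age (so earlier-onset
    # patients accrue longer follow-up, as in an enrolled cohort), clamped to
    # the coverage window: onsets predating record coverage surface at the
    # coverage start, the way first-coded episodes do in registry data
    birth <- as.Date("1937-01-01") +
      floor(stats::runif(n) * as.numeric(as.Date("1966-12-31") -
                                           as.Date("1937-01-01")))
    t2d_date <- birth + round(age * 365.25)
    t2d_date <- pmin(pmax(t2d_date, config$onset_date_range[1]),
                     config$onset_date_range[2])

    covars <- data.frame(
      person_id = ids,
      sex = stats::rbinom(n, 1L, 0.60),
      age_t2d_onset = age,
      bmi = stats::rnorm(n, 30, 4.5),
      smoking = stats::rbinom(n, 1L, 0.57),
      hypertension = stats::rbinom(n, 1L, 0.80),
      tc = stats::rnorm(n, 5.93, 1.28),
      ldl = stats::rnorm(n, 3.93, 0.83),
      hdl = stats::rnorm(n, 1.21, 0.33),
      tg = stats::rnorm(n, 2.25, 1.27),
      lipid_med = stats::rbinom(n, 1L, 0.54),
      glucose = stats::rnorm(n, 6.64, 2.95),
      stringsAsFactors = FALSE
    )
    for (k in 1:10) covars[[paste0("PC", k)]] <- stats::rnorm(n)

    hb <- config$hazard_betas
    bg <- rep(as.numeric(hb$genetic), length.out = 3L)
    b_early <- hb$genetic_early %||% 0
    clin_beta <- hb$clinical
    clin_lp <- rep(0, n)
    for (nm in names(clin_beta)) {
      if (!nm %in% names(covars)) {
        stop(sprintf("hazard_betas$clinical names unknown covariate '%s'", nm),
             call. = FALSE)
      }
      clin_lp <- clin_lp + clin_beta[[nm]] * covars[[nm]]
    }
    clin_lp <- clin_lp - mean(clin_lp)
    early <- as.numeric(age <= config$interaction_age)

    # subtype event times (years after T2D onset)
    t_sub <- matrix(Inf, n, 3L, dimnames = list(ids, subtypes))
    if (config$baseline_hazard_rate > 0) {
      for (k in 1:3) {
        rate <- config$baseline_hazard_rate *
          exp((bg[k] + b_early * early) * g[, k] + clin_lp)
        t_sub[, k] <- stats::rexp(n) / rate
      }
    }
    t_death <- if (config$death_rate > 0) {
      stats::rexp(n) / config$death_rate
    } else {
      rep(Inf, n)
    }

    ep_person <- character(0); ep_disease <- character(0); ep_date <- as.Date(character(0))
    sr_person <- character(0); sr_disease <- character(0)

    # T2D onset episodes for everybody
    ep_person <- c(ep_person, ids)
    ep_disease <- c(ep_disease, rep("T2D", n))
    ep_date <- c(ep_date, t2d_date)

    for (k in 1:3) {
      has <- which(is.finite(t_sub[, k]) & t_sub[, k] < t_death)
      if (!length(has)) next
      days <- pmax(1, ceiling(t_sub[has, k] * 365.25))
      dt <- t2d_date[has] + days
      self_only <- stats::runif(length(has)) < config$selfreport_frac
      keep <- has[!self_only]
      if (length(keep)) {
        ep_person <- c(ep_person, ids[keep])
        ep_disease <- c(ep_disease, rep(subtypes[k], length(keep)))
        ep_date <- c(ep_date, dt[!self_only])
      }
      if (any(self_only)) {
        sr_person <- c(sr_person, ids[has[self_only]])
        sr_disease <- c(sr_disease, rep(subtypes[k], sum(self_only)))
      }
    }

    # prevalent CVD: a coded subtype episode on or before the T2D onset
    if (config$prevalent_cvd_frac > 0) {
      n_prev <- floor(config$prevalent_cvd_frac * n)
      if (n_prev > 0) {
        who <- sample.int(n, n_prev)
        dis <- sample(subtypes, n_prev, replace = TRUE)
        ep_person <- c(ep_person, ids[who])
        ep_disease <- c(ep_disease, dis)
        ep_date <- c(ep_date, t2d_date[who] - sample(0:1825, n_prev, replace = TRUE))
      }
    }

    # sample a concrete code (with a dot suffix) for each episode
    cm <- config$code_maps
    sys_out <- character(length(ep_person))
    code_out <- character(length(ep_person))
    for (d in unique(ep_disease)) {
      rows <- cm[cm$disease == d, , drop = FALSE]
      idx <- which(ep_disease == d)
      pick <- sample.int(nrow(rows), length(idx), replace = TRUE)
      sys_out[idx] <- rows$system[pick]
      code_out[idx] <- sprintf("%s.%d", rows$prefix[pick],
                               sample(0:9, length(idx), replace = TRUE))
    }
    episodes <- data.frame(
      person_id = ep_person,
      system = sys_out,
      code = code_out,
      date = ep_date,
      stringsAsFactors = FALSE
    )
    episodes$date <- pmax(episodes$date, config$study_start)
    episodes <- episodes[order(episodes$person_id, episodes$date), ]
    rownames(episodes) <- NULL

    death_date <- t2d_date + pmax(1, ceiling(t_death * 365.25))
    died <- is.finite(t_death) & death_date <= config$censor_date
    deaths <- data.frame(
      person_id = ids[died],
      date = death_date[died],
      stringsAsFactors = FALSE
    )

    self_report <- data.frame(person_id = sr_person, disease = sr_disease,
                              stringsAsFactors = FALSE)

    list(episodes = episodes, deaths = deaths, covariates = covars,
         self_report = self_report, true_scores = g)
  })
}

#' Simulate a complete synthetic study bundle
#'
#' Chains [simulate_genotypes()], [simulate_effects_and_sumstats()] and
#' [simulate_cohort()] under seeds derived from `config$seed`, applies the
#' configured completely-at-random genotype missingness after true genetic
#' scores are computed, and returns everything the downstream analysis
#' needs as a `study_bundle`.
#'
#' @param config A [sim_config()].
#' @return A `study_bundle`: list with `config`, `genotypes`, `variants`,
#'   `true_effects`, `sumstats`, `episodes`, `deaths`, `covariates`,
#'   `self_report`, `true_scores`.
#' @export
simulate_study <- function(config = sim_config()) {
  validate_sim_config(config)
  geno <- simulate_genotypes(config, seed = config$seed)
  eff <- simulate_effects_and_sumstats(config, geno$variants,
                                       seed = config$seed + 1L)
  coh <- simulate_cohort(config, geno$dosages, eff$true_effects,
                         geno$variants, seed = config$seed + 2L)
  dos <- geno$dosages
  if (config$missing_rate > 0) {
    dos <- with_seed(config$seed + 3L, {
      mask <- stats::runif(length(dos)) < config$missing_rate
      dos[mask] <- NA_integer_
      dos
    })
  }
  structure(
    list(config = config,
         genotypes = dos,
         variants = geno$variants,
         true_effects = eff$true_effects,
         sumstats = eff$sumstats,
         episodes = coh$episodes,
         deaths = coh$deaths,
         covariates = coh$covariates,
         self_report = coh$self_report,
         true_scores = coh$true_scores),
    class = "study_bundle"
  )
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("Synthetic study bundle\n")
  cat(sprintf("  %d people x %d variants; %d episodes, %d deaths\n",
              nrow(x$genotypes), ncol(x$genotypes),
              nrow(x$episodes), nrow(x$deaths)))
  cat(sprintf("  self-report-only diagnoses: %d\n", nrow(x$self_report)))
  invisible(x)
}

#' Write a study bundle to plain-text files
#'
#' Genotypes, variants, summary statistics and covariates as tab-separated
#' text; episodes, deaths and self-reports as CSV; the generating
#' configuration as a YAML manifest.
#'
#' @param bundle A `study_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  geno <- data.frame(person_id = rownames(bundle$genotypes),
                     bundle$genotypes, check.names = FALSE)
  wtsv(geno, "genotypes.tsv")
  wtsv(bundle$variants, "variants.tsv")
  for (k in names(bundle$sumstats)) {
    wtsv(bundle$sumstats[[k]], sprintf("sumstats_%s.tsv", k))
  }
  wtsv(data.frame(variant_id = rownames(bundle$true_effects),
                  bundle$true_effects), "true_effects.tsv")
  wtsv(bundle$covariates, "covariates.tsv")
  utils::write.csv(bundle$episodes, file.path(dir, "episodes.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$deaths, file.path(dir, "deaths.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$self_report, file.path(dir, "self_report.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- bundle$config
  manifest <- list(
    n_individuals = cfg$n_individuals,
    n_variants = cfg$n_variants,
    maf_range = cfg$maf_range,
    h2 = as.numeric(cfg$h2),
    rho_g = apply(cfg$rho_g, 1, as.numeric, simplify = FALSE),
    gwas_n = as.numeric(cfg$gwas_n),
    t2d_onset_mean_sd = cfg$t2d_onset_mean_sd,
    onset_date_range = format(cfg$onset_date_range),
    hazard_betas = list(genetic = as.numeric(cfg$hazard_betas$genetic),
                        genetic_early = cfg$hazard_betas$genetic_early,
                        clinical = as.list(cfg$hazard_betas$clinical)),
    interaction_age = cfg$interaction_age,
    baseline_hazard_rate = cfg$baseline_hazard_rate,
    death_rate = cfg$death_rate,
    censor_date = format(cfg$censor_date),
    study_start = format(cfg$study_start),
    missing_rate = cfg$missing_rate,
    ld_block_size = cfg$ld_block_size,
    ld_block_r = cfg$ld_block_r,
    selfreport_frac = cfg$selfreport_frac,
    prevalent_cvd_frac = cfg$prevalent_cvd_frac,
    seed = cfg$seed
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
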