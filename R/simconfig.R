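#' Simulation configuration for a synthetic CVD-in-T2D study
#'
#' Bundles every parameter of the synthetic study generator: genotype panel
#' size and allele-frequency range, the liability-scale genetic architecture
#' of the three CVD subtypes (coronary artery disease, ischemic stroke,
#' heart failure), the GWAS noise model, the type-2-diabetes onset
#' distribution, the proportional-hazards model that produces CVD events
#' after T2D onset, and the coded-episode emission rules.
#'
#' @param n_individuals Number of simulated people (default 21092, the size
#'   of a realistic biobank T2D cohort).
#' @param n_variants Number of independent biallelic variants.
#' @param maf_range Length-2 numeric in (0, 0.5]; effect-allele frequencies
#'   are drawn uniformly from this interval.
#' @param h2 Length-3 vector of liability-scale heritabilities captured by
#'   the simulated panel, one per subtype (CAD, IS, HF), each in [0, 1).
#' @param rho_g 3x3 genetic-correlation matrix across subtypes (symmetric,
#'   positive semi-definite, unit diagonal).
#' @param gwas_n Length-3 effective sample sizes of the subtype GWAS; the
#'   sampling variance of an observed per-allele effect is
#'   1 / (gwas_n * 2 * EAF * (1 - EAF)).
#' @param t2d_onset_mean_sd Length-2: mean and SD (years) of the normal
#'   distribution of T2D onset age, truncated to [30, 80].
#' @param onset_date_range Length-2 dates bounding the T2D calendar onset
#'   window (birth-cohort-derived onsets are clamped into it).
#' @param hazard_betas List with elements `genetic` (length-3 log hazard
#'   ratio per SD of the true subtype genetic score), `genetic_early`
#'   (additional genetic log-HR applied when T2D onset age is at or below
#'   `interaction_age`; models a PRS-by-onset-age interaction) and
#'   `clinical` (named log-HRs per covariate unit).
#' @param interaction_age Onset-age cutoff (years) for `genetic_early`.
#' @param baseline_hazard_rate Per-subtype baseline CVD hazard
#'   (events per person-year) after T2D onset.
#' @param death_rate Hazard of death from other causes (per person-year).
#' @param censor_date Administrative censoring date (ISO-8601).
#' @param study_start Earliest possible episode date (hospital-records
#'   coverage start).
#' @param code_maps Data frame with columns `disease`, `system`, `prefix`
#'   mapping each simulated disease to the diagnosis/procedure codes it may
#'   be recorded under; see [default_code_definitions()].
#' @param missing_rate Completely-at-random missing-dosage rate in [0, 1).
#' @param ld_block_size Integer B; variants are generated in blocks of B
#'   loci sharing a latent haplotype indicator (B = 1 means independence).
#' @param ld_block_r Target pairwise dosage correlation within a block.
#' @param selfreport_frac Fraction of true subtype cases whose diagnosis is
#'   withheld from the coded episodes and recorded as self-report only
#'   (emulates interview-only disease history used for stage-1 training).
#' @param prevalent_cvd_frac Fraction of people given a CVD episode on or
#'   before their T2D onset, exercising the prevalent-case exclusion rule.
#' @param seed Integer seed; the whole study bundle is a deterministic
#'   function of the configuration including this seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 21092L,
                       n_variants = 2000L,
                       maf_range = c(0.01, 0.5),
                       h2 = c(CAD = 0.50, IS = 0.25, HF = 0.30),
                       rho_g = default_rho_g(),
                       gwas_n = c(CAD = 550000, IS = 520000, HF = 977000),
                       t2d_onset_mean_sd = c(61.7, 7),
                       onset_date_range = as.Date(c("1996-01-01", "2018-12-31")),
                       hazard_betas = default_hazard_betas(),
                       interaction_age = 55,
                       baseline_hazard_rate = 0.0105,
                       death_rate = 0.012,
                       censor_date = as.Date("2021-02-05"),
                       study_start = as.Date("1994-04-01"),
                       code_maps = default_code_definitions(),
                       missing_rate = 0,
                       ld_block_size = 1L,
                       ld_block_r = 0,
                       selfreport_frac = 0.2,
                       prevalent_cvd_frac = 0.02,
                       seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants),
    maf_range = as.numeric(maf_range),
    h2 = h2,
    rho_g = rho_g,
    gwas_n = gwas_n,
    t2d_onset_mean_sd = as.numeric(t2d_onset_mean_sd),
    onset_date_range = as_date_strict(onset_date_range, "onset_date_range"),
    hazard_betas = hazard_betas,
    interaction_age = interaction_age,
    baseline_hazard_rate = baseline_hazard_rate,
    death_rate = death_rate,
    censor_date = as_date_strict(censor_date, "censor_date"),
    study_start = as_date_strict(study_start, "study_start"),
    code_maps = code_maps,
    missing_rate = missing_rate,
    ld_block_size = as.integer(ld_block_size),
    ld_block_r = ld_block_r,
    selfreport_frac = selfreport_frac,
    prevalent_cvd_frac = prevalent_cvd_frac,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_individuals < 2L) stop("n_individuals must be >= 2", call. = FALSE)
  if (cfg$n_variants < 1L) stop("n_variants must be >= 1", call. = FALSE)
  mr <- cfg$maf_range
  if (length(mr) != 2L || any(!is.finite(mr)) || mr[1] > mr[2] ||
      mr[1] <= 0 || mr[2] > 0.5) {
    stop("maf_range must lie within (0, 0.5] with min <= max", call. = FALSE)
  }
  if (length(cfg$h2) != 3L || any(cfg$h2 < 0) || any(cfg$h2 >= 1)) {
    stop("h2 must be three values in [0, 1)", call. = FALSE)
  }
  if (!is_psd_corr(cfg$rho_g)) {
    stop("rho_g must be a symmetric positive semi-definite correlation matrix",
         call. = FALSE)
  }
  if (length(cfg$gwas_n) != 3L || any(cfg$gwas_n <= 0)) {
    stop("gwas_n must be three positive sample sizes", call. = FALSE)
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  if (cfg$ld_block_size < 1L) stop("ld_block_size must be >= 1", call. = FALSE)
  if (cfg$ld_block_r < 0 || cfg$ld_block_r > 1) {
    stop("ld_block_r must be in [0, 1]", call. = FALSE)
  }
  hb <- cfg$hazard_betas
  if (!is.list(hb) || is.null(hb$genetic) || is.null(hb$clinical)) {
    stop("hazard_betas must list `genetic` and `clinical` effects", call. = FALSE)
  }
  if (length(hb$genetic) == 1L) hb$genetic <- rep(hb$genetic, 3L)
  if (length(hb$genetic) != 3L) {
    stop("hazard_betas$genetic must have length 1 or 3", call. = FALSE)
  }
  cm <- cfg$code_maps
  if (!is.data.frame(cm) ||
      !all(c("disease", "system", "prefix") %in% names(cm))) {
    stop("code_maps must be a data frame with disease/system/prefix columns",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Default genetic-correlation matrix across CVD subtypes
#'
#' Moderate-to-strong positive genetic correlations between coronary artery
#' disease, ischemic stroke and heart failure, as reported by multi-trait
#' GWAS of cardiovascular outcomes.
#' @return 3x3 correlation matrix with dimnames CAD/IS/HF.
#' @export
default_rho_g <- function() {
  m <- matrix(c(1, 0.5, 0.6,
                0.5, 1, 0.5,
                0.6, 0.5, 1), 3, 3,
              dimnames = list(c("CAD", "IS", "HF"), c("CAD", "IS", "HF")))
  m
}

#' Default log hazard ratios used by the cohort simulator
#'
#' Genetic effect of log(1.3) per SD of each subtype's true genetic score,
#' an extra early-onset genetic effect of log(1.51/1.23) (matching the
#' observed contrast between hazard ratios below and above 55 years of
#' onset in diabetic cohorts), and clinical effects in the range reported
#' for diabetic cohorts (age, male sex, BMI, smoking, hypertension,
#' glucose, lipid-lowering medication).
#' @return List with `genetic`, `genetic_early` and `clinical` components.
#' @export
default_hazard_betas <- function() {
  list(
    genetic = c(CAD = log(1.3), IS = log(1.3), HF = log(1.3)),
    genetic_early = log(1.51 / 1.23),
    clinical = c(age_t2d_onset = log(1.04),
                 sex = log(1.53),
                 bmi = log(1.02),
                 smoking = log(1.27),
                 hypertension = log(1.37),
                 glucose = log(1.03),
                 lipid_med = log(1.24))
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  individuals: %d, variants: %d (LD blocks of %d, r = %.2f)\n",
              x$n_individuals, x$n_variants, x$ld_block_size, x$ld_block_r))
  cat(sprintf("  h2 (CAD, IS, HF): %s\n", paste(x$h2, collapse = ", ")))
  cat(sprintf("  genetic HR/SD: %s\n",
              paste(sprintf("%.3f", exp(x$hazard_betas$genetic)), collapse = ", ")))
  cat(sprintf("  baseline hazard: %g /person-year, censor %s, seed %d\n",
              x$baseline_hazard_rate, format(x$censor_date), x$seed))
  invisible(x)
}
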