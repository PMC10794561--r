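#' Construct a PRS weight set
#'
#' @param variant_id Character vector of unique variant ids.
#' @param effect_allele Allele the weight counts.
#' @param weight Per-allele (log-scale) effect sizes; must be finite.
#' @param other_allele Optional non-effect allele (enables strand checks).
#' @param label Name of the weight set, conventionally `method x subtype`.
#' @return Data frame of class `weight_set`.
#' @export
weight_set <- function(variant_id, effect_allele, weight,
                       other_allele = NA_character_, label = "weights") {
  if (anyDuplicated(variant_id)) {
    stop("duplicate variant ids in weight set", call. = FALSE)
  }
  if (any(!is.finite(weight))) stop("non-finite weights", call. = FALSE)
  w <- data.frame(variant_id = as.character(variant_id),
                  effect_allele = toupper(as.character(effect_allele)),
                  other_allele = toupper(rep_len(as.character(other_allele),
                                                 length(variant_id))),
                  weight = as.numeric(weight),
                  stringsAsFactors = FALSE)
  attr(w, "label") <- label
  class(w) <- c("weight_set", "data.frame")
  w
}

#' Read a weight file (TSV: variant_id, effect_allele, other_allele, weight)
#' @param path File path.
#' @param label Weight-set label (defaults to the file name).
#' @return A `weight_set`.
#' @export
read_weight_set <- function(path, label = basename(path)) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("variant_id", "effect_allele", "weight") %in% names(d)))
  weight_set(d$variant_id, d$effect_allele, d$weight,
             other_allele = d$other_allele %||% NA_character_, label = label)
}

#' Harmonize a weight set to the genotype allele convention
#'
#' Matches weights to the variant table by id. If the weight's effect
#' allele equals the counted (dosage) allele the weight is kept; if it
#' equals the other allele the weight is negated (the constant offset this
#' introduces is immaterial after standardization). Strand flips are
#' resolved by complementing; strand-ambiguous A/T and C/G variants and
#' unmatched or allele-mismatched entries are dropped. Nothing is fatal;
#' all categories are counted in the attached report.
#'
#' @param weights A `weight_set`.
#' @param variants Variant table with `variant_id`, `ref`, `alt` (counted
#'   allele = `alt`).
#' @return Harmonized `weight_set` (effect allele = counted allele for all
#'   retained rows) with a `harmony` attribute counting kept / negated /
#'   strand-flipped / ambiguous / unmatched / mismatched variants.
#' @export
harmonize <- function(weights, variants) {
  stopifnot(inherits(weights, "weight_set"))
  idx <- match(weights$variant_id, variants$variant_id)
  counted <- toupper(variants$alt[idx])
  other <- toupper(variants$ref[idx])

  ea <- weights$effect_allele
  unmatched <- is.na(idx)
  ambiguous <- !unmatched & (counted == allele_complement(other))

  nafalse <- function(x) { x[is.na(x)] <- FALSE; x }
  keep_as_is <- nafalse(ea == counted)
  negate <- nafalse(ea == other)
  flip_keep <- nafalse(allele_complement(ea) == counted)
  flip_negate <- nafalse(allele_complement(ea) == other)
  # direct match takes precedence over a strand interpretation
  flip_keep[keep_as_is | negate] <- FALSE
  flip_negate[keep_as_is | negate] <- FALSE

  usable <- !unmatched & !ambiguous &
    (keep_as_is | negate | flip_keep | flip_negate)
  mismatched <- !unmatched & !ambiguous & !usable

  w <- weights$weight
  w[negate | flip_negate] <- -w[negate | flip_negate]

  out <- weight_set(weights$variant_id[usable],
                    counted[usable],
                    w[usable],
                    other_allele = other[usable],
                    label = attr(weights, "label"))
  attr(out, "harmony") <- c(
    kept = sum(keep_as_is & usable),
    negated = sum(negate & usable),
    strand_flipped = sum((flip_keep | flip_negate) & usable),
    ambiguous = sum(ambiguous, na.rm = TRUE),
    unmatched = sum(unmatched),
    mismatched = sum(mismatched)
  )
  out
}

#' Compute polygenic scores
#'
#' `score_i = sum_j weight_j * dosage_ij` over the harmonized weights.
#' Missing dosages are imputed as twice the study effect-allele frequency
#' (computed from the genotypes themselves), or the person is dropped in
#' strict mode.
#'
#' @param genotypes n x m dosage matrix (people in rows, variant ids as
#'   column names, values in [0, 2] or NA).
#' @param weights Harmonized `weight_set` whose effect allele is the
#'   counted allele of `genotypes`.
#' @param impute_missing Either "mean" (default) or "drop".
#' @return A `prs_vector`: numeric scores named by person id, with
#'   attributes `label`, `n_variants_used`, `n_dropped`.
#' @export
score <- function(genotypes, weights, impute_missing = c("mean", "drop")) {
  impute_missing <- match.arg(impute_missing)
  stopifnot(inherits(weights, "weight_set"))
  use <- weights$variant_id %in% colnames(genotypes)
  n_dropped <- sum(!use)
  w <- weights[use, , drop = FALSE]
  if (nrow(w) == 0) stop("empty score: no weight overlaps the genotypes",
                         call. = FALSE)
  g <- genotypes[, w$variant_id, drop = FALSE]
  storage.mode(g) <- "double"
  if (anyNA(g)) {
    if (impute_missing == "mean") {
      eaf2 <- colMeans(g, na.rm = TRUE) # = 2 * EAF
      na_idx <- which(is.na(g), arr.ind = TRUE)
      g[na_idx] <- eaf2[na_idx[, 2]]
    } else {
      drop_person <- rowSums(is.na(g)) > 0
      g <- g[!drop_person, , drop = FALSE]
      if (nrow(g) == 0) stop("all persons dropped (missing dosages)",
                             call. = FALSE)
    }
  }
  s <- drop(g %*% w$weight)
  names(s) <- rownames(g)
  structure(s, class = "prs_vector",
            label = attr(weights, "label"),
            n_variants_used = nrow(w),
            n_dropped = n_dropped)
}

#' Standardize a PRS to zero mean and unit SD
#'
#' @param prs A `prs_vector` (or plain numeric).
#' @return Standardized `prs_vector` with attributes `center` and `scale`.
#' @export
standardize_prs <- function(prs) {
  m <- mean(prs)
  s <- stats::sd(prs)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize: score standard deviation is 0", call. = FALSE)
  }
  structure((unclass(prs) - m) / s, class = "prs_vector",
            label = attr(prs, "label"),
            n_variants_used = attr(prs, "n_variants_used"),
            n_dropped = attr(prs, "n_dropped"),
            center = m, scale = s)
}

#' @export
print.prs_vector <- function(x, ...) {
  cat(sprintf("PRS '%s': %d people, %s variants used (%s dropped)\n",
              attr(x, "label") %||% "?", length(x),
              attr(x, "n_variants_used") %||% "?",
              attr(x, "n_dropped") %||% "?"))
  print(utils::head(unclass(x)))
  invisible(x)
}

#' Clumping-and-thresholding candidate weights (P+T)
#'
#' Greedy selection by ascending GWAS p-value: a variant is retained if its
#' p-value is at or below `p_max` and its squared dosage correlation with
#' every already-retained variant within `window_kb` on the same chromosome
#' is at or below `r2_max`. Weights of retained variants are their GWAS
#' betas. Ties in p are broken by (chrom, pos) so the result does not
#' depend on input row order.
#'
#' @param sumstats Data frame with `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `p`.
#' @param genotypes Dosage matrix supplying the correlation structure
#'   (the study's own genotypes serve as the LD source).
#' @param p_max P-value threshold.
#' @param r2_max Squared-correlation threshold.
#' @param window_kb Window in kilobases within which LD is checked.
#' @param label Label for the returned `weight_set`.
#' @return `weight_set` of the retained variants (possibly empty, with a
#'   warning).
#' @export
clump_threshold <- function(sumstats, genotypes, p_max = 5e-8, r2_max = 0.1,
                            window_kb = 250,
                            label = sprintf("P+T(p<=%g,r2<=%g)", p_max, r2_max)) {
  need <- c("variant_id", "chrom", "pos", "beta", "p")
  stopifnot(all(need %in% names(sumstats)))
  cand <- sumstats[sumstats$p <= p_max, , drop = FALSE]
  cand <- cand[order(cand$p, cand$chrom, cand$pos, cand$variant_id), , drop = FALSE]
  if (nrow(cand) == 0) {
    warning("no variant passes the p-value threshold; empty weight set")
    return(weight_set(character(0), character(0), numeric(0), label = label))
  }
  window <- window_kb * 1000
  kept <- integer(0)
  g_kept <- NULL
  for (i in seq_len(nrow(cand))) {
    vid <- cand$variant_id[i]
    if (!vid %in% colnames(genotypes)) next
    ok <- TRUE
    if (length(kept)) {
      near <- which(cand$chrom[kept] == cand$chrom[i] &
                      abs(cand$pos[kept] - cand$pos[i]) <= window)
      if (length(near)) {
        gi <- as.numeric(genotypes[, vid])
        r <- suppressWarnings(
          stats::cor(gi, genotypes[, cand$variant_id[kept[near]], drop = FALSE],
                     use = "pairwise.complete.obs"))
        r[is.na(r)] <- 0
        if (any(r^2 > r2_max)) ok <- FALSE
      }
    }
    if (ok) kept <- c(kept, i)
  }
  res <- cand[kept, , drop = FALSE]
  weight_set(res$variant_id,
             res$effect_allele %||% rep(NA_character_, nrow(res)),
             res$beta,
             other_allele = res$other_allele %||% NA_character_,
             label = label)
}

#' Build a weight set directly from GWAS summary statistics
#'
#' All variants, weights equal to the observed GWAS betas. Useful as an
#' externally produced candidate (e.g. alongside P+T) when variants are
#' independent.
#'
#' @param sumstats Summary-statistics data frame.
#' @param label Weight-set label.
#' @return A `weight_set`.
#' @export
sumstats_weights <- function(sumstats, label = "gwas-beta") {
  weight_set(sumstats$variant_id, sumstats$effect_allele, sumstats$beta,
             other_allele = sumstats$other_allele %||% NA_character_,
             label = label)
}
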