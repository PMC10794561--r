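toy_variants <- function() {
  data.frame(variant_id = c("v1", "v2", "v3", "v4"),
             chrom = "1", pos = c(1e4, 2e4, 3e4, 4e4),
             ref = c("A", "C", "G", "A"),
             alt = c("G", "T", "A", "T"),   # v4 is A/T: strand-ambiguous
             eaf = c(0.2, 0.3, 0.4, 0.25),
             stringsAsFactors = FALSE)
}

test_that("harmonization keeps, negates, strand-flips and drops correctly", {
  v <- toy_variants()
  w <- weight_set(c("v1", "v2", "v3", "v4", "v9"),
                  effect_allele = c("G", "C", "T", "A", "G"),
                  other_allele = c("A", "T", "C", "T", "A"),
                  weight = c(0.1, 0.2, 0.3, 0.4, 0.5))
  h <- harmonize(w, v)
  rep <- attr(h, "harmony")
  # v1: effect allele is the counted allele -> kept as is
  expect_equal(h$weight[h$variant_id == "v1"], 0.1)
  # v2: effect allele is the other allele -> negated
  expect_equal(h$weight[h$variant_id == "v2"], -0.2)
  # v3: T/C on the opposite strand of A/G -> strand flip, T ~ A (counted)
  expect_equal(h$weight[h$variant_id == "v3"], 0.3)
  # v4 ambiguous, v9 unmatched -> dropped
  expect_false(any(c("v4", "v9") %in% h$variant_id))
  expect_equal(unname(rep["ambiguous"]), 1)
  expect_equal(unname(rep["unmatched"]), 1)
  expect_equal(nrow(h), 3)
})

test_that("scores are the weighted dosage sums", {
  g <- matrix(c(0, 1, 2), 1, 3,
              dimnames = list("P1", c("v1", "v2", "v3")))
  v <- toy_variants()[1:3, ]
  w <- harmonize(weight_set(c("v1", "v2", "v3"), v$alt, c(0.1, -0.2, 0.3)), v)
  s <- score(g, w)
  expect_equal(unname(s["P1"]), 0 * 0.1 + 1 * -0.2 + 2 * 0.3)
})

test_that("all-zero weights give zero scores and standardization fails", {
  g <- matrix(rbinom(20, 2, 0.4), 10, 2,
              dimnames = list(paste0("P", 1:10), c("v1", "v2")))
  v <- toy_variants()[1:2, ]
  w <- harmonize(weight_set(c("v1", "v2"), v$alt, c(0, 0)), v)
  s <- score(g, w)
  expect_true(all(s == 0))
  expect_error(standardize_prs(s), "standard deviation is 0")
})

test_that("an empty overlap is an error", {
  g <- matrix(0:1, 2, 1, dimnames = list(c("P1", "P2"), "vX"))
  w <- weight_set("v1", "G", 0.5)
  expect_error(score(g, w), "empty score")
})

test_that("scoring with the true effects recovers the true genetic score", {
  cfg <- sim_config(n_individuals = 1000, n_variants = 300, seed = 9)
  b <- simulate_study(cfg)
  # per-allele weights derived from the standardized-scale true effects
  sd_dos <- sqrt(2 * b$variants$eaf * (1 - b$variants$eaf))
  w <- weight_set(b$variants$variant_id, b$variants$alt,
                  b$true_effects[, "CAD"] / sd_dos)
  s <- score(b$genotypes, harmonize(w, b$variants))
  truth <- b$true_scores[names(s), "CAD"]
  expect_gt(cor(s, truth), 0.99)
})

test_that("mean imputation and strict mode handle missing dosages", {
  g <- matrix(c(0, 1, 2, NA, 1, 2), 3, 2,
              dimnames = list(paste0("P", 1:3), c("v1", "v2")))
  v <- toy_variants()[1:2, ]
  w <- harmonize(weight_set(c("v1", "v2"), v$alt, c(1, 1)), v)
  s_mean <- score(g, w, impute_missing = "mean")
  expect_equal(length(s_mean), 3)
  expect_equal(unname(s_mean["P1"]), 0 + mean(c(1, 2)))  # NA -> 2*EAF = 1.5
  s_strict <- score(g, w, impute_missing = "drop")
  expect_equal(names(s_strict), c("P2", "P3"))
})

test_that("score is linear in the weights", {
  cfg <- tiny_config()
  b <- simulate_study(cfg)
  v <- b$variants
  set.seed(1)
  w1 <- weight_set(v$variant_id, v$alt, rnorm(nrow(v)), label = "w1")
  w2 <- weight_set(v$variant_id, v$alt, rnorm(nrow(v)), label = "w2")
  w12 <- weight_set(v$variant_id, v$alt, w1$weight + w2$weight)
  g <- b$genotypes
  s <- score(g, harmonize(w12, v))
  expect_equal(unclass(s),
               unclass(score(g, harmonize(w1, v))) +
                 unclass(score(g, harmonize(w2, v))),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("flipping a counted allele leaves standardized scores unchanged", {
  cfg <- tiny_config()
  b <- simulate_study(cfg)
  v <- b$variants
  set.seed(2)
  w <- weight_set(v$variant_id, v$alt, rnorm(nrow(v)), other_allele = v$ref)
  s1 <- standardize_prs(score(b$genotypes, harmonize(w, v)))
  # flip the genotype convention of variant 5: counted allele becomes ref
  v2 <- v
  v2$ref[5] <- v$alt[5]
  v2$alt[5] <- v$ref[5]
  g2 <- b$genotypes
  g2[, 5] <- 2L - g2[, 5]
  s2 <- standardize_prs(score(g2, harmonize(w, v2)))
  expect_lt(max(abs(unclass(s1) - unclass(s2))), 1e-12)
})

test_that("clumping without LD keeps every variant passing the threshold", {
  cfg <- tiny_config()
  b <- simulate_study(cfg)
  ss <- b$sumstats$CAD
  ws <- clump_threshold(ss, b$genotypes, p_max = 0.05, r2_max = 1,
                        window_kb = 250)
  expect_setequal(ws$variant_id, ss$variant_id[ss$p <= 0.05])
})

test_that("of two perfectly correlated variants the smaller p wins", {
  g <- cbind(v1 = c(0, 1, 2, 1, 0, 2, 1, 1),
             v2 = c(0, 1, 2, 1, 0, 2, 1, 1))
  rownames(g) <- paste0("P", 1:8)
  ss <- data.frame(variant_id = c("v1", "v2"), chrom = "1",
                   pos = c(1000, 2000), effect_allele = "G",
                   other_allele = "A", beta = c(0.5, 0.4),
                   p = c(1e-6, 1e-8))
  ws <- clump_threshold(ss, g, p_max = 1e-4, r2_max = 0.1, window_kb = 250)
  expect_equal(ws$variant_id, "v2")
})

test_that("clumping equals the brute-force greedy oracle on block LD", {
  cfg <- sim_config(n_individuals = 800, n_variants = 60, seed = 31,
                    ld_block_size = 5L, ld_block_r = 0.9,
                    gwas_n = c(2000, 2000, 2000))
  b <- simulate_study(cfg)
  ss <- b$sumstats$CAD
  ws <- clump_threshold(ss, b$genotypes, p_max = 0.05, r2_max = 0.1,
                        window_kb = 250)
  oracle <- brute_clump(ss, b$genotypes, p_max = 0.05, r2_max = 0.1,
                        window_kb = 250)
  expect_equal(sort(ws$variant_id), oracle)
  # result is invariant to input row order
  ss_shuf <- ss[sample(nrow(ss)), ]
  ws2 <- clump_threshold(ss_shuf, b$genotypes, p_max = 0.05, r2_max = 0.1,
                         window_kb = 250)
  expect_equal(ws$variant_id, ws2$variant_id)
  # and always a subset of the p <= p_max set
  expect_true(all(ws$variant_id %in% ss$variant_id[ss$p <= 0.05]))
})

test_that("no variant passing the threshold yields an empty set with warning", {
  cfg <- tiny_config(gwas_n = c(100, 100, 100))
  b <- simulate_study(cfg)
  expect_warning(
    ws <- clump_threshold(b$sumstats$CAD, b$genotypes, p_max = 1e-300),
    "empty weight set")
  expect_equal(nrow(ws), 0)
})
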