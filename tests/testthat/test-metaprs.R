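# small cohort with three correlated component scores driving the hazard
meta_test_data <- function(n = 2000, seed = 5, betas = c(0.3, 0.2, 0.1),
                           rho = 0.5) {
  set.seed(seed)
  sigma <- matrix(rho, 3, 3); diag(sigma) <- 1
  z <- matrix(rnorm(n * 3), n, 3) %*% chol(sigma)
  colnames(z) <- c("CAD", "IS", "HF")
  rate <- 0.01 * exp(drop(z %*% betas))
  tm <- ceiling(rexp(n) / rate * 365.25 / 365.25)
  ev <- as.integer(tm < 3000)
  tm <- pmin(tm, 3000)
  cohort <- data.frame(person_id = sprintf("P%04d", 1:n),
                       follow_up_days = tm, event = ev)
  rownames(z) <- cohort$person_id
  list(cohort = cohort, components = z)
}

test_that("select_best picks the discriminative candidate and honours ties", {
  set.seed(8)
  n <- 1500
  truth <- rnorm(n)
  labels <- rbinom(n, 1, plogis(-1.5 + truth))
  cands <- list(signal = truth + rnorm(n, 0, 0.5), noise = rnorm(n))
  sel <- select_best(cands, labels)
  expect_equal(sel$label, "signal")

  # single candidate returned trivially; identical candidates -> first label
  expect_equal(select_best(list(only = truth), labels)$label, "only")
  sel_tie <- select_best(list(a = truth, b = truth), labels)
  expect_equal(sel_tie$label, "a")
  expect_error(select_best(list(), labels), "no candidate")
})

test_that("stratified folds are balanced, seeded and event-covering", {
  ev <- rbinom(500, 1, 0.15)
  f1 <- make_folds(ev, k = 5, seed = 3)
  f2 <- make_folds(ev, k = 5, seed = 3)
  expect_identical(f1, f2)
  expect_true(all(tabulate(f1, 5) >= floor(500 / 5) - 2))
  for (k in 1:5) expect_gt(sum(ev[f1 == k]), 0)
  expect_false(identical(f1, make_folds(ev, k = 5, seed = 4)))
})

test_that("fit_meta stores per-fold values whose means are the model", {
  d <- meta_test_data()
  m <- fit_meta(d$components, d$cohort, seed = 17)
  expect_equal(m$beta,
               rowMeans(vapply(m$per_fold, `[[`, numeric(3), "beta")))
  expect_equal(m$rho, Reduce(`+`, lapply(m$per_fold, `[[`, "rho")) / 5)
  expect_true(all(abs(m$rho[upper.tri(m$rho)]) <= 1))
  expect_equal(unname(diag(m$rho)), rep(1, 3))
  expect_gt(m$denominator, 0)
  den <- m$beta
  expect_equal(m$denominator,
               sqrt(drop(t(den) %*% m$rho %*% den)), tolerance = 1e-12)
  # determinism: same seed -> same folds and model
  m2 <- fit_meta(d$components, d$cohort, seed = 17)
  expect_identical(m$folds, m2$folds)
  expect_equal(m$beta, m2$beta)
})

test_that("identical components trigger the ridge path and recover the score", {
  d <- meta_test_data(n = 1200, betas = c(0.4, 0, 0))
  comp <- d$components
  comp[, 2] <- comp[, 1]
  comp[, 3] <- comp[, 1]
  w <- capture_warnings(m <- fit_meta(comp, d$cohort, seed = 2))
  expect_true(all(grepl("near-collinear", w)))
  expect_gt(length(w), 0)
  s <- suppressWarnings(apply_meta(m, comp))
  z <- (comp[, 1] - mean(comp[, 1])) / sd(comp[, 1])
  # meta reduces to the common component after standardization
  expect_gt(abs(cor(s, z)), 1 - 1e-10)
  expect_equal(sd(s), 1, tolerance = 0.05)
})

test_that("apply_meta reduces exactly in the closed-form cases", {
  skeleton <- fit_meta(meta_test_data(n = 600, seed = 9)$components,
                       meta_test_data(n = 600, seed = 9)$cohort, seed = 1)
  z <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("CAD", "IS", "HF")))

  m1 <- skeleton
  m1$beta <- c(CAD = 1, IS = 0, HF = 0)
  m1$center <- c(0, 0, 0); m1$scale <- c(1, 1, 1)
  m1$denominator <- sqrt(drop(t(m1$beta) %*% m1$rho %*% m1$beta))
  expect_equal(unname(apply_meta(m1, z)), unname(z[, 1]), tolerance = 1e-12)

  m2 <- skeleton
  m2$beta <- c(CAD = 1, IS = 1, HF = 1)
  m2$rho <- matrix(1, 3, 3)
  m2$center <- c(0, 0, 0); m2$scale <- c(1, 1, 1)
  m2$denominator <- sqrt(drop(t(m2$beta) %*% m2$rho %*% m2$beta))
  zz <- cbind(CAD = z[, 1], IS = z[, 1], HF = z[, 1])
  expect_equal(m2$denominator, 3)
  expect_equal(unname(apply_meta(m2, zz)), unname(z[, 1]), tolerance = 1e-12)
})

test_that("meta variance is 1 when scores follow the model correlation", {
  d <- meta_test_data(n = 3000, seed = 23)
  m <- fit_meta(d$components, d$cohort, seed = 4)
  set.seed(31)
  z <- matrix(rnorm(10000 * 3), 10000, 3) %*% chol(m$rho)
  colnames(z) <- c("CAD", "IS", "HF")
  m0 <- m
  m0$center <- c(0, 0, 0); m0$scale <- c(1, 1, 1)
  s <- apply_meta(m0, z)
  expect_equal(var(s), 1, tolerance = 0.03)
})

test_that("relabeling the subtypes permutes the model but not the scores", {
  d <- meta_test_data(n = 1500, seed = 41, betas = c(0.35, 0.15, 0.05))
  perm <- c(3, 1, 2)
  m <- fit_meta(d$components, d$cohort, seed = 6)
  mp <- fit_meta(d$components[, perm], d$cohort, seed = 6)
  expect_equal(unname(mp$beta), unname(m$beta[perm]), tolerance = 1e-8)
  expect_equal(unname(mp$rho), unname(m$rho[perm, perm]), tolerance = 1e-12)
  s <- apply_meta(m, d$components)
  sp <- apply_meta(mp, d$components[, perm])
  expect_lt(max(abs(s - sp)), 1e-8)
})

test_that("a single causal component dominates the combination", {
  d <- meta_test_data(n = 4000, seed = 51, betas = c(0.5, 0, 0), rho = 0.2)
  m <- fit_meta(d$components, d$cohort, seed = 7)
  expect_gt(m$beta["CAD"], m$beta["IS"])
  expect_gt(m$beta["CAD"], m$beta["HF"])
  s <- apply_meta(m, d$components)
  z1 <- (d$components[, 1] - mean(d$components[, 1])) / sd(d$components[, 1])
  expect_gt(cor(s, z1), 0.9)
})

test_that("missing components drop the person with a warning", {
  d <- meta_test_data(n = 800, seed = 61)
  m <- fit_meta(d$components, d$cohort, seed = 8)
  comp <- d$components
  comp[5, 2] <- NA
  expect_warning(s <- apply_meta(m, comp), "dropping 1")
  expect_equal(length(s), 799)
})

test_that("a fold without events is an error", {
  d <- meta_test_data(n = 40, seed = 71)
  d$cohort$event <- 0
  d$cohort$event[1] <- 1
  expect_error(fit_meta(d$components, d$cohort, seed = 9), "zero events")
})

test_that("meta models serialize to JSON and back", {
  d <- meta_test_data(n = 600, seed = 81)
  m <- fit_meta(d$components, d$cohort, seed = 10)
  path <- tempfile(fileext = ".json")
  write_meta_model(m, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$denominator, m$denominator, tolerance = 1e-12)
  expect_equal(unlist(back$beta), m$beta, tolerance = 1e-12)
  expect_equal(length(back$per_fold), 5)
  unlink(path)
})
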