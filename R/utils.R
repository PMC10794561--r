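# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Draw n rows from a zero-mean multivariate normal with covariance `sigma`.
# Uses an eigendecomposition so that positive *semi*-definite matrices
# (e.g. perfectly correlated traits) are handled exactly: negative
# eigenvalues within numerical noise are clipped to zero.
rmvnorm0 <- function(n, sigma) {
  k <- nrow(sigma)
  eig <- eigen(sigma, symmetric = TRUE)
  vals <- eig$values
  if (any(vals < -1e-8 * max(abs(vals), 1))) {
    stop("covariance matrix is not positive semi-definite", call. = FALSE)
  }
  vals[vals < 1e-12 * max(vals, 0)] <- 0
  z <- matrix(stats::rnorm(n * k), n, k)
  z %*% (t(eig$vectors) * sqrt(vals))
}

is_psd_corr <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) return(FALSE)
  if (max(abs(m - t(m))) > tol) return(FALSE)
  if (max(abs(diag(m) - 1)) > tol) return(FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol)
}

as_date_strict <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  ok <- !is.na(x) & nzchar(as.character(x))
  parsed <- suppressWarnings(as.Date(as.character(x[ok]), format = "%Y-%m-%d"))
  if (anyNA(parsed)) {
    bad <- which(ok)[which(is.na(parsed))]
    stop(sprintf("unparseable %s at row(s) %s", what,
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  out[ok] <- parsed
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# DNA strand complement for allele harmonization
allele_complement <- function(a) {
  chartr("ACGTacgt", "TGCAtgca", a)
}
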