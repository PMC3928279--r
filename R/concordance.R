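#' Mantel-type permutation correlation between two profile matrices
#'
#' Measures agreement between two target-by-rookery origin-profile matrices
#' (e.g. genetic/rookery-size versus drifter/rookery-size estimates). The
#' statistic is the Pearson correlation of the vectorized entries; the null
#' distribution is generated by randomly permuting the rows and the columns
#' of `B`, which preserves both margins' value sets while breaking the
#' pairing. The p-value counts permuted correlations at least as large as
#' the observed one, with the observed configuration included in the null
#' set, so the smallest attainable p is `1 / (n_perm + 1)`.
#'
#' @param A,B numeric matrices of identical shape.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @return a `concordance_test`: list with `r`, `p`, `n_perm`, `seed`.
#' @export
mantel_test <- function(A, B, n_perm = 9999, seed = 1L) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) {
    abort(sprintf("shape mismatch: A is %dx%d, B is %dx%d.",
                  nrow(A), ncol(A), nrow(B), ncol(B)))
  }
  assert_scalar_count(n_perm, "n_perm", min = 1)
  if (var(as.numeric(A)) == 0 || var(as.numeric(B)) == 0) {
    abort("zero variance in a profile matrix.")
  }
  r_obs <- cor(as.numeric(A), as.numeric(B))
  a <- as.numeric(A)
  p <- with_seed(seed, {
    ge <- vapply(seq_len(n_perm), function(i) {
      Bp <- B[sample.int(nrow(B)), sample.int(ncol(B)), drop = FALSE]
      cor(a, as.numeric(Bp)) >= r_obs - 1e-12
    }, logical(1))
    (sum(ge) + 1) / (n_perm + 1)
  })
  structure(list(r = r_obs, p = p, n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "concordance_test")
}

#' @export
print.concordance_test <- function(x, ...) {
  cat(sprintf("# Mantel-type matrix correlation: r = %.3f, p = %.4f (%d permutations)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}

#' @export
tidy.concordance_test <- function(x, ...) {
  tibble::tibble(r = x$r, p = x$p, n_perm = x$n_perm, seed = x$seed)
}

#' Log-log regression between genetic and drifter origin profiles
#'
#' Ordinary least squares of `log(drifter)` on `log(genetic)` over paired
#' origin proportions. Zeros cannot be logged; by default each zero is
#' replaced by half the smallest nonzero value of its own profile
#' (`zeros = "half-min"`), or the pair can be dropped (`zeros = "drop"`).
#'
#' @param genetic,drifter numeric vectors of paired proportions, equal
#'   length.
#' @param zeros zero-handling rule, `"half-min"` (default) or `"drop"`.
#' @return a `profile_regression`: list with `slope`, `intercept`, `r`
#'   (Pearson correlation of the log pairs), `n` usable pairs, the
#'   transformed data, and the underlying `lm` fit.
#' @export
log_profile_regression <- function(genetic, drifter, zeros = c("half-min", "drop")) {
  zeros <- match.arg(zeros)
  if (length(genetic) != length(drifter)) abort("profiles must have equal length.")
  if (any(genetic < 0) || any(drifter < 0)) abort("proportions must be non-negative.")
  x <- genetic; y <- drifter
  if (zeros == "half-min") {
    fill <- function(v) {
      nz <- v[v > 0]
      if (length(nz) == 0) abort("a profile is all zeros.")
      v[v == 0] <- min(nz) / 2
      v
    }
    x <- fill(x); y <- fill(y)
  } else {
    keep <- x > 0 & y > 0
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 3) abort("fewer than 3 usable pairs.")
  lx <- log(x); ly <- log(y)
  fit <- lm(ly ~ lx)
  structure(list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r = cor(lx, ly), n = length(x),
    data = tibble::tibble(log_genetic = lx, log_drifter = ly),
    fit = fit
  ), class = "profile_regression")
}

#' @export
print.profile_regression <- function(x, ...) {
  cat(sprintf("# log-profile regression: slope = %.3f, intercept = %.3f, r = %.3f (n = %d)\n",
              x$slope, x$intercept, x$r, x$n))
  invisible(x)
}

#' @export
tidy.profile_regression <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.profile_regression <- function(x, ...) {
  tibble::tibble(r = x$r, r_squared = x$r^2, n = x$n)
}
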