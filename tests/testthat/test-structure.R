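test_that("identical populations show no differentiation, fixed ones complete fixation", {
  same <- ht(P1 = c(6, 4), P2 = c(6, 4))
  res <- pairwise_fixation(same, n_perm = 199, seed = 1)
  expect_lte(res$index[1, 2], 0)
  expect_equal(res$index_display[1, 2], 0)
  expect_gt(res$p[1, 2], 0.05)
  fixed <- ht(P1 = c(10, 0), P2 = c(0, 10))
  res2 <- pairwise_fixation(fixed, n_perm = 199, seed = 1)
  expect_equal(res2$index[1, 2], 1.0, tolerance = 1e-12)
  expect_lte(res2$p[1, 2], 0.05)
})

test_that("the two-population index matches the explicit pairwise-difference oracle", {
  tab <- ht(P1 = c(7, 3), P2 = c(2, 8))
  res <- pairwise_fixation(tab, n_perm = 99, seed = 7)
  delta <- identity_distance(hap_ids(tab))
  expect_equal(res$index[1, 2], oracle_fixation_2pop(hap_counts(tab), delta),
               tolerance = 1e-10)
  # seeded batch, both identity and molecular distances
  set.seed(21)
  for (i in 1:25) {
    tb <- random_table(2, 4, sample(5:15, 1), seed = 400 + i)
    d <- identity_distance(hap_ids(tb))
    r <- pairwise_fixation(tb, n_perm = 1, seed = i)
    expect_equal(r$index[1, 2], oracle_fixation_2pop(hap_counts(tb), d), tolerance = 1e-10)
    dm <- matrix(runif(16), 4)[seq_len(nrow(tb)), seq_len(nrow(tb)), drop = FALSE]
    dm <- (dm + t(dm)) / 2; diag(dm) <- 0
    dimnames(dm) <- list(hap_ids(tb), hap_ids(tb))
    r2 <- pairwise_fixation(tb, dist = dm, n_perm = 1, seed = i)
    expect_equal(r2$index[1, 2], oracle_fixation_2pop(hap_counts(tb), dm), tolerance = 1e-10)
  }
})

test_that("two-level AMOVA on two populations reproduces the pairwise index", {
  tb <- random_table(2, 5, 12, seed = 55)
  fit <- amova(tb, groups = NULL, n_perm = 99, seed = 2)
  pw <- pairwise_fixation(tb, n_perm = 99, seed = 2)
  expect_equal(fit$phi$value[fit$phi$statistic == "Phi_ST"], pw$index[1, 2], tolerance = 1e-12)
  expect_equal(sum(fit$components$df), sum(sample_sizes(tb)) - 1)
})

test_that("three-level variance components match the enumeration oracle", {
  set.seed(77)
  for (i in 1:5) {
    tb <- random_table(4, 5, 10, seed = 500 + i)
    groups <- setNames(c("g1", "g1", "g2", "g2"), pop_ids(tb))
    dm <- matrix(runif(25), 5); dm <- (dm + t(dm)) / 2; diag(dm) <- 0
    dimnames(dm) <- list(hap_ids(tb), hap_ids(tb))
    fit <- amova(tb, groups = groups, dist = dm, n_perm = 1, seed = i)
    orc <- oracle_amova3(hap_counts(tb), groups, dm)
    expect_equal(fit$components$variance, unname(orc), tolerance = 1e-10)
    expect_equal(sum(fit$components$df), sum(sample_sizes(tb)) - 1)
    # Phi_ST identity over components
    tot <- sum(orc)
    expect_equal(fit$phi$value[3], (orc[["sigma_a"]] + orc[["sigma_b"]]) / tot, tolerance = 1e-10)
  }
})

test_that("saturated two-group structure pins Phi_ST at one", {
  tb <- hap_table(tibble::tibble(haplotype = c("a", "b"),
                                 P1 = c(8L, 0L), P2 = c(8L, 0L),
                                 P3 = c(0L, 8L), P4 = c(0L, 8L)),
                  roles = "feeding")
  groups <- setNames(c("g1", "g1", "g2", "g2"), pop_ids(tb))
  fit <- amova(tb, groups = groups, n_perm = 99, seed = 3)
  expect_equal(fit$phi$value[fit$phi$statistic == "Phi_ST"], 1, tolerance = 1e-12)
  expect_gt(fit$phi$value[fit$phi$statistic == "Phi_CT"], 0.9)
})

test_that("identical compositions give near-zero Phi and non-significant p", {
  tb <- hap_table(tibble::tibble(haplotype = c("a", "b"),
                                 P1 = c(10L, 10L), P2 = c(10L, 10L),
                                 P3 = c(10L, 10L), P4 = c(10L, 10L)),
                  roles = "feeding")
  groups <- setNames(c("g1", "g1", "g2", "g2"), pop_ids(tb))
  fit <- amova(tb, groups = groups, n_perm = 199, seed = 4)
  expect_lt(abs(fit$phi$value[fit$phi$statistic == "Phi_ST"]), 0.1)
  expect_gt(fit$phi$p[fit$phi$statistic == "Phi_ST"], 0.05)
})

test_that("Phi statistics are invariant under uniform distance scaling", {
  tb <- random_table(4, 5, 10, seed = 909)
  groups <- setNames(c("g1", "g1", "g2", "g2"), pop_ids(tb))
  dm <- matrix(runif(25), 5); dm <- (dm + t(dm)) / 2; diag(dm) <- 0
  dimnames(dm) <- list(hap_ids(tb), hap_ids(tb))
  f1 <- amova(tb, groups = groups, dist = dm, n_perm = 1, seed = 5)
  f2 <- amova(tb, groups = groups, dist = 3.7 * dm, n_perm = 1, seed = 5)
  expect_equal(f1$phi$value, f2$phi$value, tolerance = 1e-10)
})

test_that("permutation p-values are stable across seeds", {
  tb <- ht(P1 = c(7, 3, 2), P2 = c(3, 6, 3))
  n_perm <- 999
  ps <- vapply(1:10, function(s) pairwise_fixation(tb, n_perm = n_perm, seed = s)$p[1, 2],
               numeric(1))
  expect_lt(diff(range(ps)), 3 / sqrt(n_perm))
})

test_that("guard rails: tiny populations and bad permutation counts error", {
  expect_error(pairwise_fixation(ht(P1 = c(1, 0), P2 = c(2, 2))), "fewer than 2")
  expect_error(pairwise_fixation(ht(P1 = c(2, 1), P2 = c(2, 2)), n_perm = 0), "n_perm")
})
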