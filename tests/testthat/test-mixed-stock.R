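rook2 <- function() {
  hap_table(tibble::tibble(haplotype = c("A", "B"), R1 = c(20L, 0L), R2 = c(0L, 20L)),
            roles = "rookery")
}
fg_5050 <- function() {
  hap_table(tibble::tibble(haplotype = c("A", "B"), M1 = c(50L, 50L)), roles = "feeding")
}

test_that("orphan haplotypes are excluded and reported; rookery-backed ones kept", {
  feeding <- read_haplotype_table(table1_path())
  # a rookery panel that backs every haplotype except the two orphans
  backed <- setdiff(hap_ids(feeding), c("A76", "A92"))
  rk <- hap_table(tibble::tibble(haplotype = backed, RK = rep(5L, length(backed))),
                  roles = "rookery")
  expect_warning(res <- filter_orphans(feeding, rk), "A76")
  expect_setequal(res$removed, c("A76", "A92"))
  expect_false(any(c("A76", "A92") %in% rownames(res$input$C_M)))
  # the hybrid haplotype is present at the rookery panel and must survive
  expect_true("EixCcBR3" %in% rownames(res$input$C_M))
  expect_equal(sum(res$input$C_M), 157 - 2)
})

test_that("full rookery coverage passes through unchanged", {
  res <- filter_orphans(fg_5050(), rook2())
  expect_length(res$removed, 0)
  expect_equal(sum(res$input$C_M), 100)
})

test_that("a feeding population made entirely of orphans is an error", {
  feeding <- hap_table(tibble::tibble(haplotype = c("X", "Y"), M1 = c(3L, 4L)),
                      roles = "feeding")
  expect_error(filter_orphans(feeding, rook2()), "M1")
})

test_that("input validation catches missing and non-positive sizes", {
  expect_error(msa_input(fg_5050(), rook2(), sizes = c(R1 = 1)), "R2")
  expect_error(msa_input(fg_5050(), rook2(), sizes = c(R1 = 1, R2 = 0)), "positive")
  expect_error(fit_many_to_many(msa_input(fg_5050(), rook2()), chain_length = 50),
               "chain_length")
})

test_that("a single rookery forces unit contributions everywhere", {
  rk <- hap_table(tibble::tibble(haplotype = c("A", "B"), R1 = c(5L, 5L)), roles = "rookery")
  fg <- hap_table(tibble::tibble(haplotype = c("A", "B"), M1 = c(3L, 2L), M2 = c(1L, 4L)),
                  roles = "feeding")
  fit <- fit_many_to_many(msa_input(fg, rk), chain_length = 500, seed = 3, n_chains = 2)
  expect_equal(unname(fit$theta$mean[, 1]), c(1, 1), tolerance = 1e-12)
})

test_that("disjoint rookeries recover the observed mixture regardless of sizes", {
  inp <- msa_input(fg_5050(), rook2(), sizes = c(R1 = 1, R2 = 1))
  fit <- fit_many_to_many(inp, chain_length = 4000, seed = 5)
  expect_lt(max(abs(fit$theta$mean["M1", ] - 0.5)), 0.05)
  # size covariate shifts rookery-centric phi, not the data-dominated theta
  inp9 <- msa_input(fg_5050(), rook2(), sizes = c(R1 = 9, R2 = 1))
  fit9 <- fit_many_to_many(inp9, chain_length = 4000, seed = 5)
  expect_lt(max(abs(fit9$theta$mean["M1", ] - 0.5)), 0.05)
  expect_gt(fit9$phi$mean["R2", "M1"], fit9$phi$mean["R1", "M1"] + 0.2)
})

test_that("every stored simplex sums to one at every draw", {
  inp <- msa_input(fg_5050(), rook2(), sizes = c(R1 = 2, R2 = 1))
  fit <- fit_many_to_many(inp, chain_length = 600, seed = 11, save_draws = TRUE)
  for (ch in fit$draws) {
    M <- length(fit$feeding_grounds); R <- length(fit$rookeries)
    th <- array(t(ch$theta), dim = c(M, R, nrow(ch$theta)))
    expect_true(all(abs(apply(th, c(1, 3), sum) - 1) < 1e-9))
    ph <- array(t(ch$phi), dim = c(R, M + 1, nrow(ch$phi)))
    expect_true(all(abs(apply(ph, c(1, 3), sum) - 1) < 1e-9))
  }
})

test_that("permuting rookery order permutes the estimates", {
  rk <- rook2()
  rk_swapped <- hap_table(tibble::tibble(haplotype = c("A", "B"),
                                         R2 = c(0L, 20L), R1 = c(20L, 0L)),
                          roles = "rookery")
  inp1 <- msa_input(fg_5050(), rk, sizes = c(R1 = 3, R2 = 1))
  inp2 <- msa_input(fg_5050(), rk_swapped, sizes = c(R1 = 3, R2 = 1))
  f1 <- fit_many_to_many(inp1, chain_length = 4000, seed = 13)
  f2 <- fit_many_to_many(inp2, chain_length = 4000, seed = 13)
  expect_equal(f1$theta$mean[, c("R1", "R2")], f2$theta$mean[, c("R1", "R2")],
               tolerance = 0.04)
})

test_that("the scale reduction factor behaves at its limits", {
  const <- list(matrix(rep(1, 50), ncol = 1), matrix(rep(1, 50), ncol = 1))
  expect_equal(gelman_rubin(const), 1)
  set.seed(2)
  same <- list(matrix(rnorm(10000), ncol = 1), matrix(rnorm(10000), ncol = 1))
  expect_lt(gelman_rubin(same), 1.05)
  apart <- list(matrix(rnorm(200, 0), ncol = 1), matrix(rnorm(200, 10), ncol = 1))
  expect_gt(gelman_rubin(apart), 1.1)
  expect_error(gelman_rubin(list(matrix(rnorm(100), ncol = 1))), "2 chains")
  expect_error(gelman_rubin(list(matrix(1:5, ncol = 1), matrix(1:5, ncol = 1))), "short")
})

test_that("the scale reduction factor tracks an independent implementation", {
  skip_if_not_installed("coda")
  set.seed(14)
  ch1 <- rnorm(5000); ch2 <- rnorm(5000, 0.05)
  mine <- gelman_rubin(list(matrix(ch1, ncol = 1), matrix(ch2, ncol = 1)))
  ref <- unname(coda::gelman.diag(coda::mcmc.list(coda::mcmc(ch1), coda::mcmc(ch2)),
                                  autoburnin = FALSE, transform = FALSE)$psrf[1, 1])
  expect_equal(mine, ref, tolerance = 0.02)
})
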