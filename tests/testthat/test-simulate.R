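test_that("generators are pure functions of configuration and seed", {
  cfg <- sim_scenario("benchmark", seed = 19)
  a <- gen_rookery_tables(cfg); b <- gen_rookery_tables(cfg)
  expect_identical(hap_counts(a$table), hap_counts(b$table))
  expect_identical(a$freqs, b$freqs)
  expect_identical(hap_counts(gen_feeding_tables(cfg, a$freqs)),
                   hap_counts(gen_feeding_tables(cfg, a$freqs)))
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_sequences(gen_sequences(cfg), f1)
  write_sequences(gen_sequences(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  t1 <- gen_drifter_tracks(cfg); t2 <- gen_drifter_tracks(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("low Dirichlet concentration yields well-separated rookery pools", {
  overlaps <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = s, n_rookeries = 4, n_haplotypes = 10, concentration = 0.1)
    fr <- gen_rookery_tables(cfg)$freqs
    pairs <- utils::combn(ncol(fr), 2)
    mean(vapply(seq_len(ncol(pairs)), function(i) {
      sum(pmin(fr[, pairs[1, i]], fr[, pairs[2, i]]))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(mean(overlaps), 0.3)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(seed = 1, n_haplotypes = 0), "n_haplotypes")
  cfg <- sim_config(seed = 1)
  cfg$rookery_n[1] <- 0
  expect_error(gen_rookery_tables(cfg), "sample size of 0")
  cfg2 <- sim_config(seed = 1)
  expect_error(gen_feeding_tables(cfg2, matrix(0.1, 3, 3)), "expected")
  expect_error(sim_config(seed = 1, arrival = matrix(1.2, 4, 3)), "arrival")
  expect_error(sim_config(seed = 1, mixing = matrix(0.3, 5, 4)), "sum to 1")
})

test_that("feeding-ground haplotype frequencies converge to the mixture expectation", {
  cfg <- sim_config(seed = 23, n_rookeries = 3, n_feeding = 2, n_haplotypes = 8,
                    feeding_n = 10000)
  fr <- gen_rookery_tables(cfg)$freqs
  fg <- gen_feeding_tables(cfg, fr)
  cnt <- matrix(0, cfg$H, cfg$M, dimnames = list(rownames(fr), pop_ids(fg)))
  cnt[hap_ids(fg), ] <- hap_counts(fg)
  for (m in seq_len(cfg$M)) {
    expected <- as.numeric(fr %*% cfg$mixing[m, ])
    observed <- cnt[, m] / sum(cnt[, m])
    se <- sqrt(expected * (1 - expected) / 10000)
    expect_true(all(abs(observed - expected) <= 3 * se + 1e-9))
  }
})

test_that("simulated catalogs are distinct and near the JC limit under equal rates", {
  cfg <- sim_config(seed = 31, n_haplotypes = 6, seq_length = 2000,
                    mut_per_hap = 3, ti_prob = 1 / 3)
  s <- gen_sequences(cfg)
  expect_equal(length(unique(unclass(s))), 6)
  d <- tn93_distance(s)
  ch <- lapply(unclass(s), function(x) strsplit(x, "")[[1]])
  for (i in 1:5) for (j in (i + 1):6) {
    p <- mean(ch[[i]] != ch[[j]])
    expect_lt(abs(d[i, j] - jc_distance(p)), 5e-5)
  }
  expect_error(sim_config(seed = 1, n_haplotypes = 50, seq_length = 10) |> gen_sequences(),
               "distinct")
})

test_that("forced arrivals are always counted and probabilistic ones match binomials", {
  cfg1 <- sim_config(seed = 41, n_rookeries = 2, n_targets = 2, n_release = 20,
                     arrival = matrix(1, 2, 2), lifespan_meanlog = log(120),
                     lifespan_sdlog = 0.1)
  tr1 <- gen_drifter_tracks(cfg1)
  pc1 <- count_passages(tr1, rookery_boxes(cfg1$rookeries), target_boxes(cfg1$targets))
  # every release starts inside its own box, so each rookery's arrivals cover
  # at least its own releases (strays entering a box late may add to n only)
  expect_true(all(pc1$k >= cfg1$n_release))
  expect_true(all(pc1$k <= matrix(pc1$n, 2, 2)))

  a <- 0.3; n_rel <- 400
  cfg2 <- sim_config(seed = 43, n_rookeries = 1, n_targets = 1, n_release = n_rel,
                     arrival = matrix(a, 1, 1), lifespan_meanlog = log(150),
                     lifespan_sdlog = 0.2)
  tr2 <- gen_drifter_tracks(cfg2)
  pc2 <- count_passages(tr2, rookery_boxes(cfg2$rookeries), target_boxes(cfg2$targets))
  expect_equal(unname(pc2$n), n_rel)
  expect_lt(abs(pc2$k[1, 1] / n_rel - a), 3 * sqrt(a * (1 - a) / n_rel))
})

test_that("the lifespan filter removes the lognormal's sub-cutoff fraction", {
  cfg <- sim_config(seed = 47, n_rookeries = 1, n_release = 400,
                    lifespan_meanlog = log(150), lifespan_sdlog = 0.8)
  tr <- gen_drifter_tracks(cfg)
  n_before <- length(unique(tr$id))
  kept <- suppressWarnings(filter_lifespan(tr, 90))
  frac_dropped <- 1 - length(unique(kept$id)) / n_before
  expected <- stats::plnorm(90, log(150), 0.8)
  expect_lt(abs(frac_dropped - expected), 3 * sqrt(expected * (1 - expected) / n_before) + 0.01)
})
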