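# Independent brute-force oracles: everything here works on explicitly
# enumerated individuals and double loops, never through the package's
# count-vector quadratic forms.

# expand a haplotype-by-population count matrix into per-individual
# haplotype indices, one vector per population
expand_individuals <- function(cnt) {
  lapply(seq_len(ncol(cnt)), function(p) rep(seq_len(nrow(cnt)), cnt[, p]))
}

# sum of delta over unordered individual pairs of a single sample
pair_sum <- function(ind, delta) {
  s <- 0
  n <- length(ind)
  if (n < 2) return(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) s <- s + delta[ind[[i]], ind[[j]]]
  s
}

# two-level AMOVA fixation index from explicit pairwise-difference sums
oracle_fixation_2pop <- function(cnt, delta) {
  inds <- expand_individuals(cnt)
  n_p <- lengths(inds)
  N <- sum(n_p)
  P <- length(inds)
  pooled <- unlist(inds)
  ssd_t <- pair_sum(pooled, delta) / N
  ssd_wp <- sum(vapply(seq_len(P), function(p) pair_sum(inds[[p]], delta) / n_p[p], numeric(1)))
  ssd_ap <- ssd_t - ssd_wp
  sigma_w <- ssd_wp / (N - P)
  n_c <- (N - sum(n_p^2) / N) / (P - 1)
  sigma_a <- (ssd_ap / (P - 1) - sigma_w) / n_c
  if (sigma_a + sigma_w <= 0) 0 else sigma_a / (sigma_a + sigma_w)
}

# three-level AMOVA variance components from explicit enumeration
oracle_amova3 <- function(cnt, groups, delta) {
  inds <- expand_individuals(cnt)
  names(inds) <- colnames(cnt)
  n_p <- lengths(inds)
  N <- sum(n_p)
  P <- length(inds)
  glabs <- unique(groups)
  G <- length(glabs)
  N_g <- vapply(glabs, function(g) sum(n_p[groups == g]), numeric(1))
  ssd_t <- pair_sum(unlist(inds), delta) / N
  ssd_wp <- sum(vapply(seq_len(P), function(p) pair_sum(inds[[p]], delta) / n_p[p], numeric(1)))
  ssd_wg <- sum(vapply(glabs, function(g) {
    pair_sum(unlist(inds[groups == g]), delta) / sum(n_p[groups == g])
  }, numeric(1)))
  ssd_ag <- ssd_t - ssd_wg
  ssd_apwg <- ssd_wg - ssd_wp
  sumsq_g <- vapply(glabs, function(g) sum(n_p[groups == g]^2), numeric(1))
  n1 <- (N - sum(sumsq_g / N_g)) / (P - G)
  n2 <- (sum(sumsq_g / N_g) - sum(n_p^2) / N) / (G - 1)
  n3 <- (N - sum(N_g^2) / N) / (G - 1)
  sigma_c <- ssd_wp / (N - P)
  sigma_b <- (ssd_apwg / (P - G) - sigma_c) / n1
  sigma_a <- (ssd_ag / (G - 1) - sigma_c - n2 * sigma_b) / n3
  c(sigma_a = sigma_a, sigma_b = sigma_b, sigma_c = sigma_c)
}

# brute-force membership scan for drifter counting: per fix, per box,
# per target, with no early exits
oracle_count_passages <- function(tracks, boxes, targets) {
  point_in <- function(lat, lon, b) {
    lat >= b$lat_min && lat <= b$lat_max &&
      (if (b$lon_min <= b$lon_max) lon >= b$lon_min && lon <= b$lon_max
       else lon >= b$lon_min || lon <= b$lon_max)
  }
  targ_ids <- unique(targets$target)
  n <- stats::setNames(integer(nrow(boxes)), boxes$id)
  k <- matrix(0L, nrow(boxes), length(targ_ids), dimnames = list(boxes$id, targ_ids))
  for (id in unique(tracks$id)) {
    tr <- tracks[tracks$id == id, ]
    tr <- tr[order(tr$timestamp), ]
    for (r in seq_len(nrow(boxes))) {
      entry <- NA
      for (i in seq_len(nrow(tr))) {
        if (point_in(tr$lat[i], tr$lon[i], boxes[r, ])) { entry <- i; break }
      }
      if (is.na(entry)) next
      n[r] <- n[r] + 1L
      for (t in seq_along(targ_ids)) {
        tb <- targets[targets$target == targ_ids[t], ]
        hit <- FALSE
        for (i in entry:nrow(tr)) {
          for (b in seq_len(nrow(tb))) {
            if (point_in(tr$lat[i], tr$lon[i], tb[b, ])) { hit <- TRUE; break }
          }
          if (hit) break
        }
        if (hit) k[r, t] <- k[r, t] + 1L
      }
    }
  }
  list(n = n, k = k)
}

# Kimura two-parameter distance in closed form
k80_distance <- function(P, Q) {
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# Jukes-Cantor distance in closed form
jc_distance <- function(p) {
  -0.75 * log(1 - 4 * p / 3)
}

# build a pair of equal-base-composition sequences differing by
# composition-preserving "swap pairs" of sites, so the TN93 pooled
# frequencies are exactly (1/4, 1/4, 1/4, 1/4)
balanced_pair <- function(L, swaps) {
  stopifnot(L %% 4 == 0)
  x <- rep(c("A", "C", "G", "T"), each = L / 4)
  y <- x
  used <- integer(0)
  for (sw in swaps) {
    i <- setdiff(which(x == sw[1]), used)[1]
    j <- setdiff(which(x == sw[2]), used)[1]
    y[i] <- sw[2]; y[j] <- sw[1]
    used <- c(used, i, j)
  }
  seq_set(c(x = paste0(x, collapse = ""), y = paste0(y, collapse = "")))
}

# shared small fixtures
table1_path <- function() system.file("extdata", "table1_740bp.csv", package = "stockmix")
collapse_path <- function() system.file("extdata", "collapse_382bp.csv", package = "stockmix")

ht <- function(...) {
  # ht(A = c(3, 0), B = c(1, 2)) -> hap_table with haplotypes h1, h2, ...
  cols <- list(...)
  H <- length(cols[[1]])
  df <- tibble::tibble(haplotype = sprintf("h%d", seq_len(H)))
  for (nm in names(cols)) df[[nm]] <- as.integer(cols[[nm]])
  hap_table(df, roles = "feeding")
}

random_table <- function(n_pops, n_haps, n_per_pop, seed) {
  set.seed(seed)
  repeat {
    m <- vapply(seq_len(n_pops), function(p) {
      g <- rgamma(n_haps, 0.5)
      as.numeric(rmultinom(1, n_per_pop, g / sum(g)))
    }, numeric(n_haps))
    if (all(colSums(m) >= 2) && all(rowSums(m) > 0)) break
  }
  df <- tibble::tibble(haplotype = sprintf("h%d", seq_len(n_haps)))
  for (p in seq_len(n_pops)) df[[sprintf("P%d", p)]] <- as.integer(m[, p])
  hap_table(df, roles = "feeding")
}
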