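# Analysis of molecular variance in the Excoffier-Smouse-Quattro framework,
# computed directly from haplotype count vectors and a haplotype-level
# distance matrix. The supplied distances play the role of squared
# inter-individual distances (the Arlequin convention): an identity matrix
# gives the classical frequency F-ST, a molecular matrix gives phi-ST.

# sum of squared deviations of a pooled sample given haplotype counts c:
# SSD = (1 / 2N) * c' delta c   (delta has zero diagonal)
ssd_pooled <- function(counts, delta) {
  n <- sum(counts)
  if (n == 0) return(0)
  as.numeric(t(counts) %*% delta %*% counts) / (2 * n)
}

# two-level variance decomposition for a set of populations (columns of cnt)
amova2_components <- function(cnt, delta) {
  n_p <- colSums(cnt)
  N <- sum(n_p)
  P <- ncol(cnt)
  ssd_wp <- sum(vapply(seq_len(P), function(p) ssd_pooled(cnt[, p], delta), numeric(1)))
  ssd_t <- ssd_pooled(rowSums(cnt), delta)
  ssd_ap <- ssd_t - ssd_wp
  df_w <- N - P
  df_a <- P - 1
  sigma_w <- ssd_wp / df_w
  n_c <- (N - sum(n_p^2) / N) / df_a
  sigma_a <- (ssd_ap / df_a - sigma_w) / n_c
  list(ssd_ap = ssd_ap, ssd_wp = ssd_wp, df_a = df_a, df_w = df_w,
       sigma_a = sigma_a, sigma_w = sigma_w)
}

fixation_index <- function(cnt, delta) {
  cmp <- amova2_components(cnt, delta)
  tot <- cmp$sigma_a + cmp$sigma_w
  if (tot <= 0) return(0)
  cmp$sigma_a / tot
}

# random reassignment of individuals to populations with fixed sizes,
# returned as a haplotype-by-population count matrix
permute_individuals <- function(cnt) {
  n_p <- colSums(cnt)
  pool <- rep(seq_len(nrow(cnt)), rowSums(cnt))
  pool <- sample(pool)
  idx <- cumsum(c(0, n_p))
  out <- vapply(seq_along(n_p), function(p) {
    tabulate(pool[(idx[p] + 1):idx[p + 1]], nbins = nrow(cnt))
  }, numeric(nrow(cnt)))
  matrix(out, nrow = nrow(cnt), dimnames = dimnames(cnt))
}

#' Pairwise fixation indices with permutation p-values
#'
#' For every pair of populations, performs a two-level analysis of molecular
#' variance and reports the fixation index
#' `sigma_among / (sigma_among + sigma_within)`. With `dist = NULL` the
#' haplotype-identity distance is used and the index is the classical
#' frequency-only F-ST; with a TN93 matrix it is phi-ST. Significance is
#' assessed by randomly reassigning individuals to the two populations
#' (sample sizes fixed); the p-value counts permuted indices at least as
#' large as the observed one, with the observed configuration included in
#' the null set.
#'
#' @param table a [hap_table] with at least 2 populations, each of size >= 2.
#' @param dist haplotype distance matrix covering the table's haplotypes, or
#'   `NULL` for the identity (frequency-only) distance.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @return a `pairwise_structure` object: list with `index` (raw, possibly
#'   negative), `index_display` (negatives truncated to 0), `p` matrices,
#'   `metric`, `n_perm`, `seed`. Use [generics::tidy()] for a long tibble.
#' @export
pairwise_fixation <- function(table, dist = NULL, n_perm = 10000, seed = 1L) {
  assert_scalar_count(n_perm, "n_perm", min = 1)
  cnt_all <- hap_counts(table)
  pops <- pop_ids(table)
  if (length(pops) < 2) abort("need at least 2 populations.")
  small <- pops[colSums(cnt_all) < 2]
  if (length(small)) {
    abort(paste0("population(s) with fewer than 2 individuals: ", paste(small, collapse = ", ")))
  }
  metric <- if (is.null(dist)) "F_ST" else "phi_ST"
  delta_all <- if (is.null(dist)) identity_distance(rownames(cnt_all)) else {
    as.matrix(dist)[rownames(cnt_all), rownames(cnt_all)]
  }
  P <- length(pops)
  idx <- matrix(0, P, P, dimnames = list(pops, pops))
  pmat <- matrix(1, P, P, dimnames = list(pops, pops))
  with_seed(seed, {
    for (i in seq_len(P - 1)) {
      for (j in (i + 1):P) {
        cnt <- cnt_all[, c(i, j)]
        keep <- rowSums(cnt) > 0
        cnt <- cnt[keep, , drop = FALSE]
        delta <- delta_all[keep, keep, drop = FALSE]
        obs <- fixation_index(cnt, delta)
        ge <- vapply(seq_len(n_perm), function(k) {
          fixation_index(permute_individuals(cnt), delta) >= obs - 1e-12
        }, logical(1))
        idx[i, j] <- idx[j, i] <- obs
        pmat[i, j] <- pmat[j, i] <- (sum(ge) + 1) / (n_perm + 1)
      }
    }
  })
  structure(list(index = idx, index_display = pmax(idx, 0), p = pmat,
                 metric = metric, n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "pairwise_structure")
}

#' @export
print.pairwise_structure <- function(x, ...) {
  cat(sprintf("# pairwise %s (%d permutations, seed %d)\n", x$metric, x$n_perm, x$seed))
  print(round(x$index_display, 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.pairwise_structure <- function(x, ...) {
  pops <- rownames(x$index)
  pairs <- which(upper.tri(x$index), arr.ind = TRUE)
  tibble::tibble(
    pop1 = pops[pairs[, 1]], pop2 = pops[pairs[, 2]],
    metric = x$metric,
    index = x$index[pairs], index_display = x$index_display[pairs],
    p = x$p[pairs], significant = x$p[pairs] <= 0.05
  )
}

#' Hierarchical analysis of molecular variance
#'
#' Partitions molecular variance among groups of populations, among
#' populations within groups, and within populations, following the
#' Excoffier-Smouse-Quattro moment estimators with unequal-size
#' coefficients. Supplying group labels for every population (e.g. ocean
#' regions, or the current systems bathing each feeding ground) gives the
#' 3-level design with Phi_CT, Phi_SC and Phi_ST; a single group reduces to
#' the 2-level design (Phi_ST only).
#'
#' Permutation p-values: Phi_ST permutes individuals among all populations,
#' Phi_SC permutes individuals among populations within their group, and
#' Phi_CT permutes whole populations among groups.
#'
#' @param table a [hap_table].
#' @param groups named character vector `population -> group`; defaults to
#'   the table's group attribute.
#' @param dist haplotype distance matrix or `NULL` for identity distance.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return an `amova_fit`: list with `components` tibble (level, df, SSD,
#'   variance, pct), `phi` tibble (statistic, value, p), plus metadata.
#' @export
amova <- function(table, groups = NULL, dist = NULL, n_perm = 10000, seed = 1L) {
  assert_scalar_count(n_perm, "n_perm", min = 1)
  if (is.null(groups)) groups <- pop_groups(table)
  if (is.null(groups)) groups <- setNames(rep("all", length(pop_ids(table))), pop_ids(table))
  pops <- pop_ids(table)
  if (!all(pops %in% names(groups))) {
    abort(paste0("missing group for population(s): ",
                 paste(setdiff(pops, names(groups)), collapse = ", ")))
  }
  groups <- groups[pops]
  if (any(table(groups) < 1)) abort("every group needs at least one population.")
  cnt <- hap_counts(table)
  delta <- if (is.null(dist)) identity_distance(rownames(cnt)) else {
    as.matrix(dist)[rownames(cnt), rownames(cnt)]
  }
  metric <- if (is.null(dist)) "F_ST" else "phi_ST"
  G <- length(unique(groups))

  if (G == 1) {
    cmp <- amova2_components(cnt, delta)
    tot <- cmp$sigma_a + cmp$sigma_w
    phi_st <- if (tot <= 0) 0 else cmp$sigma_a / tot
    pv <- with_seed(seed, {
      ge <- vapply(seq_len(n_perm), function(k) {
        fixation_index(permute_individuals(cnt), delta) >= phi_st - 1e-12
      }, logical(1))
      (sum(ge) + 1) / (n_perm + 1)
    })
    components <- tibble::tibble(
      level = c("among populations", "within populations"),
      df = c(cmp$df_a, cmp$df_w),
      SSD = c(cmp$ssd_ap, cmp$ssd_wp),
      variance = c(cmp$sigma_a, cmp$sigma_w)
    )
    components$pct <- 100 * components$variance / sum(components$variance)
    phi <- tibble::tibble(statistic = "Phi_ST", value = phi_st, p = pv)
    return(structure(list(components = components, phi = phi, metric = metric,
                          groups = groups, n_perm = as.integer(n_perm),
                          seed = as.integer(seed)),
                     class = "amova_fit"))
  }

  obs <- amova3(cnt, groups, delta)
  pv <- with_seed(seed, {
    ge_st <- 0; ge_sc <- 0; ge_ct <- 0
    glabs <- unique(groups)
    for (k in seq_len(n_perm)) {
      # Phi_ST: individuals among all populations
      st <- amova3(perm_counts_all(cnt), groups, delta)
      if (st$phi_st >= obs$phi_st - 1e-12) ge_st <- ge_st + 1
      # Phi_SC: individuals among populations within groups
      sc <- amova3(perm_counts_within(cnt, groups), groups, delta)
      if (sc$phi_sc >= obs$phi_sc - 1e-12) ge_sc <- ge_sc + 1
      # Phi_CT: whole populations among groups
      ct <- amova3(cnt, setNames(sample(groups), names(groups)), delta)
      if (ct$phi_ct >= obs$phi_ct - 1e-12) ge_ct <- ge_ct + 1
    }
    c(st = (ge_st + 1) / (n_perm + 1),
      sc = (ge_sc + 1) / (n_perm + 1),
      ct = (ge_ct + 1) / (n_perm + 1))
  })
  components <- tibble::tibble(
    level = c("among groups", "among populations within groups", "within populations"),
    df = c(obs$df_a, obs$df_b, obs$df_c),
    SSD = c(obs$ssd_ag, obs$ssd_apwg, obs$ssd_wp),
    variance = c(obs$sigma_a, obs$sigma_b, obs$sigma_c)
  )
  components$pct <- 100 * components$variance / sum(components$variance)
  phi <- tibble::tibble(
    statistic = c("Phi_CT", "Phi_SC", "Phi_ST"),
    value = c(obs$phi_ct, obs$phi_sc, obs$phi_st),
    p = unname(pv[c("ct", "sc", "st")])
  )
  structure(list(components = components, phi = phi, metric = metric,
                 groups = groups, n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "amova_fit")
}

amova3 <- function(cnt, groups, delta) {
  pops <- colnames(cnt)
  n_p <- colSums(cnt)
  N <- sum(n_p)
  P <- ncol(cnt)
  glabs <- unique(groups)
  G <- length(glabs)
  N_g <- vapply(glabs, function(g) sum(n_p[groups == g]), numeric(1))

  ssd_wp <- sum(vapply(seq_len(P), function(p) ssd_pooled(cnt[, p], delta), numeric(1)))
  ssd_wg <- sum(vapply(glabs, function(g) {
    ssd_pooled(rowSums(cnt[, groups == g, drop = FALSE]), delta)
  }, numeric(1)))
  ssd_t <- ssd_pooled(rowSums(cnt), delta)
  ssd_ag <- ssd_t - ssd_wg
  ssd_apwg <- ssd_wg - ssd_wp

  df_a <- G - 1; df_b <- P - G; df_c <- N - P
  sumsq_by_g <- vapply(glabs, function(g) sum(n_p[groups == g]^2), numeric(1))
  n1 <- (N - sum(sumsq_by_g / N_g)) / df_b
  n2 <- (sum(sumsq_by_g / N_g) - sum(n_p^2) / N) / df_a
  n3 <- (N - sum(N_g^2) / N) / df_a

  sigma_c <- ssd_wp / df_c
  sigma_b <- if (df_b > 0) (ssd_apwg / df_b - sigma_c) / n1 else 0
  sigma_a <- (ssd_ag / df_a - sigma_c - n2 * sigma_b) / n3
  tot <- sigma_a + sigma_b + sigma_c
  list(ssd_ag = ssd_ag, ssd_apwg = ssd_apwg, ssd_wp = ssd_wp,
       df_a = df_a, df_b = df_b, df_c = df_c,
       sigma_a = sigma_a, sigma_b = sigma_b, sigma_c = sigma_c,
       phi_ct = if (tot <= 0) 0 else sigma_a / tot,
       phi_sc = if (sigma_b + sigma_c <= 0) 0 else sigma_b / (sigma_b + sigma_c),
       phi_st = if (tot <= 0) 0 else (sigma_a + sigma_b) / tot)
}

perm_counts_all <- function(cnt) {
  out <- permute_individuals(cnt)
  dimnames(out) <- dimnames(cnt)
  out
}

perm_counts_within <- function(cnt, groups) {
  out <- cnt
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (length(cols) > 1) {
      sub <- permute_individuals(cnt[, cols, drop = FALSE])
      out[, cols] <- sub
    }
  }
  out
}

#' @export
print.amova_fit <- function(x, ...) {
  cat(sprintf("# AMOVA (%s distances, %d permutations)\n", x$metric, x$n_perm))
  print(as.data.frame(x$components), row.names = FALSE)
  print(as.data.frame(x$phi), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.amova_fit <- function(x, ...) x$phi

#' @importFrom generics glance
#' @export
glance.amova_fit <- function(x, ...) {
  tibble::tibble(
    metric = x$metric,
    n_levels = nrow(x$components) + 1L,
    df_total = sum(x$components$df),
    phi_st = x$phi$value[x$phi$statistic == "Phi_ST"],
    p_st = x$phi$p[x$phi$statistic == "Phi_ST"],
    n_perm = x$n_perm, seed = x$seed
  )
}
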