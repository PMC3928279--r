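#' Remove orphan haplotypes and assemble mixed-stock input
#'
#' Orphan haplotypes — observed at a feeding ground but never at any
#' characterized rookery — cannot be assigned a source and are excluded from
#' mixed stock analysis. Haplotypes present in any rookery are retained even
#' when rare or of hybrid origin. Removals are reported and warned about.
#'
#' @param feeding a [hap_table] of feeding-ground samples.
#' @param rookeries a [hap_table] of rookery samples sharing the haplotype
#'   namespace.
#' @param sizes rookery sizes: a named numeric vector or a tibble with
#'   columns `id` and `size` (nesting females per season). `NULL` gives every
#'   rookery equal weight (covariate off).
#' @return list with `input` (an `msa_input`) and `removed` (character
#'   vector of excluded haplotype ids).
#' @export
filter_orphans <- function(feeding, rookeries, sizes = NULL) {
  rook_tot <- rowSums(hap_counts(rookeries))
  known <- names(rook_tot)[rook_tot > 0]
  orphans <- setdiff(hap_ids(feeding), known)
  if (length(orphans)) {
    fg_cnt <- hap_counts(feeding)
    lost <- colSums(fg_cnt[setdiff(rownames(fg_cnt), orphans), , drop = FALSE]) == 0
    if (any(lost)) {
      abort(paste0("feeding population(s) consisting solely of orphan haplotypes: ",
                   paste(names(lost)[lost], collapse = ", ")))
    }
    warn(paste0("excluding orphan haplotype(s) absent from all rookeries: ",
                paste(orphans, collapse = ", ")))
    df <- tibble::as_tibble(as.data.frame(feeding))
    df <- df[!df$haplotype %in% orphans, ]
    feeding <- hap_table(df, roles = pop_roles(feeding), groups = pop_groups(feeding),
                         locus = hap_locus(feeding))
  }
  list(input = msa_input(feeding, rookeries, sizes), removed = orphans)
}

#' Construct mixed-stock input
#'
#' @inheritParams filter_orphans
#' @return an `msa_input`: list with aligned count matrices `C_R`
#'   (haplotypes x rookeries), `C_M` (haplotypes x feeding grounds) and the
#'   size vector `S`.
#' @export
msa_input <- function(feeding, rookeries, sizes = NULL) {
  orphans <- setdiff(hap_ids(feeding), hap_ids(rookeries))
  if (length(orphans)) {
    abort(paste0("feeding table contains orphan haplotype(s); run filter_orphans() first: ",
                 paste(orphans, collapse = ", ")))
  }
  haps <- hap_ids(rookeries)
  C_R <- hap_counts(rookeries)
  C_M <- matrix(0L, length(haps), length(pop_ids(feeding)),
                dimnames = list(haps, pop_ids(feeding)))
  fg_cnt <- hap_counts(feeding)
  C_M[rownames(fg_cnt), ] <- fg_cnt
  R <- ncol(C_R)
  if (is.null(sizes)) {
    S <- setNames(rep(1, R), colnames(C_R))
  } else {
    if (is.data.frame(sizes)) sizes <- setNames(sizes$size, sizes$id)
    miss <- setdiff(colnames(C_R), names(sizes))
    if (length(miss)) abort(paste0("missing size for rookery(ies): ", paste(miss, collapse = ", ")))
    S <- sizes[colnames(C_R)]
  }
  if (any(!is.finite(S)) || any(S <= 0)) abort("rookery sizes must be finite and strictly positive.")
  structure(list(C_R = C_R, C_M = C_M, S = S), class = "msa_input")
}

#' Fit the many-to-many mixed stock model
#'
#' Joint Bayesian estimation of where turtles sampled at each feeding ground
#' hatched (feeding-ground-centric contributions `theta`) and where the
#' hatchlings of each rookery go (rookery-centric destination vectors
#' `phi`). Each rookery r has a simplex `phi_r` over the feeding grounds
#' plus an UNKNOWN sink, with a flat Dirichlet(1) prior; rookery haplotype
#' frequencies `f_r` have Dirichlet(1) priors updated by the rookery samples.
#' Rookery size enters as an ecological covariate: the mixture sampled at
#' feeding ground m is
#' `theta_{m,r} = S_r phi_{r,m} / sum_r' S_r' phi_{r',m}`,
#' so large rookeries are a priori likelier sources of any given immature
#' turtle.
#'
#' Sampling is Gibbs over latent natal-rookery assignments of each
#' feeding-ground individual and the `f_r` (both conjugate), with a
#' Metropolis step for each `phi_r` (Dirichlet proposal whose concentration
#' is adapted during burn-in only). One chain is run per rookery, each
#' initialized with every individual assigned to that rookery
#' (overdispersed starts), and the potential scale reduction factor is
#' computed across chains for every stored parameter.
#'
#' @param input an `msa_input` from [msa_input()] or [filter_orphans()].
#' @param chain_length total MCMC sweeps per chain (default 20000).
#' @param burn_frac fraction of each chain discarded as burn-in (default 0.5).
#' @param seed integer seed.
#' @param n_chains number of chains; default one per rookery (minimum 2 when
#'   more than one rookery).
#' @param thin keep every `thin`-th post-burn-in sweep; default targets about
#'   2000 stored draws per chain.
#' @param save_draws keep the raw stored draws in the result.
#' @return an `msa_fit`: posterior means and central 95% intervals for
#'   `theta` (feeding-ground-centric, feeding grounds x rookeries) and `phi`
#'   (rookery-centric, rookeries x destinations incl. UNKNOWN), Gelman-Rubin
#'   factors per parameter, and chain metadata. Use [generics::tidy()] /
#'   [generics::glance()].
#' @export
fit_many_to_many <- function(input, chain_length = 20000, burn_frac = 0.5, seed = 1L,
                             n_chains = NULL, thin = NULL, save_draws = FALSE) {
  stopifnot(inherits(input, "msa_input"))
  assert_scalar_count(chain_length, "chain_length", min = 100)
  if (!is.numeric(burn_frac) || burn_frac <= 0 || burn_frac >= 1) {
    abort("`burn_frac` must be in (0, 1).")
  }
  C_R <- input$C_R; C_M <- input$C_M; S <- as.numeric(input$S)
  if (any(!is.finite(S))) abort("non-finite rookery size.")
  H <- nrow(C_R); R <- ncol(C_R); M <- ncol(C_M)
  rook_ids <- colnames(C_R); fg_ids <- colnames(C_M)
  dest_ids <- c(fg_ids, "UNKNOWN")
  n_m <- colSums(C_M)
  if (is.null(n_chains)) n_chains <- R
  n_chains <- assert_scalar_count(n_chains, "n_chains", min = 1)
  n_burn <- floor(chain_length * burn_frac)
  n_keep <- chain_length - n_burn
  if (is.null(thin)) thin <- max(1L, n_keep %/% 2000L)
  thin <- assert_scalar_count(thin, "thin", min = 1)
  n_store <- n_keep %/% thin

  nz <- lapply(seq_len(M), function(m) which(C_M[, m] > 0))

  run_chain <- function(chain_id, chain_seed) {
    with_seed(chain_seed, {
      init_r <- ((chain_id - 1L) %% R) + 1L
      A <- matrix(0, H, R); N <- matrix(0, R, M)
      A[, init_r] <- rowSums(C_M)
      N[init_r, ] <- n_m
      f <- matrix(0, H, R)
      phi <- matrix(0, R, M + 1)
      for (r in seq_len(R)) phi[r, ] <- rdirichlet1(rep(1, M + 1))
      prop_c <- rep(50 * (M + 1), R)
      acc <- rep(0L, R); acc_win <- 0L
      theta_store <- matrix(NA_real_, n_store, M * R)
      phi_store <- matrix(NA_real_, n_store, R * (M + 1))
      stored <- 0L

      log_cond_phi <- function(r, phi_r, phi) {
        phi2 <- phi; phi2[r, ] <- phi_r
        D <- colSums(S * phi2[, seq_len(M), drop = FALSE])
        if (any(D <= 0)) return(-Inf)
        sum(N[r, ] * log(pmax(phi_r[seq_len(M)], 1e-300))) - sum(n_m * log(D))
      }
      ldirichlet <- function(x, alpha) {
        sum((alpha - 1) * log(pmax(x, 1e-300))) + lgamma(sum(alpha)) - sum(lgamma(alpha))
      }

      for (sweep in seq_len(chain_length)) {
        # f_r | rookery counts + assigned feeding individuals (conjugate)
        for (r in seq_len(R)) f[, r] <- rdirichlet1(1 + C_R[, r] + A[, r])
        # phi_r | assignments: Metropolis-within-Gibbs alternating an
        # independence proposal from the approximate conjugate Dirichlet
        # (exact if the normalizer were constant) with an adaptive
        # random-walk Dirichlet proposal
        for (r in seq_len(R)) {
          # dedicated move for the weakly identified UNKNOWN share: random
          # walk on its log-odds, rescaling the observed destinations
          cur <- phi[r, ]
          uB <- cur[M + 1]
          if (uB > 1e-12 && uB < 1 - 1e-12) {
            t_new <- log(uB / (1 - uB)) + rnorm(1, 0, 0.6)
            uB2 <- 1 / (1 + exp(-t_new))
            prop <- c(cur[seq_len(M)] * (1 - uB2) / (1 - uB), uB2)
            lr <- log_cond_phi(r, prop, phi) - log_cond_phi(r, cur, phi) +
              (M - 1) * (log(1 - uB2) - log(1 - uB)) +
              log(uB2 * (1 - uB2)) - log(uB * (1 - uB))
            if (is.finite(lr) && log(runif(1)) < lr) phi[r, ] <- prop
          }
          for (sub in 1:2) {
            cur <- phi[r, ]
            if (sub == 1L) {
              a_ind <- c(N[r, ], 0) + 1
              prop <- rdirichlet1(a_ind)
              lr <- log_cond_phi(r, prop, phi) - log_cond_phi(r, cur, phi) +
                ldirichlet(cur, a_ind) - ldirichlet(prop, a_ind)
            } else {
              a_fwd <- prop_c[r] * cur + 0.1
              prop <- rdirichlet1(a_fwd)
              a_bwd <- prop_c[r] * prop + 0.1
              lr <- log_cond_phi(r, prop, phi) - log_cond_phi(r, cur, phi) +
                ldirichlet(cur, a_bwd) - ldirichlet(prop, a_fwd)
            }
            if (is.finite(lr) && log(runif(1)) < lr) {
              phi[r, ] <- prop
              if (sub == 2L) acc[r] <- acc[r] + 1L
            }
          }
        }
        acc_win <- acc_win + 1L
        if (sweep <= n_burn && acc_win == 50L) {
          rate <- acc / 50
          prop_c[rate < 0.20] <- prop_c[rate < 0.20] * 1.5
          prop_c[rate > 0.45] <- prop_c[rate > 0.45] / 1.5
          acc <- rep(0L, R); acc_win <- 0L
        }
        # derived feeding-ground-centric mixture (size covariate)
        W <- S * phi[, seq_len(M), drop = FALSE]      # R x M
        theta <- t(W) / colSums(W)                    # M x R
        # latent assignments z (counted per haplotype cell)
        A <- matrix(0, H, R); N <- matrix(0, R, M)
        for (m in seq_len(M)) {
          for (h in nz[[m]]) {
            w <- theta[m, ] * f[h, ]
            if (sum(w) <= 0) w <- rep(1, R)
            draw <- as.numeric(rmultinom(1, C_M[h, m], w))
            A[h, ] <- A[h, ] + draw
            N[, m] <- N[, m] + draw
          }
        }
        if (sweep > n_burn && (sweep - n_burn) %% thin == 0L && stored < n_store) {
          stored <- stored + 1L
          theta_store[stored, ] <- as.numeric(theta)
          phi_store[stored, ] <- as.numeric(phi)
        }
      }
      list(theta = theta_store[seq_len(stored), , drop = FALSE],
           phi = phi_store[seq_len(stored), , drop = FALSE])
    })
  }

  chains <- lapply(seq_len(n_chains), function(k) {
    run_chain(k, substream_seed(seed, paste0("msa_chain_", k)))
  })

  theta_all <- do.call(rbind, lapply(chains, `[[`, "theta"))
  phi_all <- do.call(rbind, lapply(chains, `[[`, "phi"))
  summarize_mat <- function(draws, nrow_out, ncol_out, rn, cn) {
    stats <- apply(draws, 2, function(v) c(mean(v), quantile(v, c(0.025, 0.975))))
    shape <- function(i) matrix(stats[i, ], nrow_out, ncol_out, dimnames = list(rn, cn))
    list(mean = shape(1), lo = shape(2), hi = shape(3))
  }
  theta_sum <- summarize_mat(theta_all, M, R, fg_ids, rook_ids)
  phi_sum <- summarize_mat(phi_all, R, M + 1, rook_ids, dest_ids)

  gr <- NULL
  if (n_chains >= 2) {
    rhat_theta <- gelman_rubin(lapply(chains, `[[`, "theta"))
    rhat_phi <- gelman_rubin(lapply(chains, `[[`, "phi"))
    gr <- dplyr::bind_rows(
      tibble::tibble(block = "theta",
                     feeding_ground = rep(fg_ids, times = R),
                     rookery = rep(rook_ids, each = M),
                     rhat = rhat_theta),
      tibble::tibble(block = "phi",
                     feeding_ground = rep(dest_ids, each = R),
                     rookery = rep(rook_ids, times = M + 1),
                     rhat = rhat_phi)
    )
  }

  structure(list(
    theta = theta_sum, phi = phi_sum, gr = gr,
    feeding_grounds = fg_ids, rookeries = rook_ids, sizes = setNames(S, rook_ids),
    chain_length = chain_length, burn = n_burn, n_chains = n_chains,
    thin = thin, seed = as.integer(seed),
    draws = if (save_draws) chains else NULL
  ), class = "msa_fit")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The classic between/within-chain variance comparison: values near 1
#' indicate the chains have forgotten their starting points.
#'
#' @param chains list (length >= 2) of equal-size numeric matrices
#'   (draws x parameters) or vectors, one per chain, post burn-in.
#' @return numeric vector of factors, one per parameter.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2) abort("need at least 2 chains.")
  chains <- lapply(chains, function(ch) if (is.matrix(ch)) ch else matrix(ch, ncol = 1))
  n <- unique(vapply(chains, nrow, integer(1)))
  if (length(n) != 1) abort("chains must have equal length.")
  if (n < 10) abort("chains too short (need >= 10 post-burn-in draws).")
  means <- vapply(chains, colMeans, numeric(ncol(chains[[1]])))
  vars <- vapply(chains, function(ch) apply(ch, 2, var), numeric(ncol(chains[[1]])))
  means <- matrix(means, ncol = length(chains))
  vars <- matrix(vars, ncol = length(chains))
  W <- rowMeans(vars)
  B_over_n <- apply(means, 1, var)
  vplus <- (n - 1) / n * W + B_over_n
  rhat <- sqrt(vplus / W)
  rhat[vplus <= .Machine$double.eps] <- 1     # constant across and within chains
  rhat[W <= .Machine$double.eps & B_over_n > .Machine$double.eps] <- Inf
  unname(rhat)
}

#' @export
print.msa_fit <- function(x, ...) {
  cat(sprintf("# many-to-many mixed stock fit: %d rookeries -> %d feeding grounds\n",
              length(x$rookeries), length(x$feeding_grounds)))
  cat(sprintf("# %d chains x %d sweeps (burn-in %d, thin %d), seed %d\n",
              x$n_chains, x$chain_length, x$burn, x$thin, x$seed))
  if (!is.null(x$gr)) {
    cat(sprintf("# Gelman-Rubin: max %.3f, mean %.3f\n", max(x$gr$rhat), mean(x$gr$rhat)))
  }
  cat("# feeding-ground-centric posterior means (theta):\n")
  print(round(x$theta$mean, 3))
  invisible(x)
}

#' @export
tidy.msa_fit <- function(x, view = c("feeding", "rookery"), ...) {
  view <- match.arg(view)
  if (view == "feeding") {
    s <- x$theta
    tibble::tibble(
      feeding_ground = rep(rownames(s$mean), times = ncol(s$mean)),
      rookery = rep(colnames(s$mean), each = nrow(s$mean)),
      mean = as.numeric(s$mean), lo95 = as.numeric(s$lo), hi95 = as.numeric(s$hi)
    )
  } else {
    s <- x$phi
    tibble::tibble(
      rookery = rep(rownames(s$mean), times = ncol(s$mean)),
      destination = rep(colnames(s$mean), each = nrow(s$mean)),
      mean = as.numeric(s$mean), lo95 = as.numeric(s$lo), hi95 = as.numeric(s$hi)
    )
  }
}

#' @export
glance.msa_fit <- function(x, ...) {
  tibble::tibble(
    n_rookeries = length(x$rookeries),
    n_feeding = length(x$feeding_grounds),
    n_chains = x$n_chains,
    chain_length = x$chain_length,
    burn = x$burn,
    rhat_max = if (is.null(x$gr)) NA_real_ else max(x$gr$rhat),
    rhat_mean = if (is.null(x$gr)) NA_real_ else mean(x$gr$rhat),
    seed = x$seed
  )
}
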