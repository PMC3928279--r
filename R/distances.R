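#' Tamura-Nei (TN93) pairwise distances
#'
#' Closed-form TN93 distance (substitutions per site) between every pair of
#' aligned sequences. The model distinguishes the two transition types
#' (A<->G within purines, C<->T within pyrimidines) from transversions and
#' allows unequal base frequencies. For each pair, sites where either
#' sequence carries a gap are excluded (pairwise deletion) and base
#' frequencies are estimated by pooling the two sequences over the remaining
#' sites.
#'
#' With equal base frequencies the formula reduces to Kimura's two-parameter
#' (K80) distance, and with equal frequencies and equal rates to the
#' Jukes-Cantor (JC69) distance; those reductions serve as closed-form checks.
#'
#' @param seqs a [seq_set] with at least 2 sequences.
#' @return symmetric matrix of distances with zero diagonal, dimnames the
#'   sequence ids.
#' @section Errors:
#' Saturated pairs (a logarithm argument falling to zero or below) and pairs
#' with no gap-free overlap raise errors naming the pair.
#' @export
tn93_distance <- function(seqs) {
  if (length(seqs) < 2) abort("need at least 2 sequences.")
  ids <- names(seqs)
  chars <- lapply(unclass(seqs), function(s) strsplit(s, "")[[1]])
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- tn93_pair(chars[[i]], chars[[j]], ids[i], ids[j])
    }
  }
  d
}

tn93_pair <- function(x, y, idx, idy) {
  use <- x != "-" & y != "-"
  if (!any(use)) abort(sprintf("no gap-free overlap between '%s' and '%s'.", idx, idy))
  x <- x[use]; y <- y[use]
  L <- length(x)
  # pooled empirical base frequencies over the pair
  tab <- table(factor(c(x, y), levels = c("A", "C", "G", "T")))
  g <- as.numeric(tab) / (2 * L)
  names(g) <- c("A", "C", "G", "T")
  gR <- g[["A"]] + g[["G"]]; gY <- g[["C"]] + g[["T"]]
  diffs <- x != y
  P1 <- sum(diffs & ((x == "A" & y == "G") | (x == "G" & y == "A"))) / L
  P2 <- sum(diffs & ((x == "C" & y == "T") | (x == "T" & y == "C"))) / L
  Q <- sum(diffs) / L - P1 - P2
  if (P1 + P2 + Q == 0) return(0)

  safe_div <- function(a, b) if (a == 0) 0 else a / b
  k1 <- safe_div(2 * g[["A"]] * g[["G"]], gR)
  k2 <- safe_div(2 * g[["C"]] * g[["T"]], gY)
  k3 <- 2 * (gR * gY - safe_div(g[["A"]] * g[["G"]] * gY, gR) - safe_div(g[["C"]] * g[["T"]] * gR, gY))
  w3 <- 1 - safe_div(Q, 2 * gR * gY)
  terms <- 0
  if (k1 > 0) {
    w1 <- 1 - P1 / k1 - Q / (2 * gR)
    if (w1 <= 0) abort(sprintf("saturated A/G transitions between '%s' and '%s'.", idx, idy))
    terms <- terms - k1 * log(w1)
  } else if (P1 > 0) {
    abort(sprintf("A/G transitions observed between '%s' and '%s' but a purine frequency is zero.", idx, idy))
  }
  if (k2 > 0) {
    w2 <- 1 - P2 / k2 - Q / (2 * gY)
    if (w2 <= 0) abort(sprintf("saturated C/T transitions between '%s' and '%s'.", idx, idy))
    terms <- terms - k2 * log(w2)
  } else if (P2 > 0) {
    abort(sprintf("C/T transitions observed between '%s' and '%s' but a pyrimidine frequency is zero.", idx, idy))
  }
  if (w3 <= 0) abort(sprintf("saturated transversions between '%s' and '%s'.", idx, idy))
  terms <- terms - k3 * log(w3)
  unname(max(terms, 0))
}

#' Identity ("frequency-only") distance matrix
#'
#' `d_ij = 1` for distinct haplotypes and `0` on the diagonal. Feeding this
#' to the AMOVA machinery yields the classical haplotype-frequency fixation
#' index F-ST; a molecular (e.g. TN93) matrix yields phi-ST.
#'
#' @param ids character vector of haplotype ids.
#' @return square 0/1 matrix with dimnames `ids`.
#' @export
identity_distance <- function(ids) {
  n <- length(ids)
  d <- matrix(1, n, n, dimnames = list(ids, ids)) - diag(n)
  d
}
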