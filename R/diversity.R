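#' Classify a query sequence against a haplotype catalog
#'
#' Exact-match classification: the query is assigned the id of the unique
#' catalog sequence it matches at every site, or `"NEW"` if it differs from
#' every catalog entry (a previously undescribed haplotype).
#'
#' @param query a single aligned sequence (character scalar) with the same
#'   length as the catalog alignment.
#' @param catalog a [seq_set].
#' @return a haplotype id from the catalog, or `"NEW"`.
#' @export
classify_sequence <- function(query, catalog) {
  query <- toupper(query)
  if (nchar(query) != alignment_length(catalog)) {
    abort(sprintf("query length %d does not match alignment length %d.",
                  nchar(query), alignment_length(catalog)))
  }
  hit <- names(catalog)[unclass(catalog) == query]
  if (length(hit) == 0) "NEW" else hit[1]
}

#' Collapse long haplotypes onto their short equivalents
#'
#' Pools the counts of long-fragment haplotypes that become indistinguishable
#' on a shorter fragment (e.g. 740 bp haplotypes sharing a 382 bp
#' equivalent). Rows mapping to the same short id are summed; per-population
#' sample sizes are unchanged.
#'
#' @param table a [hap_table].
#' @param map named character vector `long id -> short id` covering every
#'   haplotype in `table` (see [read_collapse_map()]).
#' @param locus locus tag for the collapsed table, default `"382bp"`.
#' @return a [hap_table] on the short haplotype ids, in order of first
#'   appearance.
#' @export
collapse_haplotypes <- function(table, map, locus = "382bp") {
  miss <- setdiff(hap_ids(table), names(map))
  if (length(miss)) {
    abort(paste0("haplotype(s) missing from collapse map: ", paste(miss, collapse = ", ")))
  }
  m <- hap_counts(table)
  short <- map[rownames(m)]
  pooled <- rowsum(m, group = short, reorder = FALSE)
  df <- tibble::tibble(haplotype = rownames(pooled))
  for (p in colnames(pooled)) df[[p]] <- as.integer(pooled[, p])
  hap_table(df, roles = pop_roles(table), groups = pop_groups(table), locus = locus)
}

#' Nei gene (haplotype) diversity with standard error
#'
#' Unbiased gene diversity `h = n/(n-1) (1 - sum p_i^2)`: the probability
#' that two sequences drawn without replacement carry different haplotypes.
#' The variance follows Nei (1987, eq. 8.12), the convention used by
#' population-genetic software for haplotype data.
#'
#' @param counts integer vector of haplotype counts, total `n >= 2`.
#' @return tibble with columns `n`, `n_hap`, `h`, `se_h`.
#' @examples
#' gene_diversity(c(7, 1, 3, 1))
#' @export
gene_diversity <- function(counts) {
  counts <- check_counts(counts)
  n <- sum(counts)
  if (n < 2) abort("gene diversity needs a sample of at least 2.")
  p <- counts / n
  s2 <- sum(p^2)
  h <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (sum(p^3) - s2^2) + s2 - s2^2)
  tibble::tibble(n = n, n_hap = sum(counts > 0), h = h, se_h = sqrt(max(v, 0)))
}

#' Nucleotide diversity from haplotype counts and distances
#'
#' `pi = n/(n-1) * sum_ij p_i p_j d_ij` where `d_ij` is the per-site distance
#' between haplotypes i and j: the expected per-site difference between two
#' sequences drawn from the sample, with the small-sample correction. The
#' standard error uses Tajima's (1983) total variance when the alignment
#' length `L` is supplied, and is `NA` otherwise.
#'
#' @param counts integer vector of haplotype counts (total `n >= 2`).
#' @param dist square symmetric matrix of per-site distances between the
#'   haplotypes, in the same order as `counts`.
#' @param L optional alignment length (sites) for the variance formula.
#' @return tibble with columns `n`, `pi`, `se_pi`.
#' @export
nucleotide_diversity <- function(counts, dist, L = NULL) {
  counts <- check_counts(counts)
  dist <- as.matrix(dist)
  if (nrow(dist) != length(counts) || ncol(dist) != length(counts)) {
    abort(sprintf("distance matrix is %dx%d but there are %d haplotypes.",
                  nrow(dist), ncol(dist), length(counts)))
  }
  n <- sum(counts)
  if (n < 2) abort("nucleotide diversity needs a sample of at least 2.")
  p <- counts / n
  pi <- n / (n - 1) * as.numeric(t(p) %*% dist %*% p)
  se <- NA_real_
  if (!is.null(L)) {
    v <- (n + 1) / (3 * (n - 1)) * pi / L +
      2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
    se <- sqrt(max(v, 0))
  }
  tibble::tibble(n = n, pi = pi, se_pi = se)
}

check_counts <- function(counts) {
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers.")
  }
  as.integer(counts)
}

#' Per-population diversity summary
#'
#' Computes Nei gene diversity for every population of a haplotype table and,
#' when a distance matrix over the table's haplotypes is supplied, nucleotide
#' diversity as well.
#'
#' @param table a [hap_table].
#' @param dist optional [tn93_distance()] matrix (or any symmetric per-site
#'   distance matrix) whose row names cover the table's haplotypes.
#' @param L optional alignment length for the `se_pi` formula.
#' @return tibble with one row per population: `pop`, `n`, `n_hap`, `h`,
#'   `se_h`, and `pi`, `se_pi` when `dist` is given.
#' @export
diversity_summary <- function(table, dist = NULL, L = NULL) {
  m <- hap_counts(table)
  res <- purrr::map_dfr(pop_ids(table), function(p) {
    cnt <- m[, p]
    out <- dplyr::bind_cols(tibble::tibble(pop = p), gene_diversity(cnt))
    if (!is.null(dist)) {
      keep <- cnt > 0
      d <- as.matrix(dist)[rownames(m)[keep], rownames(m)[keep], drop = FALSE]
      out <- dplyr::bind_cols(out, nucleotide_diversity(cnt[keep], d, L = L)[c("pi", "se_pi")])
    }
    out
  })
  res
}
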