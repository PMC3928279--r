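#' Haplotype frequency tables
#'
#' A `hap_table` is a tibble with a `haplotype` identifier column and one
#' integer count column per population, plus metadata carried in attributes:
#' the role of each population (`"rookery"` or `"feeding"`), an optional group
#' label per population (ocean region or current group, used by [amova()]),
#' and a locus tag recording the fragment the haplotypes were scored on
#' (e.g. `"740bp"` or `"382bp"`).
#'
#' Invariants enforced at construction: counts are non-negative integers,
#' population ids are unique, and every haplotype row has a positive total
#' (all-zero rows are rejected here; [read_haplotype_table()] drops them with
#' a warning instead).
#'
#' @param counts a data frame whose first column (named `haplotype`) holds
#'   unique haplotype ids and whose remaining columns hold integer counts,
#'   one column per population.
#' @param roles named character vector mapping every population id to
#'   `"rookery"` or `"feeding"`. A single unnamed value is recycled.
#' @param groups optional named character vector mapping population ids to
#'   group labels.
#' @param locus character scalar tag for the sequence fragment.
#' @return a `hap_table` (subclass of `tbl_df`).
#' @examples
#' tab <- hap_table(
#'   tibble::tibble(haplotype = c("A", "B"), P1 = c(3L, 1L), P2 = c(0L, 2L)),
#'   roles = "feeding"
#' )
#' sample_sizes(tab)
#' @export
hap_table <- function(counts, roles, groups = NULL, locus = "740bp") {
  counts <- tibble::as_tibble(counts)
  if (ncol(counts) < 2L) abort("`counts` needs a haplotype column and at least one population column.")
  names(counts)[1] <- "haplotype"
  counts$haplotype <- as.character(counts$haplotype)
  pops <- names(counts)[-1]
  if (anyDuplicated(pops)) abort("population ids must be unique.")
  if (anyDuplicated(counts$haplotype)) {
    abort(paste0("duplicate haplotype ids: ",
                 paste(unique(counts$haplotype[duplicated(counts$haplotype)]), collapse = ", ")))
  }
  for (p in pops) {
    v <- counts[[p]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != round(v))) {
      bad <- which(!is.finite(v) | v < 0 | v != round(v))[1]
      abort(sprintf("counts must be non-negative integers; offending cell row '%s', column '%s'.",
                    counts$haplotype[bad], p))
    }
    counts[[p]] <- as.integer(v)
  }
  m <- as.matrix(counts[-1])
  if (any(rowSums(m) == 0)) {
    abort(paste0("haplotype rows with zero total: ",
                 paste(counts$haplotype[rowSums(m) == 0], collapse = ", ")))
  }
  if (length(roles) == 1L && is.null(names(roles))) roles <- setNames(rep(roles, length(pops)), pops)
  if (!all(pops %in% names(roles))) {
    abort(paste0("missing role for population(s): ",
                 paste(setdiff(pops, names(roles)), collapse = ", ")))
  }
  roles <- roles[pops]
  if (!all(roles %in% c("rookery", "feeding"))) abort("roles must be 'rookery' or 'feeding'.")
  if (!is.null(groups)) {
    if (!all(pops %in% names(groups))) {
      abort(paste0("missing group for population(s): ",
                   paste(setdiff(pops, names(groups)), collapse = ", ")))
    }
    groups <- groups[pops]
  }
  structure(counts,
            roles = roles, groups = groups, locus = locus,
            class = c("hap_table", class(tibble::tibble())))
}

#' @rdname hap_table
#' @param x a `hap_table`.
#' @export
hap_counts <- function(x) {
  stopifnot(inherits(x, "hap_table"))
  m <- as.matrix(as.data.frame(x)[-1])
  rownames(m) <- x$haplotype
  storage.mode(m) <- "integer"
  m
}

#' @rdname hap_table
#' @export
hap_ids <- function(x) x$haplotype

#' @rdname hap_table
#' @export
pop_ids <- function(x) names(x)[-1]

#' @rdname hap_table
#' @export
sample_sizes <- function(x) colSums(hap_counts(x))

#' @rdname hap_table
#' @export
pop_roles <- function(x) attr(x, "roles")

#' @rdname hap_table
#' @export
pop_groups <- function(x) attr(x, "groups")

#' @rdname hap_table
#' @export
hap_locus <- function(x) attr(x, "locus")

#' Attach group labels to a haplotype table
#'
#' @param x a `hap_table`.
#' @param groups named character vector, one label per population.
#' @return `x` with its group attribute replaced.
#' @export
set_pop_groups <- function(x, groups) {
  hap_table(tibble::as_tibble(as.data.frame(x)), roles = pop_roles(x),
            groups = groups, locus = hap_locus(x))
}

#' Restrict a haplotype table to a subset of populations
#'
#' Drops any haplotype rows whose total becomes zero after the subset.
#'
#' @param x a `hap_table`.
#' @param pops character vector of population ids to keep.
#' @return a `hap_table`.
#' @export
select_pops <- function(x, pops) {
  miss <- setdiff(pops, pop_ids(x))
  if (length(miss)) abort(paste0("unknown population(s): ", paste(miss, collapse = ", ")))
  df <- tibble::as_tibble(as.data.frame(x))[c("haplotype", pops)]
  keep <- rowSums(as.matrix(df[-1])) > 0
  g <- pop_groups(x)
  hap_table(df[keep, ], roles = pop_roles(x)[pops],
            groups = if (is.null(g)) NULL else g[pops], locus = hap_locus(x))
}

#' @export
print.hap_table <- function(x, ...) {
  cat(sprintf("# hap_table: %d haplotypes x %d populations (locus %s)\n",
              nrow(x), ncol(x) - 1L, hap_locus(x)))
  cat("# roles: ", paste(sprintf("%s=%s", pop_ids(x), pop_roles(x)), collapse = ", "), "\n", sep = "")
  if (!is.null(pop_groups(x))) {
    cat("# groups: ", paste(sprintf("%s=%s", pop_ids(x), pop_groups(x)), collapse = ", "), "\n", sep = "")
  }
  NextMethod()
}
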