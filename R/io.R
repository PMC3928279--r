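#' Read a haplotype frequency table from CSV
#'
#' The canonical dialect is comma-separated UTF-8 with a header row and the
#' haplotype id in the first column; every other column is a population of
#' integer counts (the layout of a published haplotype-frequency table).
#' Haplotype rows whose total count is zero are dropped with a warning.
#'
#' @param path path to a CSV file.
#' @param roles named character vector mapping population ids to `"rookery"`
#'   or `"feeding"`; a single unnamed value is recycled over all populations.
#' @param groups optional named character vector of group labels.
#' @param locus locus tag, default `"740bp"`.
#' @return a [hap_table].
#' @export
read_haplotype_table <- function(path, roles = "feeding", groups = NULL, locus = "740bp") {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(df)[1] <- "haplotype"
  for (p in names(df)[-1]) {
    v <- df[[p]]
    if (!is.numeric(v) || anyNA(v) || any(v != round(v)) || any(v < 0)) {
      bad <- which(!is.numeric(v) | is.na(v) | v != round(v) | v < 0)[1]
      abort(sprintf("non-integer or negative count at row '%s', column '%s' of %s.",
                    df$haplotype[bad], p, path))
    }
  }
  tot <- rowSums(as.matrix(df[-1]))
  if (any(tot == 0)) {
    warn(paste0("dropping haplotype row(s) with zero total count: ",
                paste(df$haplotype[tot == 0], collapse = ", ")))
    df <- df[tot > 0, ]
  }
  hap_table(df, roles = roles, groups = groups, locus = locus)
}

#' Write a haplotype table to CSV (canonical dialect)
#'
#' @param x a [hap_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(x)), path)
  invisible(path)
}

#' Read a long-to-short haplotype equivalence map
#'
#' Two-column CSV (`long,short`). Haplotypes with no short equivalent map to
#' themselves.
#'
#' @param path path to a CSV file.
#' @return named character vector: `long id -> short id`.
#' @export
read_collapse_map <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (ncol(df) != 2L) abort("collapse map must have exactly two columns (long, short).")
  if (anyDuplicated(df[[1]])) abort("duplicate long-haplotype ids in collapse map.")
  setNames(df[[2]], df[[1]])
}

#' Read rookery metadata from CSV
#'
#' Expects columns `id`, `lat`, `lon`, `size` where `size` is the estimated
#' number of nesting females per season (the ecological covariate used by the
#' mixed stock and drifter estimators). Longitudes are normalized to
#' `[-180, 180)`.
#'
#' @param path path to a CSV file.
#' @return a tibble with columns `id`, `lat`, `lon`, `size`.
#' @export
read_rookeries <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_rookeries(df)
}

validate_rookeries <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("id", "lat", "lon", "size")
  if (!all(need %in% names(df))) {
    abort(paste0("rookery table must have columns ", paste(need, collapse = ", "), "."))
  }
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) abort("rookery ids must be unique.")
  if (any(!is.finite(df$lat)) || any(df$lat < -90 | df$lat > 90)) abort("latitude out of [-90, 90].")
  if (any(!is.finite(df$lon))) abort("longitude must be finite.")
  if (any(!is.finite(df$size)) || any(df$size <= 0)) abort("rookery sizes must be strictly positive.")
  df$lon <- wrap_lon(df$lon)
  df[need]
}

#' Read surface drifter trajectories from CSV
#'
#' Expects columns `id`, `timestamp` (ISO-8601), `lat`, `lon` — the shape of
#' a Global Drifter Program export reduced to position fixes. Fixes are
#' grouped by drifter id and sorted ascending in time; drifters with fewer
#' than two fixes are dropped with a warning.
#'
#' @param path path to a CSV file.
#' @return a `drifter_tracks` tibble with columns `id`, `timestamp`
#'   (POSIXct, UTC), `lat`, `lon`.
#' @export
read_drifter_tracks <- function(path) {
  # readr's parse warning is superseded by the located error raised below
  df <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(
                      id = readr::col_character(),
                      timestamp = readr::col_datetime(),
                      lat = readr::col_double(),
                      lon = readr::col_double()
                    ))
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("unparseable field at line %d of %s (expected %s).",
                  probs$row[1] + 1L, path, probs$expected[1]))
  }
  if (anyNA(df$timestamp)) {
    abort(sprintf("unparseable timestamp at data line %d of %s.",
                  which(is.na(df$timestamp))[1], path))
  }
  drifter_tracks(df)
}

#' Construct a validated set of drifter tracks
#'
#' @param df data frame with columns `id`, `timestamp`, `lat`, `lon`.
#' @return a `drifter_tracks` tibble, fixes sorted by id and time.
#' @export
drifter_tracks <- function(df) {
  df <- tibble::as_tibble(df)[c("id", "timestamp", "lat", "lon")]
  df$id <- as.character(df$id)
  if (!inherits(df$timestamp, "POSIXct")) {
    df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  }
  attr(df$timestamp, "tzone") <- "UTC"
  if (any(df$lat < -90 | df$lat > 90)) abort("drifter latitude out of [-90, 90].")
  if (any(!is.finite(df$lon))) abort("drifter longitude must be finite.")
  df$lon <- wrap_lon(df$lon)
  df <- dplyr::arrange(df, .data$id, .data$timestamp)
  dup <- df |>
    dplyr::group_by(.data$id) |>
    dplyr::filter(duplicated(.data$timestamp)) |>
    dplyr::ungroup()
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate timestamp for drifter '%s'; timestamps must be strictly increasing.",
                  dup$id[1]))
  }
  nfix <- table(df$id)
  short <- names(nfix)[nfix < 2]
  if (length(short)) {
    warn(paste0("dropping drifter(s) with fewer than 2 fixes: ", paste(short, collapse = ", ")))
    df <- df[!df$id %in% short, ]
  }
  class(df) <- c("drifter_tracks", class(tibble::tibble()))
  df
}

#' Write drifter tracks to CSV (canonical dialect)
#'
#' @param tracks a `drifter_tracks` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_drifter_tracks <- function(tracks, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(tracks)), path)
  invisible(path)
}

#' Per-drifter lifespans
#'
#' @param tracks a `drifter_tracks` tibble.
#' @return tibble with columns `id`, `n_fixes`, `days` (last minus first fix).
#' @export
track_lifespans <- function(tracks) {
  tracks |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      n_fixes = dplyr::n(),
      days = as.numeric(difftime(max(.data$timestamp), min(.data$timestamp), units = "days")),
      .groups = "drop"
    )
}

#' Read an aligned haplotype catalog from FASTA
#'
#' All records must have equal length (an alignment); gap characters `-` are
#' allowed, lower-case input is upper-cased, and IUPAC ambiguity codes are
#' rejected because the downstream distance and diversity estimators assume
#' unambiguous states.
#'
#' @param path path to a FASTA file.
#' @return a [seq_set].
#' @export
read_sequences <- function(path) {
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) abort(sprintf("no FASTA records in %s.", path))
  chars <- vapply(as.character(dna), function(s) paste0(toupper(s), collapse = ""), character(1))
  seq_set(chars)
}

#' Construct an aligned sequence set
#'
#' @param x named character vector of aligned sequences over `A,C,G,T,-`.
#' @return a `seq_set`: the upper-cased vector with an `alignment_length`
#'   attribute.
#' @export
seq_set <- function(x) {
  if (is.null(names(x)) || anyDuplicated(names(x))) abort("sequences must have unique names.")
  x <- toupper(x)
  lens <- nchar(x)
  if (length(unique(lens)) != 1L) {
    abort(sprintf("ragged alignment: lengths %s.", paste(unique(lens), collapse = ", ")))
  }
  bad <- vapply(x, function(s) grepl("[^ACGT-]", s), logical(1))
  if (any(bad)) {
    abort(paste0("illegal character (ambiguity codes unsupported) in record(s): ",
                 paste(names(x)[bad], collapse = ", ")))
  }
  structure(x, alignment_length = unname(lens[1]), class = "seq_set")
}

#' @rdname seq_set
#' @param s a `seq_set`.
#' @export
alignment_length <- function(s) attr(s, "alignment_length")

#' Write a sequence set to FASTA
#'
#' @param s a [seq_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(s, path) {
  lines <- as.vector(rbind(paste0(">", names(s)), unclass(s)))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("# seq_set: %d aligned sequences of length %d\n", length(x), alignment_length(x)))
  show <- head(seq_along(x), 6)
  for (i in show) {
    s <- unclass(x)[i]
    cat(sprintf("  %s: %s%s\n", names(x)[i], substr(s, 1, 40), if (nchar(s) > 40) "..." else ""))
  }
  if (length(x) > 6) cat(sprintf("  ... and %d more\n", length(x) - 6))
  invisible(x)
}
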