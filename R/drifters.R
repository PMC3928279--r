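#' Delineate boxes around rookeries
#'
#' Builds a latitude/longitude box of the given span centered on each
#' rookery coordinate (default 4 degrees x 4 degrees, the release-area
#' convention for counting drifters that pass a rookery). Boxes crossing the
#' antimeridian are represented with `lon_min > lon_max` and handled by all
#' membership tests.
#'
#' @param rookeries tibble with columns `id`, `lat`, `lon` (and usually
#'   `size`), e.g. from [read_rookeries()].
#' @param span box side length in degrees (default 4).
#' @return tibble with columns `id`, `lat_min`, `lat_max`, `lon_min`,
#'   `lon_max`.
#' @export
rookery_boxes <- function(rookeries, span = 4) {
  if (!all(c("id", "lat", "lon") %in% names(rookeries))) {
    abort("rookeries must have columns id, lat, lon.")
  }
  half <- span / 2
  tibble::tibble(
    id = as.character(rookeries$id),
    lat_min = rookeries$lat - half,
    lat_max = rookeries$lat + half,
    lon_min = wrap_lon(rookeries$lon - half),
    lon_max = wrap_lon(rookeries$lon + half)
  )
}

#' Define target regions as sets of boxes
#'
#' Target regions group feeding grounds with similar current exposure; each
#' region is a union of boxes (one row per box, regions may repeat). By
#' default each supplied feeding-ground point becomes a box of `radius`
#' degrees half-width.
#'
#' @param points tibble with columns `target`, `lat`, `lon`; one box per row.
#' @param radius half-width of each box in degrees (default 2).
#' @return tibble with columns `target`, `lat_min`, `lat_max`, `lon_min`,
#'   `lon_max`.
#' @export
target_boxes <- function(points, radius = 2) {
  if (!all(c("target", "lat", "lon") %in% names(points))) {
    abort("target points must have columns target, lat, lon.")
  }
  tibble::tibble(
    target = as.character(points$target),
    lat_min = points$lat - radius,
    lat_max = points$lat + radius,
    lon_min = wrap_lon(points$lon - radius),
    lon_max = wrap_lon(points$lon + radius)
  )
}

check_boxes <- function(boxes, what) {
  if (nrow(boxes) == 0) abort(sprintf("empty %s set.", what))
  if (any(boxes$lat_min >= boxes$lat_max)) {
    abort(sprintf("inverted latitude bounds in %s '%s'.",
                  what, boxes[[1]][boxes$lat_min >= boxes$lat_max][1]))
  }
  invisible(boxes)
}

# edge-inclusive membership; lon_min > lon_max means the box wraps the
# antimeridian
in_box <- function(lat, lon, lat_min, lat_max, lon_min, lon_max) {
  lat_ok <- lat >= lat_min & lat <= lat_max
  lon_ok <- if (lon_min <= lon_max) lon >= lon_min & lon <= lon_max
            else lon >= lon_min | lon <= lon_max
  lat_ok & lon_ok
}

#' Exclude short-lived drifters
#'
#' Drifters transmitting for less than three months carry too little
#' trajectory to inform connectivity and are excluded; the boundary is
#' inclusive (a lifespan of exactly `min_days` is retained).
#'
#' @param tracks a `drifter_tracks` tibble.
#' @param min_days minimum lifespan in days (default 90).
#' @return the retained `drifter_tracks`.
#' @export
filter_lifespan <- function(tracks, min_days = 90) {
  ls <- track_lifespans(tracks)
  keep <- ls$id[ls$days >= min_days]
  dropped <- setdiff(ls$id, keep)
  if (length(dropped)) {
    warn(sprintf("excluding %d drifter(s) with lifespan < %s days.", length(dropped), min_days))
  }
  out <- tracks[tracks$id %in% keep, ]
  class(out) <- class(tracks)
  out
}

#' Count box passages and subsequent target arrivals
#'
#' For each rookery box, counts the drifters whose trajectory enters it
#' (`n_r`, at most once per drifter) and, among those, the drifters with any
#' fix at or after the first in-box fix lying inside each target region
#' (`k_rt`). Arrival must follow passage: fixes inside a target before the
#' drifter ever enters the box do not count. A drifter may contribute to
#' several rookeries.
#'
#' @param tracks lifespan-filtered `drifter_tracks`.
#' @param boxes rookery boxes from [rookery_boxes()].
#' @param targets target boxes from [target_boxes()].
#' @return a `passage_counts` object: list with `n` (named integer vector
#'   per rookery) and `k` (rookeries x targets integer matrix).
#' @export
count_passages <- function(tracks, boxes, targets) {
  check_boxes(boxes, "rookery box")
  check_boxes(targets, "target region")
  rook_ids <- boxes$id
  targ_ids <- unique(targets$target)
  n <- setNames(integer(length(rook_ids)), rook_ids)
  k <- matrix(0L, length(rook_ids), length(targ_ids), dimnames = list(rook_ids, targ_ids))
  by_id <- split(seq_len(nrow(tracks)), tracks$id)
  for (rows in by_id) {
    lat <- tracks$lat[rows]; lon <- tracks$lon[rows]
    # membership of every fix in every target region (union over its boxes)
    tmem <- vapply(targ_ids, function(t) {
      tb <- targets[targets$target == t, ]
      Reduce(`|`, lapply(seq_len(nrow(tb)), function(b) {
        in_box(lat, lon, tb$lat_min[b], tb$lat_max[b], tb$lon_min[b], tb$lon_max[b])
      }))
    }, logical(length(lat)))
    tmem <- matrix(tmem, nrow = length(lat))
    for (r in seq_along(rook_ids)) {
      inb <- in_box(lat, lon, boxes$lat_min[r], boxes$lat_max[r],
                    boxes$lon_min[r], boxes$lon_max[r])
      if (!any(inb)) next
      entry <- which(inb)[1]
      n[r] <- n[r] + 1L
      after <- entry:length(lat)
      hit <- colSums(tmem[after, , drop = FALSE]) > 0
      k[r, hit] <- k[r, hit] + 1L
    }
  }
  structure(list(n = n, k = k), class = "passage_counts")
}

#' @export
print.passage_counts <- function(x, ...) {
  cat("# passage counts (n = drifters through box; k = subsequent arrivals)\n")
  print(cbind(n = x$n, x$k))
  invisible(x)
}

#' @export
tidy.passage_counts <- function(x, ...) {
  tibble::tibble(
    rookery = rep(rownames(x$k), times = ncol(x$k)),
    target = rep(colnames(x$k), each = nrow(x$k)),
    n = rep(unname(x$n), times = ncol(x$k)),
    k = as.integer(x$k)
  )
}

#' Bayesian drifter-based natal origin probabilities
#'
#' Combines passage/arrival counts with rookery size. The arrival
#' probability from rookery r to target t is given the posterior mean of a
#' Beta(1,1)-Binomial model, `a_rt = (k_rt + 1) / (n_r + 2)` (a rookery with
#' no long-lived drifters keeps the prior mean 1/2), and the origin
#' probability weights arrivals by rookery output:
#' `P(r | t) = a_rt * S_r / sum_r' a_r't * S_r'`.
#' The Beta smoothing guarantees every rookery strictly positive mass, so
#' rookeries with zero observed arrivals (e.g. distant ones no drifter
#' reached) still appear with small probabilities, as a finite drifter
#' sample cannot rule them out.
#'
#' @param counts a `passage_counts` object.
#' @param sizes rookery sizes: named numeric vector or tibble with `id`,
#'   `size` columns covering every rookery in `counts`.
#' @return an `origin_posterior`: list with `prob` (rookeries x targets,
#'   columns summing to 1), and the inputs `k`, `n`, `S` echoed.
#' @export
origin_posterior <- function(counts, sizes) {
  stopifnot(inherits(counts, "passage_counts"))
  rooks <- rownames(counts$k)
  if (length(rooks) == 0) abort("no rookeries in passage counts.")
  if (is.data.frame(sizes)) sizes <- setNames(sizes$size, sizes$id)
  miss <- setdiff(rooks, names(sizes))
  if (length(miss)) abort(paste0("missing size for rookery(ies): ", paste(miss, collapse = ", ")))
  S <- sizes[rooks]
  if (any(!is.finite(S)) || any(S <= 0)) abort("rookery sizes must be finite and strictly positive.")
  a_hat <- (counts$k + 1) / (counts$n + 2)
  w <- a_hat * S
  prob <- sweep(w, 2, colSums(w), "/")
  structure(list(prob = prob, k = counts$k, n = counts$n, S = S),
            class = "origin_posterior")
}

#' @export
print.origin_posterior <- function(x, ...) {
  cat("# drifter-based natal origin probabilities P(rookery | target)\n")
  print(round(x$prob, 3))
  invisible(x)
}

#' @export
tidy.origin_posterior <- function(x, ...) {
  tibble::tibble(
    rookery = rep(rownames(x$prob), times = ncol(x$prob)),
    target = rep(colnames(x$prob), each = nrow(x$prob)),
    k = as.integer(x$k),
    n = rep(unname(x$n), times = ncol(x$prob)),
    size = rep(unname(x$S), times = ncol(x$prob)),
    prob = as.numeric(x$prob)
  )
}
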