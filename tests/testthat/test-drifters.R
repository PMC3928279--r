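mk_tracks <- function(df) drifter_tracks(df)
ts0 <- function(days) as.POSIXct("2000-01-01", tz = "UTC") + days * 86400

test_that("rookery boxes span four degrees and contain their rookery", {
  rk <- tibble::tibble(id = c("r1", "r2"), lat = c(-12, 5), lon = c(-38, 179), size = c(10, 20))
  bx <- rookery_boxes(rk)
  expect_equal(bx$lat_max - bx$lat_min, c(4, 4))
  expect_true(all(in_box_chk <- mapply(function(i) {
    stockmix:::in_box(rk$lat[i], rk$lon[i], bx$lat_min[i], bx$lat_max[i],
                      bx$lon_min[i], bx$lon_max[i])
  }, seq_len(2))))
  # antimeridian wrap: box around lon 179 runs from 177 to -179
  expect_gt(bx$lon_min[2], bx$lon_max[2])
  expect_true(stockmix:::in_box(5, -179.5, bx$lat_min[2], bx$lat_max[2],
                                bx$lon_min[2], bx$lon_max[2]))
})

test_that("the lifespan filter is boundary-inclusive at the cutoff", {
  df <- dplyr::bind_rows(
    tibble::tibble(id = "short", timestamp = ts0(c(0, 60)), lat = 0, lon = 0),
    tibble::tibble(id = "exact", timestamp = ts0(c(0, 90)), lat = 0, lon = 0),
    tibble::tibble(id = "long", timestamp = ts0(c(0, 200)), lat = 0, lon = 0)
  )
  tr <- mk_tracks(df)
  expect_warning(kept <- filter_lifespan(tr, 90), "excluding 1")
  expect_setequal(unique(kept$id), c("exact", "long"))
  all_long <- mk_tracks(df[df$id != "short", ])
  expect_identical(nrow(filter_lifespan(all_long, 90)), nrow(all_long))
})

test_that("arrival must follow box passage", {
  boxes <- tibble::tibble(id = "A", lat_min = -2, lat_max = 2, lon_min = -2, lon_max = 2)
  targets <- tibble::tibble(target = "T", lat_min = 8, lat_max = 12, lon_min = -2, lon_max = 2)
  # enters box then target
  good <- mk_tracks(tibble::tibble(id = "d1", timestamp = ts0(0:2),
                                   lat = c(0, 5, 10), lon = 0))
  pc <- count_passages(good, boxes, targets)
  expect_equal(unname(pc$n["A"]), 1L)
  expect_equal(unname(pc$k["A", "T"]), 1L)
  # visits target first, then the box, never returns to the target
  bad <- mk_tracks(tibble::tibble(id = "d2", timestamp = ts0(0:2),
                                  lat = c(10, 5, 0), lon = 0))
  pc2 <- count_passages(bad, boxes, targets)
  expect_equal(unname(pc2$n["A"]), 1L)
  expect_equal(unname(pc2$k["A", "T"]), 0L)
  expect_error(count_passages(good, dplyr::mutate(boxes, lat_min = 5), targets), "inverted")
})

test_that("counting matches a brute-force per-fix membership scan", {
  set.seed(404)
  n_tracks <- 100
  rows <- lapply(seq_len(n_tracks), function(i) {
    n <- sample(10:30, 1)
    tibble::tibble(id = sprintf("d%03d", i), timestamp = ts0(seq_len(n)),
                   lat = cumsum(rnorm(n, 0, 3)), lon = cumsum(rnorm(n, 0, 3)))
  })
  tr <- mk_tracks(dplyr::bind_rows(rows))
  boxes <- tibble::tibble(id = c("A", "B"),
                          lat_min = c(-2, 3), lat_max = c(2, 7),
                          lon_min = c(-2, -10), lon_max = c(2, -6))
  targets <- tibble::tibble(target = c("T1", "T1", "T2"),
                            lat_min = c(5, -8, 0), lat_max = c(9, -4, 4),
                            lon_min = c(5, 0, 10), lon_max = c(9, 4, 14))
  pc <- count_passages(tr, boxes, targets)
  orc <- oracle_count_passages(tr, boxes, targets)
  expect_equal(pc$n, orc$n)
  expect_equal(pc$k, orc$k)
})

test_that("origin probabilities follow the smoothed size-weighted formula", {
  counts <- structure(list(n = c(A = 2L, B = 2L),
                           k = matrix(c(1L, 1L), 2, 1, dimnames = list(c("A", "B"), "T"))),
                      class = "passage_counts")
  op <- origin_posterior(counts, c(A = 2, B = 1))
  expect_equal(unname(op$prob[, "T"]), c(2 / 3, 1 / 3), tolerance = 1e-12)
  single <- structure(list(n = c(A = 5L),
                           k = matrix(3L, 1, 1, dimnames = list("A", "T"))),
                      class = "passage_counts")
  expect_equal(unname(origin_posterior(single, c(A = 7))$prob[1, 1]), 1)
})

test_that("zero-arrival rookeries keep strictly positive mass and columns normalize", {
  counts <- structure(list(n = c(A = 10L, B = 0L, C = 10L),
                           k = matrix(c(5L, 0L, 0L, 2L, 0L, 1L), 3, 2,
                                      dimnames = list(c("A", "B", "C"), c("T1", "T2")))),
                      class = "passage_counts")
  op <- origin_posterior(counts, c(A = 100, B = 50, C = 10))
  expect_true(all(op$prob > 0))
  expect_equal(unname(colSums(op$prob)), c(1, 1), tolerance = 1e-9)
})

test_that("P(r | t) is monotone in arrivals and in rookery size", {
  mk <- function(kA) structure(list(n = c(A = 10L, B = 10L),
                                    k = matrix(c(kA, 3L), 2, 1,
                                               dimnames = list(c("A", "B"), "T"))),
                               class = "passage_counts")
  p1 <- origin_posterior(mk(2L), c(A = 5, B = 5))$prob[1, 1]
  p2 <- origin_posterior(mk(4L), c(A = 5, B = 5))$prob[1, 1]
  expect_gt(p2, p1)
  q1 <- origin_posterior(mk(2L), c(A = 5, B = 5))$prob[1, 1]
  q2 <- origin_posterior(mk(2L), c(A = 9, B = 5))$prob[1, 1]
  expect_gt(q2, q1)
})

test_that("with no arrivals and equal passage counts the size-only limit is exact", {
  counts <- structure(list(n = c(A = 8L, B = 8L, C = 8L),
                           k = matrix(0L, 3, 1, dimnames = list(c("A", "B", "C"), "T"))),
                      class = "passage_counts")
  S <- c(A = 60, B = 30, C = 10)
  op <- origin_posterior(counts, S)
  expect_equal(unname(op$prob[, 1]), unname(S / sum(S)), tolerance = 1e-12)
  expect_error(origin_posterior(counts, c(A = 60, B = 30, C = -1)), "positive")
})
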