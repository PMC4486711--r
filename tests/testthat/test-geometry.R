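# Range geometry: areas, intersections, the overlap index and the
# bimodality statistic.

test_that("polygon areas follow the surveyor's formula and ignore orientation", {
  expect_equal(polygon_area(square_poly(0, 0, 1)), 1)
  expect_equal(
    polygon_area(range_polygon(c(0, 0, 1, 1), c(0, 1, 1, 0))), # reversed
    1
  )
  expect_equal(polygon_area(range_polygon(c(0, 4, 0), c(0, 0, 3))), 6)
  # non-convex L-shape: area by decomposition = 3
  expect_equal(
    polygon_area(range_polygon(
      c(0, 2, 2, 1, 1, 0), c(0, 0, 1, 1, 2, 2)
    )),
    3
  )
})

test_that("invalid rings are rejected", {
  expect_error(range_polygon(c(0, 1), c(0, 1)), "at least 3")
  expect_error(
    range_polygon(c(0, 1, 1, 0), c(0, 1, 0, 1)), # bow-tie
    "self-intersecting"
  )
  expect_error(range_polygon(c(0, 1, 2), c(0, 0, 0)), "zero area")
})

test_that("intersection areas are exact on known configurations", {
  sq <- square_poly(0, 0, 1)
  expect_equal(polygon_intersection_area(sq, sq), 1)
  expect_equal(
    polygon_intersection_area(sq, square_poly(0.5, 0, 1)), 0.5
  )
  expect_equal(
    polygon_intersection_area(sq, square_poly(5, 5, 1)), 0
  )
  # non-convex against convex: L-shape clipped by a unit square
  ell <- range_polygon(c(0, 2, 2, 1, 1, 0), c(0, 0, 1, 1, 2, 2))
  expect_equal(polygon_intersection_area(ell, square_poly(0, 0, 1)), 1)
  expect_equal(
    polygon_intersection_area(ell, square_poly(1, 1, 1)), 0
  )
})

test_that("polygon clipper matches the closed-form rectangle oracle", {
  set.seed(42)
  for (i in 1:200) {
    ra <- random_rect()
    rb <- random_rect()
    expect_equal(
      polygon_intersection_area(rect_as_poly(ra), rect_as_poly(rb)),
      rect_overlap_area(ra, rb),
      tolerance = 1e-10
    )
  }
})

test_that("intersection never exceeds the smaller area (random rectangles)", {
  set.seed(7)
  for (i in 1:100) {
    a <- rect_as_poly(random_rect())
    b <- rect_as_poly(random_rect())
    inter <- polygon_intersection_area(a, b)
    expect_lte(inter, min(polygon_area(a), polygon_area(b)) + 1e-12)
  }
})

test_that("overlap index is intersection over the smaller range", {
  expect_equal(overlap_index(10, 4, 2), 0.5)
  expect_equal(overlap_index(10, 4, 4), 1)
  expect_equal(overlap_index(10, 4, 0), 0)
  # symmetric under swapping the two areas
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 0.1, 10)
    b <- runif(1, 0.1, 10)
    x <- runif(1, 0, min(a, b))
    expect_equal(overlap_index(a, b, x), overlap_index(b, a, x))
  }
  expect_error(overlap_index(0, 4, 0), "positive")
  expect_error(overlap_index(10, 4, 5), "exceeds")
})

test_that("overlap classification uses strict 0.05 / 0.95 thresholds", {
  expect_equal(as.character(classify_overlap(0.04)), "allopatric")
  expect_equal(as.character(classify_overlap(0.96)), "sympatric")
  expect_equal(as.character(classify_overlap(0.5)), "partial")
  # boundary values are partial: the inequalities are strict
  expect_equal(as.character(classify_overlap(0.05)), "partial")
  expect_equal(as.character(classify_overlap(0.95)), "partial")
  expect_error(classify_overlap(1.2), "\\[0, 1\\]")
})

test_that("bimodality follows (z*c)/((n/2)^2) with real-valued n/2", {
  expect_equal(bimodality(7, 7, 22), 49 / 121)
  expect_equal(bimodality(8, 3, 20), 0.24)
  expect_equal(bimodality(0, 5, 10), 0)
  # odd n well-defined without truncation
  expect_equal(bimodality(2, 2, 5), 4 / 6.25)
  expect_error(bimodality(10, 11, 20), "exceeds")
  # bounded by 1, attained only at the even split
  set.seed(3)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    z <- sample(0:n, 1)
    cc <- sample(0:(n - z), 1)
    expect_lte(bimodality(z, cc, n), 1)
  }
  expect_equal(bimodality(11, 11, 22), 1)
})

test_that("summarize_overlaps counts extremes and scores bimodality", {
  s <- summarize_overlaps(c(1, 1, 0, 0))
  expect_equal(s$z, 2)
  expect_equal(s$c, 2)
  expect_equal(s$bimodality, 1)
  s2 <- summarize_overlaps(c(0.5, 0.5))
  expect_equal(s2$z + s2$c, 0)
  expect_equal(s2$bimodality, 0)
  # the relaxed-BSC configuration: 7 complete, 7 zero, 8 intermediate
  idx <- c(rep(0.99, 7), rep(0.01, 7), rep(0.5, 8))
  s3 <- summarize_overlaps(idx)
  expect_equal(s3$z, 7)
  expect_equal(s3$c, 7)
  expect_equal(round(s3$bimodality, 2), 0.40)
  expect_error(summarize_overlaps(numeric(0)), "empty")
})

test_that("pair_overlap and add_overlap wire geometry into pair tables", {
  po <- pair_overlap(square_poly(0, 0, 2), square_poly(1, 0, 1))
  expect_equal(po$overlap_index, 1) # smaller square nested
  expect_equal(as.character(po$category), "sympatric")

  pairs <- tibble::tibble(
    pair_id = c("p1", "p2"),
    species_a = c("a1", "a2"),
    species_b = c("b1", "b2"),
    branch_length_my = c(1, 2),
    overlap_index = c(0.5, NA)
  )
  polys <- list(
    a2 = square_poly(0, 0, 1, "a2"),
    b2 = square_poly(5, 5, 1, "b2")
  )
  out <- add_overlap(pairs, polys)
  expect_equal(out$overlap_index, c(0.5, 0))
  expect_equal(as.character(out$category), c("partial", "allopatric"))
  expect_error(add_overlap(pairs[2, 1:4]), "polygons")
})
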