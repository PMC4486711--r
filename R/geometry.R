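# Planar polygon geometry for species ranges.
#
# Ranges are simple rings (no holes, no self-intersection) in equal-area
# planar units; all projection work happens upstream. Intersection areas are
# computed exactly by ear-clipping each ring into triangles and clipping
# triangle pairs with Sutherland-Hodgman, so non-convex rings are handled.

#' Create a species range polygon
#'
#' Constructs a validated simple-ring polygon in planar equal-area
#' coordinates. The ring may be given open or closed (a repeated final
#' vertex is dropped) and in either orientation.
#'
#' @param x,y Numeric vectors of vertex coordinates (equal-area units).
#' @param species_id Optional species label attached to the polygon.
#' @return An object of class `range_polygon`: a list with `x`, `y`,
#'   `species_id`.
#' @examples
#' sq <- range_polygon(c(0, 1, 1, 0), c(0, 0, 1, 1), "sp1")
#' polygon_area(sq)
#' @export
range_polygon <- function(x, y, species_id = NA_character_) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("polygon coordinates must not contain NA", call. = FALSE)
  }
  n <- length(x)
  if (n >= 4 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]
    y <- y[-n]
    n <- n - 1
  }
  if (n < 3) {
    stop("invalid geometry: a polygon needs at least 3 distinct vertices",
      call. = FALSE
    )
  }
  poly <- structure(
    list(x = as.numeric(x), y = as.numeric(y), species_id = species_id),
    class = "range_polygon"
  )
  if (ring_self_intersects(poly)) {
    stop(
      "invalid geometry: self-intersecting ring",
      if (!is.na(species_id)) paste0(" for species '", species_id, "'") else "",
      call. = FALSE
    )
  }
  if (abs(signed_ring_area(poly$x, poly$y)) <= 0) {
    stop("invalid geometry: polygon has zero area", call. = FALSE)
  }
  poly
}

#' @export
print.range_polygon <- function(x, ...) {
  cat(
    "<range_polygon> ", length(x$x), " vertices, area ",
    format(polygon_area(x)),
    if (!is.na(x$species_id)) paste0(", species ", x$species_id) else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

as_range_polygon <- function(poly) {
  if (inherits(poly, "range_polygon")) return(poly)
  if (is.matrix(poly) && ncol(poly) == 2) {
    return(range_polygon(poly[, 1], poly[, 2]))
  }
  if (is.list(poly) && !is.null(poly$x) && !is.null(poly$y)) {
    return(range_polygon(poly$x, poly$y,
      species_id = poly$species_id %||% NA_character_
    ))
  }
  stop("cannot interpret input as a polygon", call. = FALSE)
}

signed_ring_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

# Segment-intersection test for ring validity: proper crossings between
# non-adjacent edges invalidate the ring. O(n^2), fine for range hulls.
ring_self_intersects <- function(poly) {
  x <- poly$x
  y <- poly$y
  n <- length(x)
  if (n <= 3) return(FALSE)
  j <- c(2:n, 1)
  ax <- x; ay <- y; bx <- x[j]; by <- y[j]
  cross2 <- function(ox, oy, px, py, qx, qy) {
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  }
  for (i in 1:(n - 1)) {
    for (k in (i + 1):n) {
      # skip adjacent edges (shared vertex)
      if (k == i || k == i %% n + 1 || i == k %% n + 1) next
      d1 <- cross2(ax[i], ay[i], bx[i], by[i], ax[k], ay[k])
      d2 <- cross2(ax[i], ay[i], bx[i], by[i], bx[k], by[k])
      d3 <- cross2(ax[k], ay[k], bx[k], by[k], ax[i], ay[i])
      d4 <- cross2(ax[k], ay[k], bx[k], by[k], bx[i], by[i])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Polygon area by the surveyor's formula
#'
#' @param poly A [range_polygon()], a two-column matrix of vertices, or a
#'   list with `x` and `y`.
#' @return Nonnegative area in squared input units; independent of vertex
#'   orientation.
#' @examples
#' polygon_area(range_polygon(c(0, 4, 0), c(0, 0, 3)))
#' @export
polygon_area <- function(poly) {
  poly <- as_range_polygon(poly)
  abs(signed_ring_area(poly$x, poly$y))
}

# Ensure counter-clockwise orientation.
ccw_ring <- function(x, y) {
  if (signed_ring_area(x, y) < 0) list(x = rev(x), y = rev(y)) else list(x = x, y = y)
}

# Signed fan decomposition of a simple CCW ring: the ring's indicator
# function equals the sum of the signed fan triangles (v1, vi, vi+1), so
# intersection areas can be computed pairwise on convex triangles.
# Returns a list of elements list(tri = 3x2 CCW matrix, sign = +1/-1);
# zero-area (collinear) fan triangles are dropped.
fan_decompose <- function(x, y) {
  r <- ccw_ring(x, y)
  x <- r$x; y <- r$y
  n <- length(x)
  tol <- 1e-14 * max(1, max(abs(x)), max(abs(y)))^2
  out <- list()
  for (i in 2:(n - 1)) {
    sa <- signed_ring_area(c(x[1], x[i], x[i + 1]), c(y[1], y[i], y[i + 1]))
    if (abs(sa) <= tol) next
    tri <- cbind(c(x[1], x[i], x[i + 1]), c(y[1], y[i], y[i + 1]))
    if (sa < 0) tri <- tri[c(1, 3, 2), ] # orient CCW for clipping
    out[[length(out) + 1L]] <- list(tri = tri, sign = sign(sa))
  }
  out
}

# Sutherland-Hodgman: clip an arbitrary subject polygon (CCW matrix) by a
# convex CCW clip polygon. Returns a vertex matrix (possibly with < 3 rows).
clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) == 0) return(out)
    cx1 <- clip[e, 1]; cy1 <- clip[e, 2]
    cx2 <- clip[e %% nc + 1, 1]; cy2 <- clip[e %% nc + 1, 2]
    ex <- cx2 - cx1; ey <- cy2 - cy1
    sx <- out[, 1]; sy <- out[, 2]
    side <- ex * (sy - cy1) - ey * (sx - cx1) # >= 0 is inside for CCW clip
    n <- nrow(out)
    nxt <- c(2:n, 1)[seq_len(n)]
    if (n == 1) nxt <- 1L
    newx <- numeric(0); newy <- numeric(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      in_i <- side[i] >= 0
      in_j <- side[j] >= 0
      if (in_i) {
        newx <- c(newx, sx[i]); newy <- c(newy, sy[i])
      }
      if (xor(in_i, in_j)) {
        t <- side[i] / (side[i] - side[j])
        newx <- c(newx, sx[i] + t * (sx[j] - sx[i]))
        newy <- c(newy, sy[i] + t * (sy[j] - sy[i]))
      }
    }
    out <- cbind(newx, newy)
  }
  out
}

#' Area of intersection of two range polygons
#'
#' Both rings are triangulated (ear clipping) and every triangle pair is
#' clipped exactly, so the result is exact for simple rings, convex or not.
#' Disjoint polygons give 0.
#'
#' @param a,b Polygons as in [polygon_area()].
#' @return Nonnegative intersection area.
#' @examples
#' sq <- range_polygon(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' sq2 <- range_polygon(c(0.5, 1.5, 1.5, 0.5), c(0, 0, 1, 1))
#' polygon_intersection_area(sq, sq2)
#' @export
polygon_intersection_area <- function(a, b) {
  a <- as_range_polygon(a)
  b <- as_range_polygon(b)
  # quick bounding-box rejection
  if (max(a$x) <= min(b$x) || max(b$x) <= min(a$x) ||
      max(a$y) <= min(b$y) || max(b$y) <= min(a$y)) {
    return(0)
  }
  tris_a <- fan_decompose(a$x, a$y)
  tris_b <- fan_decompose(b$x, b$y)
  total <- 0
  for (ta in tris_a) {
    for (tb in tris_b) {
      clipped <- clip_convex(ta$tri, tb$tri)
      if (!is.null(nrow(clipped)) && nrow(clipped) >= 3) {
        total <- total + ta$sign * tb$sign *
          abs(signed_ring_area(clipped[, 1], clipped[, 2]))
      }
    }
  }
  max(total, 0)
}

#' Range-overlap index
#'
#' The area of sympatry divided by the area of the smaller of the two
#' species ranges, giving a fraction between 0 (disjoint) and 1 (the smaller
#' range is entirely nested within the larger).
#'
#' @param area_a,area_b Positive range areas.
#' @param area_intersection Intersection area, at most `min(area_a, area_b)`.
#' @return Overlap fraction in \[0, 1\]. Vectorised over its arguments.
#' @examples
#' overlap_index(10, 4, 2)
#' @export
overlap_index <- function(area_a, area_b, area_intersection) {
  if (any(area_a <= 0) || any(area_b <= 0)) {
    stop("range areas must be positive", call. = FALSE)
  }
  if (any(area_intersection < 0)) {
    stop("intersection area must be nonnegative", call. = FALSE)
  }
  smaller <- pmin(area_a, area_b)
  if (any(area_intersection > smaller * (1 + 1e-9))) {
    stop("inconsistent areas: intersection exceeds the smaller range",
      call. = FALSE
    )
  }
  pmin(area_intersection / smaller, 1)
}

#' Classify an overlap index as allopatric, partial or sympatric
#'
#' Indices below 0.05 count as complete allopatry and above 0.95 as complete
#' sympatry, absorbing sampling incompleteness and small mapping errors at
#' the extremes; the thresholds are strict, so exactly 0.05 or 0.95 is
#' partial.
#'
#' @param index Numeric vector of overlap fractions in \[0, 1\].
#' @param allopatry,sympatry Classification thresholds.
#' @return A factor with levels `allopatric`, `partial`, `sympatric`.
#' @examples
#' classify_overlap(c(0.04, 0.5, 0.96))
#' @export
classify_overlap <- function(index, allopatry = 0.05, sympatry = 0.95) {
  if (any(is.na(index)) || any(index < 0) || any(index > 1)) {
    stop("overlap index must lie in [0, 1]", call. = FALSE)
  }
  out <- ifelse(index < allopatry, "allopatric",
    ifelse(index > sympatry, "sympatric", "partial")
  )
  factor(out, levels = c("allopatric", "partial", "sympatric"))
}

#' Bimodality of an overlap distribution
#'
#' Computes (z * c) / (a * b), where `z` and `c` count completely sympatric
#' and completely allopatric pairs and `a = b = n/2` are the counts that
#' would occur were the data split evenly between the two extreme states.
#' The score is 0 when either extreme is empty and reaches 1 only when the
#' pairs divide exactly evenly between complete sympatry and complete
#' allopatry. `n/2` is real-valued, so odd `n` is well defined.
#'
#' @param z Number of completely sympatric pairs (index > 0.95).
#' @param c Number of completely allopatric pairs (index < 0.05).
#' @param n Total number of sister pairs.
#' @return Bimodality score in \[0, 1\]. Vectorised.
#' @examples
#' bimodality(7, 7, 22)
#' bimodality(8, 3, 20)
#' @export
bimodality <- function(z, c, n) {
  if (any(n < 1)) stop("`n` must be at least 1", call. = FALSE)
  if (any(z < 0) || any(c < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(z + c > n)) {
    stop("inconsistent counts: z + c exceeds n", call. = FALSE)
  }
  (z * c) / ((n / 2) * (n / 2))
}

#' Summarise a set of overlap indices
#'
#' Counts completely sympatric and completely allopatric pairs and computes
#' the bimodality score of the distribution.
#'
#' @param indices Numeric vector of overlap fractions in \[0, 1\], one per
#'   sister pair. A data frame with an `overlap_index` column is also
#'   accepted.
#' @return A one-row tibble with columns `n`, `z` (complete sympatry),
#'   `c` (complete allopatry) and `bimodality`.
#' @examples
#' summarize_overlaps(c(1, 1, 0, 0))
#' @export
summarize_overlaps <- function(indices) {
  if (is.data.frame(indices)) {
    if (!"overlap_index" %in% names(indices)) {
      stop("data frame input needs an `overlap_index` column", call. = FALSE)
    }
    indices <- indices$overlap_index
  }
  if (length(indices) == 0) {
    stop("cannot summarise an empty set of overlap indices", call. = FALSE)
  }
  cls <- classify_overlap(indices)
  n <- length(indices)
  z <- sum(cls == "sympatric")
  cc <- sum(cls == "allopatric")
  tibble::tibble(n = n, z = z, c = cc, bimodality = bimodality(z, cc, n))
}

#' Pairwise overlap of two range polygons
#'
#' Convenience wrapper computing both areas, the intersection area, the
#' overlap index and its classification in one call.
#'
#' @param a,b Polygons as in [polygon_area()].
#' @return A one-row tibble with columns `area_a`, `area_b`,
#'   `area_intersection`, `overlap_index`, `category`.
#' @export
pair_overlap <- function(a, b) {
  a <- as_range_polygon(a)
  b <- as_range_polygon(b)
  area_a <- polygon_area(a)
  area_b <- polygon_area(b)
  inter <- polygon_intersection_area(a, b)
  idx <- overlap_index(area_a, area_b, inter)
  tibble::tibble(
    area_a = area_a, area_b = area_b, area_intersection = inter,
    overlap_index = idx, category = classify_overlap(idx)
  )
}

#' Add overlap indices and categories to a sister-pair table
#'
#' For rows that already carry an `overlap_index` the value is kept; rows
#' with polygons in `polygons` (keyed by `species_a` / `species_b`) get
#' their index computed from geometry. A `category` column is (re)derived
#' for every row.
#'
#' @param pairs A sister-pair data frame with columns `pair_id`,
#'   `species_a`, `species_b` and optionally `overlap_index`.
#' @param polygons Optional named list of [range_polygon()] objects, e.g.
#'   from [read_polygons()].
#' @return The input as a tibble with `overlap_index` and `category` filled.
#' @export
add_overlap <- function(pairs, polygons = NULL) {
  pairs <- tibble::as_tibble(pairs)
  if (!"overlap_index" %in% names(pairs)) pairs$overlap_index <- NA_real_
  need <- which(is.na(pairs$overlap_index))
  if (length(need) > 0) {
    if (is.null(polygons)) {
      stop("rows without `overlap_index` need `polygons`", call. = FALSE)
    }
    for (i in need) {
      sa <- pairs$species_a[i]
      sb <- pairs$species_b[i]
      if (!sa %in% names(polygons) || !sb %in% names(polygons)) {
        stop("no polygon for species '", setdiff(c(sa, sb), names(polygons))[1],
          "' (pair ", pairs$pair_id[i], ")",
          call. = FALSE
        )
      }
      pairs$overlap_index[i] <-
        pair_overlap(polygons[[sa]], polygons[[sb]])$overlap_index
    }
  }
  pairs$category <- classify_overlap(pairs$overlap_index)
  pairs
}
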