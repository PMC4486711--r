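# Shared fixtures, all built in code.

square_poly <- function(x0, y0, side, species_id = NA_character_) {
  range_polygon(
    c(x0, x0 + side, x0 + side, x0),
    c(y0, y0, y0 + side, y0 + side),
    species_id = species_id
  )
}

rect_poly <- function(x0, y0, w, h, species_id = NA_character_) {
  range_polygon(
    c(x0, x0 + w, x0 + w, x0),
    c(y0, y0, y0 + h, y0 + h),
    species_id = species_id
  )
}

# closed-form overlap area of two axis-aligned rectangles, the independent
# oracle for the polygon clipper
rect_overlap_area <- function(a, b) {
  max(0, min(a[2], b[2]) - max(a[1], b[1])) *
    max(0, min(a[4], b[4]) - max(a[3], b[3]))
}

random_rect <- function() {
  x0 <- runif(1, -5, 5)
  y0 <- runif(1, -5, 5)
  c(x0, x0 + runif(1, 0.1, 6), y0, y0 + runif(1, 0.1, 6)) # (x0,x1,y0,y1)
}

rect_as_poly <- function(r) {
  rect_poly(r[1], r[3], r[2] - r[1], r[4] - r[3])
}

# uniform points inside a tetrahedron-free convex body: sample a gaussian
# cloud; used to build random niche polyhedra
random_cloud <- function(n = 40, scale = 1) {
  matrix(rnorm(3 * n, sd = scale), ncol = 3)
}

# Monte-Carlo rejection estimate of the volume of {x: normals x <= offsets}
# inside a bounding box; independent oracle for the exact polytope volumes
mc_volume <- function(normals, offsets, lower, upper, n = 2e5) {
  pts <- cbind(
    runif(n, lower[1], upper[1]),
    runif(n, lower[2], upper[2]),
    runif(n, lower[3], upper[3])
  )
  inside <- rowSums(pts %*% t(normals) > rep(offsets, each = n)) == 0
  mean(inside) * prod(upper - lower)
}

quiet_consistency <- function(...) {
  suppressWarnings(percentile_consistency(...))
}
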