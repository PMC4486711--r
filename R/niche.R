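# Climatic niche quantification: PCA of bioclim-like layers on the
# correlation matrix, species niches as minimum convex polyhedra of 3-D
# principal-component scores, and niche overlap as the exact intersection
# volume of two convex polyhedra.
#
# Convex hulls are found by brute-force face enumeration (every point
# triple whose plane supports all points is a hull face), which is exact
# and vectorises well at the few-hundred-point scale of species occurrence
# clouds. Intersection volumes come from halfspace intersection: candidate
# vertices are the feasible intersections of plane triples, and the volume
# of a convex body given its vertices and face planes is summed over
# face-pyramids.

#' Principal components of a climate layer stack
#'
#' Standardises every variable to zero mean and unit variance over grid
#' cells (i.e. a PCA on the correlation matrix) and retains the first
#' `n_components` component scores per cell.
#'
#' @param layers Either a matrix/data frame of cells x variables or a 3-D
#'   array (rows x cols x variables) such as the `layers` element of
#'   [gen_raster_stack()].
#' @param n_components Number of components to retain (3, matching a
#'   3-D niche space).
#' @return A list of class `climate_pca`: `loadings` (variables x
#'   components), `scores` (cells x components), `variance_explained`
#'   (proportion per retained component), `sdev` (all singular values /
#'   sqrt(n-1)), and `center`/`scale` used for standardisation.
#' @export
pca_correlation <- function(layers, n_components = 3) {
  x <- as_layer_matrix(layers)
  if (ncol(x) < 3) stop("need at least 3 variables", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant layer: ", paste(colnames(x)[sds == 0], collapse = ", "),
      call. = FALSE
    )
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  k <- min(n_components, ncol(x))
  structure(
    list(
      loadings = p$rotation[, seq_len(k), drop = FALSE],
      scores = p$x[, seq_len(k), drop = FALSE],
      variance_explained = ve[seq_len(k)],
      variance_explained_all = ve,
      sdev = p$sdev,
      center = p$center,
      scale = p$scale,
      rotation_full = p$rotation
    ),
    class = "climate_pca"
  )
}

as_layer_matrix <- function(layers) {
  if (is.array(layers) && length(dim(layers)) == 3) {
    d <- dim(layers)
    x <- matrix(layers, nrow = d[1] * d[2], ncol = d[3])
    colnames(x) <- dimnames(layers)[[3]] %||% paste0("bio", seq_len(d[3]))
    return(x)
  }
  x <- as.matrix(layers)
  if (is.null(colnames(x))) colnames(x) <- paste0("bio", seq_len(ncol(x)))
  x
}

#' @export
print.climate_pca <- function(x, ...) {
  cat(
    "<climate_pca> ", length(x$center), " variables, ",
    nrow(x$scores), " cells; first ", ncol(x$scores),
    " components explain ",
    sprintf("%.1f%%", 100 * sum(x$variance_explained)), "\n",
    sep = ""
  )
  invisible(x)
}

#' @method tidy climate_pca
#' @export
tidy.climate_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$variance_explained_all),
    sdev = x$sdev,
    variance_explained = x$variance_explained_all,
    cumulative = cumsum(x$variance_explained_all)
  )
}

# --- convex polytope machinery -------------------------------------------

# Face planes of the convex hull of an n x 3 point matrix, by brute-force
# triple enumeration. Returns list(normals = m x 3 unit outward normals,
# offsets = m, so the hull is {x : normals %*% x <= offsets}).
hull_planes <- function(points, tol = 1e-9) {
  pts <- unique(round(points, 12))
  n <- nrow(pts)
  if (n < 4) stop("degenerate niche: fewer than 4 distinct points",
    call. = FALSE
  )
  ctr <- colMeans(pts)
  centered <- sweep(pts, 2, ctr)
  if (qr(centered)$rank < 3) {
    stop("degenerate niche: points are coplanar or collinear", call. = FALSE)
  }
  if (n > 80) return(hull_planes_large(pts, tol))
  hull_planes_brute(pts, tol)
}

# Exact hull of a large cloud: start from the extreme points along a fixed
# set of directions, build the hull of that candidate set, then fold in any
# point left outside and repeat. Terminates with every point inside, i.e.
# the true hull.
hull_planes_large <- function(pts, tol = 1e-9) {
  set.seed_free_dirs <- function(k) {
    # deterministic quasi-random directions: no RNG state touched
    i <- seq_len(k)
    phi <- acos(1 - 2 * (i - 0.5) / k)
    theta <- pi * (1 + sqrt(5)) * i
    cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  }
  dirs <- rbind(diag(3), -diag(3), set.seed_free_dirs(60))
  proj <- pts %*% t(dirs)
  cand <- sort(unique(c(
    apply(proj, 2, which.max), apply(proj, 2, which.min)
  )))
  scale <- max(1, max(abs(pts)))
  repeat {
    hp <- hull_planes_brute(pts[cand, , drop = FALSE], tol)
    slack <- pts %*% t(hp$normals) - rep(hp$offsets, each = nrow(pts))
    worst <- apply(slack, 1, max)
    outside <- which(worst > tol * scale)
    outside <- setdiff(outside, cand)
    if (length(outside) == 0) {
      hp$points <- pts
      return(hp)
    }
    # add the most violating points first to keep the candidate set lean
    add <- outside[order(worst[outside], decreasing = TRUE)]
    cand <- sort(union(cand, utils::head(add, 40)))
  }
}

hull_planes_brute <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  tri <- utils::combn(n, 3)
  p1 <- pts[tri[1, ], , drop = FALSE]
  p2 <- pts[tri[2, ], , drop = FALSE]
  p3 <- pts[tri[3, ], , drop = FALSE]
  u <- p2 - p1
  v <- p3 - p1
  nx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  ny <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  nz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  nrm <- sqrt(nx^2 + ny^2 + nz^2)
  ok <- nrm > tol * max(1, max(abs(pts)))^2
  if (!any(ok)) stop("degenerate niche: all point triples collinear",
    call. = FALSE
  )
  normals <- cbind(nx, ny, nz)[ok, , drop = FALSE] / nrm[ok]
  d <- rowSums(normals * p1[ok, , drop = FALSE])
  # supporting planes: all points on one side (chunked for memory)
  scale <- max(1, max(abs(pts)))
  keep <- logical(nrow(normals))
  flip <- logical(nrow(normals))
  chunk <- 20000L
  for (s in seq(1, nrow(normals), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(normals))
    sgn <- normals[s:e, , drop = FALSE] %*% t(pts) - d[s:e]
    above <- rowSums(sgn > tol * scale) # points strictly outside
    below <- rowSums(sgn < -tol * scale)
    keep[s:e] <- above == 0 | below == 0
    flip[s:e] <- above > 0 # outward normal points the other way
  }
  normals <- normals[keep, , drop = FALSE]
  d <- d[keep]
  fl <- flip[keep]
  normals[fl, ] <- -normals[fl, , drop = FALSE]
  d[fl] <- -d[fl]
  # dedupe coplanar faces (several triples can define one face)
  key <- paste(
    round(normals[, 1], 8), round(normals[, 2], 8),
    round(normals[, 3], 8), round(d, 8)
  )
  first <- !duplicated(key)
  list(
    normals = normals[first, , drop = FALSE],
    offsets = d[first],
    points = pts
  )
}

# Volume of a convex polytope given its vertices (k x 3) and supporting
# planes: sum of pyramids from the centroid over the face polygons.
polytope_volume <- function(vertices, normals, offsets, tol = 1e-8) {
  if (nrow(vertices) < 4) return(0)
  ctr <- colMeans(vertices)
  scale <- max(1, max(abs(vertices)))
  vol <- 0
  dists <- vertices %*% t(normals) - rep(offsets, each = nrow(vertices))
  for (f in seq_len(nrow(normals))) {
    on_face <- abs(dists[, f]) < tol * scale
    if (sum(on_face) < 3) next
    fv <- vertices[on_face, , drop = FALSE]
    nrm <- normals[f, ]
    h <- sum(nrm * (fv[1, ] - ctr)) # centroid-to-plane distance
    if (h <= 0) next # centroid on or outside the plane: degenerate
    # order face vertices by angle in the face plane
    fc <- colMeans(fv)
    a1 <- fv[1, ] - fc
    a1 <- a1 - sum(a1 * nrm) * nrm
    if (sqrt(sum(a1^2)) < tol * scale) a1 <- fv[2, ] - fc
    a1 <- a1 / sqrt(sum(a1^2))
    a2 <- c(
      nrm[2] * a1[3] - nrm[3] * a1[2],
      nrm[3] * a1[1] - nrm[1] * a1[3],
      nrm[1] * a1[2] - nrm[2] * a1[1]
    )
    rel <- sweep(fv, 2, fc)
    ang <- atan2(rel %*% a2, rel %*% a1)
    ord <- order(ang)
    xy <- cbind(rel %*% a1, rel %*% a2)[ord, , drop = FALSE]
    area <- abs(signed_ring_area(xy[, 1], xy[, 2]))
    vol <- vol + area * h / 3
  }
  vol
}

#' Minimum convex polyhedron of a species' niche scores
#'
#' The convex hull of a species' 3-D principal-component climate scores,
#' with its volume. At least four points in general position are required;
#' coplanar or collinear clouds are rejected as degenerate.
#'
#' @param points An n x 3 matrix (or data frame) of PC scores.
#' @return An object of class `niche_polyhedron` with elements `vertices`
#'   (hull vertices), `normals` / `offsets` (supporting halfspaces
#'   `normals %*% x <= offsets`) and `volume`.
#' @examples
#' cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
#' niche_polyhedron(cube)$volume
#' @export
niche_polyhedron <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be 3-dimensional", call. = FALSE)
  if (anyNA(points)) stop("points must not contain NA", call. = FALSE)
  hp <- hull_planes(points)
  dists <- hp$points %*% t(hp$normals) - rep(hp$offsets, each = nrow(hp$points))
  tol <- 1e-8 * max(1, max(abs(hp$points)))
  on_any <- rowSums(abs(dists) < tol) >= 3 # hull vertices sit on >= 3 faces
  vertices <- hp$points[on_any, , drop = FALSE]
  vol <- polytope_volume(vertices, hp$normals, hp$offsets)
  if (vol <= 0) stop("degenerate niche: zero hull volume", call. = FALSE)
  structure(
    list(
      vertices = vertices,
      normals = hp$normals,
      offsets = hp$offsets,
      volume = vol
    ),
    class = "niche_polyhedron"
  )
}

#' @export
print.niche_polyhedron <- function(x, ...) {
  cat(
    "<niche_polyhedron> ", nrow(x$vertices), " vertices, ",
    nrow(x$normals), " faces, volume ", format(x$volume), "\n",
    sep = ""
  )
  invisible(x)
}

#' Climatic niche overlap of two convex polyhedra
#'
#' Intersection volume over the volume of the smaller polyhedron. The
#' intersection is computed exactly by halfspace intersection: the
#' candidate vertices are the feasible intersections of all plane triples
#' drawn from both hulls' supporting planes.
#'
#' @param p,q `niche_polyhedron` objects.
#' @return Overlap fraction in \[0, 1\]; 0 for disjoint niches.
#' @export
polyhedron_overlap <- function(p, q) {
  stopifnot(
    inherits(p, "niche_polyhedron"),
    inherits(q, "niche_polyhedron")
  )
  vol <- halfspace_intersection_volume(
    rbind(p$normals, q$normals), c(p$offsets, q$offsets)
  )
  min(1, vol / min(p$volume, q$volume))
}

# Volume of {x : normals %*% x <= offsets} via vertex enumeration over
# plane triples (vectorised cross products), assuming the region is bounded.
halfspace_intersection_volume <- function(normals, offsets, tol = 1e-8) {
  # dedupe coincident planes (e.g. faces shared by both hulls) so each
  # face contributes exactly one pyramid to the volume
  key <- paste(
    round(normals[, 1], 8), round(normals[, 2], 8),
    round(normals[, 3], 8), round(offsets, 8)
  )
  first <- !duplicated(key)
  normals <- normals[first, , drop = FALSE]
  offsets <- offsets[first]
  m <- nrow(normals)
  if (m < 4) return(0)
  tri <- utils::combn(m, 3)
  n1 <- normals[tri[1, ], , drop = FALSE]
  n2 <- normals[tri[2, ], , drop = FALSE]
  n3 <- normals[tri[3, ], , drop = FALSE]
  d1 <- offsets[tri[1, ]]
  d2 <- offsets[tri[2, ]]
  d3 <- offsets[tri[3, ]]
  cr <- function(a, b) {
    cbind(
      a[, 2] * b[, 3] - a[, 3] * b[, 2],
      a[, 3] * b[, 1] - a[, 1] * b[, 3],
      a[, 1] * b[, 2] - a[, 2] * b[, 1]
    )
  }
  c23 <- cr(n2, n3)
  det <- rowSums(n1 * c23)
  ok <- abs(det) > tol
  if (!any(ok)) return(0)
  c31 <- cr(n3, n1)[ok, , drop = FALSE]
  c12 <- cr(n1, n2)[ok, , drop = FALSE]
  x <- (d1[ok] * c23[ok, , drop = FALSE] + d2[ok] * c31 + d3[ok] * c12) /
    det[ok]
  # feasibility check in chunks
  scale <- max(1, max(abs(offsets)))
  feas <- logical(nrow(x))
  chunk <- 50000L
  for (s in seq(1, nrow(x), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(x))
    slack <- x[s:e, , drop = FALSE] %*% t(normals) -
      rep(offsets, each = e - s + 1L)
    feas[s:e] <- rowSums(slack > tol * scale) == 0
  }
  v <- unique(round(x[feas, , drop = FALSE], 9))
  if (nrow(v) < 4) return(0)
  ctr <- colMeans(v)
  if (qr(sweep(v, 2, ctr))$rank < 3) return(0)
  polytope_volume(v, normals, offsets)
}

#' Species niche polyhedra from occurrences and a PCA
#'
#' Looks up each species' occurrence cells in the PCA score matrix and
#' builds the minimum convex polyhedron of its scores.
#'
#' @param occurrences A data frame with columns `species` and `cell` (row
#'   index into `pca$scores`).
#' @param pca A [pca_correlation()] result.
#' @return A named list of `niche_polyhedron` objects, one per species.
#' @export
species_niches <- function(occurrences, pca) {
  stopifnot(all(c("species", "cell") %in% names(occurrences)))
  split(occurrences$cell, occurrences$species) |>
    purrr::map(function(cells) {
      niche_polyhedron(pca$scores[cells, , drop = FALSE])
    })
}

#' Pairwise climatic niche overlap for a sister-pair table
#'
#' @param pairs A data frame with columns `species_a`, `species_b`.
#' @param niches Named list of `niche_polyhedron` objects (see
#'   [species_niches()]).
#' @return The pair table with a `climate_overlap` column appended.
#' @export
add_climate_overlap <- function(pairs, niches) {
  pairs <- tibble::as_tibble(pairs)
  pairs$climate_overlap <- purrr::map2_dbl(
    pairs$species_a, pairs$species_b,
    function(a, b) {
      if (!a %in% names(niches) || !b %in% names(niches)) return(NA_real_)
      polyhedron_overlap(niches[[a]], niches[[b]])
    }
  )
  pairs
}
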