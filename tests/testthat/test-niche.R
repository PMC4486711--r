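# Climatic niche space: PCA on the correlation matrix, convex polyhedra
# and their intersection volumes.

test_that("PCA on perfectly correlated variables loads one component", {
  set.seed(24)
  base <- rnorm(300)
  x <- cbind(a = base, b = 2 * base + 5, c = -base)
  p <- pca_correlation(x)
  expect_equal(p$variance_explained[1], 1, tolerance = 1e-9)
})

test_that("PCA variance fractions match a brute-force eigen oracle", {
  set.seed(25)
  x <- matrix(rnorm(200 * 6), 200, 6) %*% matrix(runif(36, -1, 1), 6, 6)
  p <- pca_correlation(x, n_components = 3)
  z <- scale(x)
  ev <- eigen(crossprod(z) / (nrow(z) - 1), symmetric = TRUE)$values
  expect_equal(
    p$variance_explained_all, ev / sum(ev),
    tolerance = 1e-8
  )
})

test_that("full-rank scores reconstruct the standardised data", {
  set.seed(26)
  x <- matrix(rnorm(100 * 5), 100, 5)
  p <- pca_correlation(x, n_components = 5)
  z <- scale(x)
  recon <- p$scores %*% t(p$rotation_full[, 1:5])
  expect_equal(unname(recon), unname(z[, ]), tolerance = 1e-8)
})

test_that("independent layers spread variance nearly evenly", {
  set.seed(27)
  x <- matrix(rnorm(4000 * 10), 4000, 10)
  p <- pca_correlation(x)
  expect_true(all(abs(p$variance_explained_all - 0.1) < 0.03))
})

test_that("constant layers are rejected by name", {
  x <- cbind(bio1 = rnorm(50), bio2 = rep(1, 50), bio3 = rnorm(50))
  expect_error(pca_correlation(x), "bio2")
})

test_that("hull volume is exact on the unit cube and ignores interior points", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  ph <- niche_polyhedron(cube)
  expect_equal(ph$volume, 1, tolerance = 1e-9)
  set.seed(28)
  inside <- matrix(runif(60, 0.1, 0.9), ncol = 3)
  ph2 <- niche_polyhedron(rbind(cube, inside))
  expect_equal(ph2$volume, 1, tolerance = 1e-9)
})

test_that("degenerate point sets are rejected", {
  flat <- cbind(runif(10), runif(10), 0)
  expect_error(niche_polyhedron(flat), "degenerate")
  expect_error(niche_polyhedron(matrix(rnorm(9), 3, 3)), "degenerate")
})

test_that("hull volume matches a Monte-Carlo rejection oracle within 2%", {
  set.seed(29)
  for (i in 1:3) {
    pts <- random_cloud(40)
    ph <- niche_polyhedron(pts)
    lo <- apply(pts, 2, min)
    hi <- apply(pts, 2, max)
    mc <- mc_volume(ph$normals, ph$offsets, lo, hi, n = 4e5)
    expect_equal(ph$volume, mc, tolerance = 0.02)
  }
})

test_that("polyhedron overlap handles identity, nesting and known offsets", {
  cube <- niche_polyhedron(as.matrix(expand.grid(0:1, 0:1, 0:1)))
  expect_equal(polyhedron_overlap(cube, cube), 1, tolerance = 1e-9)
  half <- niche_polyhedron(
    as.matrix(expand.grid(c(0.25, 0.75), c(0.25, 0.75), c(0.25, 0.75)))
  )
  expect_equal(polyhedron_overlap(cube, half), 1, tolerance = 1e-9)
  shifted <- niche_polyhedron(
    as.matrix(expand.grid(c(0.5, 1.5), 0:1, 0:1))
  )
  expect_equal(polyhedron_overlap(cube, shifted), 0.5, tolerance = 1e-9)
  far <- niche_polyhedron(as.matrix(expand.grid(5:6, 5:6, 5:6)))
  expect_equal(polyhedron_overlap(cube, far), 0)
})

test_that("intersection volume matches the Monte-Carlo oracle within 2%", {
  set.seed(30)
  for (i in 1:3) {
    a <- niche_polyhedron(random_cloud(30))
    b <- niche_polyhedron(random_cloud(30) + 0.3)
    normals <- rbind(a$normals, b$normals)
    offsets <- c(a$offsets, b$offsets)
    exact <- sympatry:::halfspace_intersection_volume(normals, offsets)
    pts <- rbind(a$vertices, b$vertices)
    lo <- apply(pts, 2, min)
    hi <- apply(pts, 2, max)
    mc <- mc_volume(normals, offsets, lo, hi, n = 4e5)
    if (mc > 0.05) {
      expect_equal(exact, mc, tolerance = 0.02)
    } else {
      expect_lt(abs(exact - mc), 0.01)
    }
  }
})

test_that("species niches and pairwise overlap wire into pair tables", {
  set.seed(34)
  stack <- gen_raster_stack(
    n_layers = 6, grid_shape = c(40, 40), cross_corr = 0.5,
    species_boxes = list(
      s1 = c(5, 20, 5, 20), s2 = c(5, 20, 5, 20), s3 = c(25, 38, 25, 38)
    ),
    n_occurrences = 60
  )
  pca <- pca_correlation(stack$layers)
  niches <- species_niches(stack$occurrences, pca)
  expect_named(niches, c("s1", "s2", "s3"))
  pairs <- tibble::tibble(
    pair_id = "p1", species_a = "s1", species_b = "s2",
    branch_length_my = 1
  )
  out <- add_climate_overlap(pairs, niches)
  expect_true(out$climate_overlap >= 0 && out$climate_overlap <= 1)
})
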