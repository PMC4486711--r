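# Trait similarity, quasi-binomial divergence regressions and the
# overlap-versus-similarity multiple regression.

test_that("trait similarity is shared count over the smaller repertoire", {
  expect_equal(trait_similarity(c("a", "b", "c"), c("b", "c", "d", "e")), 2 / 3)
  expect_equal(trait_similarity(c("a", "b"), c("a", "b", "c", "d")), 1) # subset
  expect_equal(trait_similarity(c("a", "b"), c("x", "y", "z")), 0)
  # symmetric; case-normalised
  expect_equal(
    trait_similarity(c("A", "b"), c("a", "B", "c")),
    trait_similarity(c("a", "b", "c"), c("a", "b"))
  )
  expect_error(trait_similarity(character(0), "a"), "non-empty")
  cnt <- trait_sharing_counts(c("a", "b", "c"), c("b", "c", "d", "e"))
  expect_equal(cnt$x_shared, 2)
  expect_equal(cnt$y_min, 3)
})

test_that("similarity equals 1 exactly when one set nests in the other", {
  set.seed(16)
  for (i in 1:50) {
    a <- sample(letters, sample(1:8, 1))
    b <- sample(letters, sample(1:8, 1))
    s <- trait_similarity(a, b)
    expect_equal(trait_similarity(b, a), s)
    nested <- all(a %in% b) || all(b %in% a)
    expect_equal(s == 1, nested)
  }
})

test_that("inverse logit reproduces the published proportion intercepts", {
  expect_equal(round(inverse_logit(-0.57), 2), 0.36)
  expect_equal(round(inverse_logit(-0.01), 2), 0.5)
  expect_equal(inverse_logit(0), 0.5)
  expect_error(inverse_logit(Inf), "finite")
})

test_that("quasi-binomial regression recovers known coefficients", {
  set.seed(17)
  n <- 500
  t <- runif(n, 0, 10)
  p <- plogis(-0.5 + 0.05 * t)
  y <- rep(10, n)
  x <- rbinom(n, y, p)
  fit <- quasibinomial_regression(x, y, t)
  co <- tidy(fit)
  expect_lt(abs(co$estimate[1] - (-0.5)), 3 * co$std.error[1])
  expect_lt(abs(co$estimate[2] - 0.05), 3 * co$std.error[2])
  expect_false(glance(fit)$separation)
})

test_that("the quasi correction rescales SEs without moving estimates", {
  set.seed(18)
  n <- 80
  t <- runif(n, 0, 10)
  # beta-binomial counts: strongly overdispersed relative to binomial
  p <- rbeta(n, 2, 2)
  y <- rep(12, n)
  x <- rbinom(n, y, p)
  fit <- quasibinomial_regression(x, y, t)
  expect_true(fit$overdispersed)
  expect_gt(fit$dispersion, 1)
  co <- tidy(fit)
  expect_equal(co$std.error, co$naive_se * sqrt(fit$dispersion))
  # same point estimates as the plain binomial GLM
  ref <- glm(cbind(x, y - x) ~ t, family = binomial())
  expect_equal(unname(co$estimate), unname(coef(ref)), tolerance = 1e-9)
})

test_that("degenerate all-shared data raises the separation flag", {
  fit <- quasibinomial_regression(c(5, 5, 5, 5), c(5, 5, 5, 5), 1:4)
  expect_true(fit$separation)
  expect_error(quasibinomial_regression(c(6, 1, 1), c(5, 5, 5), 1:3), "between 0")
})

test_that("climate regression mirrors the angular-scale machinery", {
  fit <- climate_regression(rep(sin(1)^2, 5), 1:5)
  expect_equal(glance(fit)$intercept, 1, tolerance = 1e-9)
  expect_equal(glance(fit)$slope, 0, tolerance = 1e-9)
  # endpoint overlap 1.0 handled at pi/2 without failure
  set.seed(19)
  fit2 <- climate_regression(c(1, 1, 0.9, 0.8, runif(10)), runif(14, 0.5, 8))
  expect_true(all(is.finite(tidy(fit2)$estimate)))
})

test_that("multiple regression recovers a planted climate effect", {
  set.seed(20)
  n <- 200
  d <- tibble::tibble(
    branch_length_my = runif(n, 0, 8),
    mimicry_similarity = runif(n),
    host_similarity = runif(n),
    climate_overlap = runif(n)
  )
  theta <- pmin(pmax(0.2 + 0.15 * d$climate_overlap + rnorm(n, 0, 0.05), 0),
    pi / 2
  )
  d$overlap_index <- sin(theta)^2
  tab <- overlap_multiple_regression(d)
  cl <- tab[tab$term == "climatic_niche_overlap", ]
  expect_lt(abs(cl$estimate - 0.15), 3 * cl$std.error)
  expect_equal(
    tab$term,
    c(
      "(Intercept)", "branch_length", "mimicry_overlap",
      "host_plant_overlap", "climatic_niche_overlap"
    )
  )
})

test_that("multiple regression flags collinear designs and tiny n", {
  set.seed(23)
  n <- 30
  d <- tibble::tibble(
    branch_length_my = runif(n),
    mimicry_similarity = runif(n),
    host_similarity = NA_real_,
    climate_overlap = runif(n),
    overlap_index = runif(n)
  )
  expect_error(overlap_multiple_regression(d), "complete cases")
  d2 <- tibble::tibble(
    branch_length_my = runif(n),
    mimicry_similarity = runif(n),
    host_similarity = runif(n),
    climate_overlap = runif(n),
    overlap_index = runif(n)
  )
  d2$host_similarity <- d2$mimicry_similarity # aliased predictor
  expect_warning(overlap_multiple_regression(d2), "rank-deficient")
})
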