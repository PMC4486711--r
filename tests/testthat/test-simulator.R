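# Speciation-geometry simulator: area splits, daughter placement, range
# movement, extinction-restart and the sweep bookkeeping.

test_that("split_area conserves area and honours the peripatric ratio", {
  expect_equal(split_area(100, "peripatric"), c(95, 5))
  set.seed(11)
  for (mode in c("sympatric", "vicariant", "parapatric")) {
    s <- split_area(123.4, mode)
    expect_equal(sum(s), 123.4)
    expect_gte(s[1], s[2])
  }
  expect_error(split_area(-1, "sympatric"), "positive")
})

test_that("mean relative size of the smaller daughter is E[min(u,1-u)] = 1/4", {
  set.seed(21)
  u <- runif(1e5)
  oracle <- mean(pmin(u, 1 - u)) # brute-force expectation, = 0.25
  set.seed(22)
  sm <- replicate(1e4, split_area(1, "vicariant")[2])
  expect_equal(mean(sm), oracle, tolerance = 0.02)
  expect_equal(oracle, 0.25, tolerance = 0.01)
})

test_that("initial placement gives the overlap dichotomy by construction", {
  set.seed(31)
  cfg <- sim_config(ancestral_fraction = 0.16)
  for (i in 1:25) {
    a <- split_area(cfg$ancestral_fraction * cfg$domain_size^2, "sympatric")
    d <- place_daughters("sympatric", a[1], a[2], cfg)
    expect_equal(box_overlap_index(d$large, d$small), 1)
    for (mode in c("vicariant", "parapatric", "peripatric")) {
      a <- split_area(cfg$ancestral_fraction * cfg$domain_size^2, mode)
      d <- place_daughters(mode, a[1], a[2], cfg)
      expect_equal(box_overlap_index(d$large, d$small), 0)
      # all boxes inside the domain
      for (bx in d) {
        expect_gte(bx$left, 0)
        expect_gte(bx$bottom, 0)
        expect_lte(bx$right, cfg$domain_size)
        expect_lte(bx$top, cfg$domain_size)
      }
    }
  }
})

test_that("vicariant and parapatric gaps are exactly 2 and 0 units", {
  set.seed(32)
  cfg <- sim_config()
  A <- cfg$ancestral_fraction * cfg$domain_size^2
  for (i in 1:25) {
    a <- split_area(A, "vicariant")
    d <- place_daughters("vicariant", a[1], a[2], cfg)
    expect_equal(d$small$left - d$large$right, 2)
    # vertical interval of the smaller meets the larger's vertical extent
    expect_gt(min(d$small$top, d$large$top), max(d$small$bottom, d$large$bottom))
    a <- split_area(A, "parapatric")
    d <- place_daughters("parapatric", a[1], a[2], cfg)
    expect_equal(d$small$left - d$large$right, 0)
  }
})

test_that("daughter areas sum to the ancestral area before movement", {
  set.seed(33)
  cfg <- sim_config(ancestral_fraction = 0.108)
  A <- cfg$ancestral_fraction * cfg$domain_size^2
  for (mode in c("sympatric", "vicariant", "peripatric")) {
    a <- split_area(A, mode)
    d <- place_daughters(mode, a[1], a[2], cfg)
    got <- box_area_a <- (d$large$right - d$large$left) *
      (d$large$top - d$large$bottom) +
      (d$small$right - d$small$left) * (d$small$top - d$small$bottom)
    expect_equal(got, A, tolerance = 1e-9)
  }
})

test_that("step_move is the identity at sd 0 mean 0 and grows at mean 0.1", {
  cfg <- sim_config(movement_sd = 0)
  b <- range_box(40, 60, 40, 60)
  expect_equal(step_move(b, 0, 0, cfg), b)
  g <- step_move(b, 0.1, 0, cfg)
  # outward convention: every side moves outward by the mean
  expect_equal(g$left, 39.9)
  expect_equal(g$right, 60.1)
  expect_equal(g$bottom, 39.9)
  expect_equal(g$top, 60.1)
  # clipping at the domain boundary
  edge <- range_box(0, 10, 0, 10)
  expect_gte(step_move(edge, 0.5, 0, cfg)$left, 0)
})

test_that("mean area change per step is zero to first order at mean 0", {
  # analytic oracle: E[(w + dl + dr)(h + db + dt)] - wh = 0 for iid
  # mean-zero deviates (independence of horizontal and vertical terms)
  set.seed(41)
  w <- 20; h <- 20
  n <- 1e5
  dl <- rnorm(n, 0, 0.5); dr <- rnorm(n, 0, 0.5)
  db <- rnorm(n, 0, 0.5); dt <- rnorm(n, 0, 0.5)
  change <- (w + dl + dr) * (h + db + dt) - w * h
  expect_lt(abs(mean(change)), 3 * sd(change) / sqrt(n))
  # the simulator's step reproduces this for an interior box
  cfg <- sim_config(movement_sd = 0.5)
  set.seed(42)
  areas <- replicate(2e4, {
    bb <- step_move(range_box(40, 60, 40, 60), 0, 0.5, cfg)
    (bb$right - bb$left) * (bb$top - bb$bottom) - 400
  })
  expect_lt(abs(mean(areas)), 3 * sd(areas) / sqrt(2e4))
})

test_that("simulate_pair keeps the dichotomy when ranges cannot move", {
  cfg <- sim_config(movement_sd = 0)
  set.seed(51)
  expect_equal(simulate_pair("sympatric", 3, cfg), 1)
  expect_equal(simulate_pair("vicariant", 3, cfg), 0)
  expect_equal(simulate_pair("parapatric", 3, cfg), 0)
  expect_equal(simulate_pair("peripatric", 3, cfg), 0)
  expect_error(simulate_pair("sympatric", -1, cfg), "positive")
})

test_that("sympatric pairs drift out of complete overlap as steps accumulate", {
  cfg <- sim_config(movement_sd = 0.5)
  set.seed(52)
  frac_complete <- vapply(c(0.1, 2, 10), function(bl) {
    ov <- sympatry:::sim_pairs_core(
      rep("sympatric", 800),
      rep(sympatry:::branch_steps(bl, 10), 800), cfg
    )$overlap
    mean(ov > 0.95)
  }, numeric(1))
  expect_true(all(diff(frac_complete) < 0))
})

test_that("run_replicate matches the mode mixture at sd 0", {
  cfg <- sim_config(movement_sd = 0)
  bl <- gen_branch_lengths(10, seed = 6)
  set.seed(61)
  r_all <- run_replicate(bl, 10, cfg)
  expect_equal(r_all$summary$z, 10)
  expect_equal(r_all$summary$c, 0)
  expect_equal(r_all$summary$bimodality, 0)
  r_none <- run_replicate(bl, 0, cfg)
  expect_equal(r_none$summary$z, 0)
  expect_equal(r_none$summary$c, 10)
  r_half <- run_replicate(bl, 5, cfg)
  expect_equal(r_half$summary$bimodality, 1)
  expect_length(r_half$overlaps, 10)
  expect_error(run_replicate(numeric(0), 0, cfg), "non-empty")
  expect_error(run_replicate(bl, 11, cfg), "between 0")
})

test_that("every replicate returns two surviving species per pair", {
  # high movement at a small ancestral range forces frequent extinction;
  # restarts must still deliver living pairs with positive overlap index
  cfg <- sim_config(movement_sd = 2, ancestral_fraction = 0.082)
  bl <- gen_branch_lengths(20, max_age = 10, seed = 7)
  set.seed(71)
  r <- run_replicate(bl, 10, cfg)
  expect_true(all(is.finite(r$overlaps)))
  expect_true(all(r$overlaps >= 0 & r$overlaps <= 1))
  expect_gt(r$restarts, 0)
})

test_that("run_sweep is deterministic given a seed and well-shaped", {
  bl <- gen_branch_lengths(6, seed = 8)
  s1 <- run_sweep(bl,
    movement_sd = c(0.5, 1), n_sympatric = c(0, 3, 6),
    n_replicates = 10, seed = 99
  )
  s2 <- run_sweep(bl,
    movement_sd = c(0.5, 1), n_sympatric = c(0, 3, 6),
    n_replicates = 10, seed = 99
  )
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 2 * 3 * 10)
  expect_true(all(s1$z + s1$c <= s1$n))
  s3 <- run_sweep(bl,
    movement_sd = 0.5, n_sympatric = 0:6, n_replicates = 10, seed = 100
  )
  expect_equal(nrow(s3), 7 * 10)
})

test_that("median complete-sympatry count rises with sympatric events", {
  bl <- gen_branch_lengths(12, seed = 9)
  sw <- run_sweep(bl,
    movement_sd = 0.5, n_sympatric = c(0, 4, 8, 12),
    n_replicates = 60, seed = 101
  )
  med <- dplyr::summarise(
    dplyr::group_by(sw, n_sympatric),
    z = median(z), c = median(c), .groups = "drop"
  )
  expect_true(all(diff(med$z) >= 0))
  expect_true(all(diff(med$c) <= 0))
})
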