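# Stochastic simulator of speciation geometry and post-speciation range
# movement on a square domain.
#
# Species ranges are axis-aligned boxes on a [0, domain_size]^2 grid.
# Speciation divides an ancestral range into two square daughters whose
# initial configuration depends on the geographic mode; each subsequent
# time step adds independent normal deviates to the four range edges
# (outward sign convention, so a positive mean makes ranges tend to grow).
# All heavy entry points (run_replicate, run_sweep) share one vectorised
# core that advances every simulated pair in lockstep, restarting pairs in
# which a daughter dwindles to zero range.

SPECIATION_MODES <- c("sympatric", "vicariant", "parapatric", "peripatric")

#' Simulation configuration
#'
#' Collects the parameters of the range-movement simulator. Defaults follow
#' the heliconiine study conditions: a 100 x 100 domain, the ancestral range
#' occupying a median-sister-range fraction of the domain, ten time steps
#' per million years of branch length, a 95:5 peripatric split and a 2-unit
#' vicariant gap.
#'
#' @param domain_size Side length of the square domain (length units).
#' @param ancestral_fraction Ancestral range area as a fraction of the
#'   domain area. The study values are 0.082 / 0.108 (relaxed BSC medians),
#'   0.135 / 0.16 (strict BSC medians) and their doubles.
#' @param movement_sd Standard deviation of the per-step edge deviates
#'   (grid units); the study grid is 0.25, 0.5, 0.75, 1, 1.5, 2.
#' @param movement_mean Mean of the edge deviates; 0 for pure drift, 0.1
#'   gives ranges a tendency to grow.
#' @param steps_per_branch_unit Time steps per unit branch length (per My).
#' @param nonsympatric_geometry Geometry used for non-sympatric speciation
#'   events: `"vicariant"`, `"parapatric"` or `"peripatric"`.
#' @param peripatric_ratio Large:small area split for peripatric speciation.
#' @param vicariant_gap Horizontal gap (grid units) between vicariant
#'   daughters.
#' @param n_replicates Replicates per parameter cell in [run_sweep()].
#' @param max_restarts Restarts allowed per pair before erroring (guards
#'   against livelock when extinction is near-certain).
#' @param boundary Either `"clip"` (edges clamped to the domain, the
#'   default) or `"reflect"` (edges bounce off the domain walls).
#' @return A list of class `sim_config`.
#' @examples
#' sim_config(movement_sd = 0.5)
#' @export
sim_config <- function(domain_size = 100,
                       ancestral_fraction = 0.16,
                       movement_sd = 0.5,
                       movement_mean = 0,
                       steps_per_branch_unit = 10,
                       nonsympatric_geometry = c(
                         "vicariant", "parapatric", "peripatric"
                       ),
                       peripatric_ratio = c(95, 5),
                       vicariant_gap = 2,
                       n_replicates = 1000,
                       max_restarts = 1000,
                       boundary = c("clip", "reflect")) {
  nonsympatric_geometry <- match.arg(nonsympatric_geometry)
  boundary <- match.arg(boundary)
  stopifnot(
    domain_size > 0, ancestral_fraction > 0, ancestral_fraction < 1,
    movement_sd >= 0, steps_per_branch_unit > 0,
    length(peripatric_ratio) == 2, all(peripatric_ratio > 0),
    vicariant_gap >= 0, n_replicates >= 1, max_restarts >= 1
  )
  structure(
    list(
      domain_size = domain_size,
      ancestral_fraction = ancestral_fraction,
      movement_sd = movement_sd,
      movement_mean = movement_mean,
      steps_per_branch_unit = steps_per_branch_unit,
      nonsympatric_geometry = nonsympatric_geometry,
      peripatric_ratio = peripatric_ratio / sum(peripatric_ratio),
      vicariant_gap = vicariant_gap,
      n_replicates = n_replicates,
      max_restarts = max_restarts,
      boundary = boundary
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    cat("  ", nm, ": ", paste(format(x[[nm]]), collapse = ":"), "\n", sep = "")
  }
  invisible(x)
}

#' Create a rectangular range box
#'
#' @param left,right,bottom,top Box extents; a living species has
#'   `right > left` and `top > bottom`.
#' @return A list of class `range_box`.
#' @export
range_box <- function(left, right, bottom, top) {
  structure(
    list(left = left, right = right, bottom = bottom, top = top),
    class = "range_box"
  )
}

#' @export
print.range_box <- function(x, ...) {
  cat(
    "<range_box> [", x$left, ", ", x$right, "] x [", x$bottom, ", ", x$top,
    "] (area ", format(box_area_scalar(x)), ")\n",
    sep = ""
  )
  invisible(x)
}

box_area_scalar <- function(b) {
  max(b$right - b$left, 0) * max(b$top - b$bottom, 0)
}

#' Is a range box extinct?
#'
#' A species is extinct when its range has dwindled to zero extent on
#' either axis.
#'
#' @param box A [range_box()].
#' @return Logical.
#' @export
box_extinct <- function(box) {
  box$right <= box$left || box$top <= box$bottom
}

#' Overlap index of two axis-aligned boxes (closed form)
#'
#' @param a,b [range_box()] objects.
#' @return Intersection area over the smaller box area.
#' @export
box_overlap_index <- function(a, b) {
  inter <- max(0, min(a$right, b$right) - max(a$left, b$left)) *
    max(0, min(a$top, b$top) - max(a$bottom, b$bottom))
  overlap_index(box_area_scalar(a), box_area_scalar(b), inter)
}

#' Divide an ancestral range area between two daughters
#'
#' Peripatric speciation uses the fixed 95:5 split; every other mode draws
#' the split fraction uniformly, so the expected relative size of the
#' smaller daughter is 1/4. The pair is returned larger-first and always
#' sums to `total_area`.
#'
#' @param total_area Positive ancestral area.
#' @param mode One of `"sympatric"`, `"vicariant"`, `"parapatric"`,
#'   `"peripatric"`.
#' @param peripatric_ratio Two positive numbers giving the peripatric split.
#' @return Numeric vector `c(area_large, area_small)`.
#' @export
split_area <- function(total_area, mode = SPECIATION_MODES,
                       peripatric_ratio = c(95, 5)) {
  mode <- match.arg(mode)
  if (total_area <= 0) stop("`total_area` must be positive", call. = FALSE)
  if (mode == "peripatric") {
    r <- sort(peripatric_ratio / sum(peripatric_ratio), decreasing = TRUE)
    return(total_area * r)
  }
  u <- stats::runif(1)
  total_area * c(max(u, 1 - u), min(u, 1 - u))
}

# Vectorised split for m pairs. Returns a list with area_large, area_small.
split_area_vec <- function(m, total_area, modes, peri) {
  large <- numeric(m)
  small <- numeric(m)
  is_peri <- modes == "peripatric"
  if (any(is_peri)) {
    large[is_peri] <- total_area * max(peri)
    small[is_peri] <- total_area * min(peri)
  }
  k <- sum(!is_peri)
  if (k > 0) {
    u <- stats::runif(k)
    large[!is_peri] <- total_area * pmax(u, 1 - u)
    small[!is_peri] <- total_area * pmin(u, 1 - u)
  }
  list(large = large, small = small)
}

# Vectorised initial placement for m pairs. Daughters start as squares.
# Returns matrices l, r, b, t of dimension m x 2 (large, small).
place_daughters_vec <- function(modes, area_large, area_small, config) {
  m <- length(modes)
  D <- config$domain_size
  gap <- config$vicariant_gap
  s1 <- sqrt(area_large)
  s2 <- sqrt(area_small)
  l <- matrix(0, m, 2); r <- matrix(0, m, 2)
  b <- matrix(0, m, 2); t <- matrix(0, m, 2)

  sym <- modes == "sympatric"
  vic <- modes == "vicariant"
  par_ <- modes == "parapatric"
  per <- modes == "peripatric"

  if (any(s1 > D) || any(s2 > D)) {
    stop("configuration error: daughter range does not fit the domain",
      call. = FALSE
    )
  }

  # sympatric: larger square uniform on the domain, smaller uniform inside it
  if (any(sym)) {
    k <- sum(sym)
    l1 <- stats::runif(k, 0, D - s1[sym])
    b1 <- stats::runif(k, 0, D - s1[sym])
    l2 <- l1 + stats::runif(k, 0, s1[sym] - s2[sym])
    b2 <- b1 + stats::runif(k, 0, s1[sym] - s2[sym])
    l[sym, 1] <- l1; r[sym, 1] <- l1 + s1[sym]
    b[sym, 1] <- b1; t[sym, 1] <- b1 + s1[sym]
    l[sym, 2] <- l2; r[sym, 2] <- l2 + s2[sym]
    b[sym, 2] <- b2; t[sym, 2] <- b2 + s2[sym]
  }

  # vicariant / parapatric: smaller square a fixed horizontal gap to the
  # right of the larger, vertical interval meeting the larger's extent
  lateral <- vic | par_
  if (any(lateral)) {
    g <- ifelse(vic[lateral], gap, 0)
    k <- sum(lateral)
    room <- D - s1[lateral] - g - s2[lateral]
    if (any(room < 0)) {
      stop("configuration error: lateral placement exceeds the domain",
        call. = FALSE
      )
    }
    l1 <- stats::runif(k, 0, room)
    b1 <- stats::runif(k, 0, D - s1[lateral])
    lo <- pmax(0, b1 - s2[lateral])
    hi <- pmin(D - s2[lateral], b1 + s1[lateral])
    b2 <- stats::runif(k, lo, hi)
    l2 <- l1 + s1[lateral] + g
    l[lateral, 1] <- l1; r[lateral, 1] <- l1 + s1[lateral]
    b[lateral, 1] <- b1; t[lateral, 1] <- b1 + s1[lateral]
    l[lateral, 2] <- l2; r[lateral, 2] <- l2 + s2[lateral]
    b[lateral, 2] <- b2; t[lateral, 2] <- b2 + s2[lateral]
  }

  # peripatric: both squares uniform on the domain, rejection-sampled to
  # be initially disjoint
  if (any(per)) {
    idx <- which(per)
    todo <- idx
    tries <- 0L
    while (length(todo) > 0) {
      k <- length(todo)
      l1 <- stats::runif(k, 0, D - s1[todo])
      b1 <- stats::runif(k, 0, D - s1[todo])
      l2 <- stats::runif(k, 0, D - s2[todo])
      b2 <- stats::runif(k, 0, D - s2[todo])
      l[todo, 1] <- l1; r[todo, 1] <- l1 + s1[todo]
      b[todo, 1] <- b1; t[todo, 1] <- b1 + s1[todo]
      l[todo, 2] <- l2; r[todo, 2] <- l2 + s2[todo]
      b[todo, 2] <- b2; t[todo, 2] <- b2 + s2[todo]
      overlapping <- pmin(r[todo, 1], r[todo, 2]) > pmax(l[todo, 1], l[todo, 2]) &
        pmin(t[todo, 1], t[todo, 2]) > pmax(b[todo, 1], b[todo, 2])
      todo <- todo[overlapping]
      tries <- tries + 1L
      if (tries > config$max_restarts) {
        stop("configuration error: peripatric placement infeasible ",
          "(ancestral_fraction = ", config$ancestral_fraction, ")",
          call. = FALSE
        )
      }
    }
  }

  list(l = l, r = r, b = b, t = t)
}

#' Place two daughter ranges according to a speciation geometry
#'
#' Daughters start as squares with side `sqrt(area)`. Sympatric speciation
#' nests the smaller daughter uniformly inside the larger; vicariant
#' speciation separates them by a fixed horizontal gap; parapatric daughters
#' abut; peripatric daughters are placed uniformly on the domain subject to
#' being disjoint. All boxes lie fully inside the domain.
#'
#' @inheritParams split_area
#' @param area_large,area_small Daughter areas (larger first).
#' @param config A [sim_config()].
#' @return A list of two [range_box()] objects, `large` and `small`.
#' @export
place_daughters <- function(mode = SPECIATION_MODES, area_large, area_small,
                            config = sim_config()) {
  mode <- match.arg(mode)
  if (area_small > area_large) {
    stop("`area_large` must be at least `area_small`", call. = FALSE)
  }
  p <- place_daughters_vec(mode, area_large, area_small, config)
  list(
    large = range_box(p$l[1, 1], p$r[1, 1], p$b[1, 1], p$t[1, 1]),
    small = range_box(p$l[1, 2], p$r[1, 2], p$b[1, 2], p$t[1, 2])
  )
}

# One movement step for edge matrices (any shape). Outward convention:
# top and right add their deviates, bottom and left subtract. Returns the
# updated edges, constrained to the domain.
step_edges <- function(l, r, b, t, mean, sd, D, boundary = "clip") {
  n <- length(l)
  l <- l - stats::rnorm(n, mean, sd)
  r <- r + stats::rnorm(n, mean, sd)
  b <- b - stats::rnorm(n, mean, sd)
  t <- t + stats::rnorm(n, mean, sd)
  if (boundary == "reflect") {
    refl <- function(x) {
      x <- abs(x)
      ifelse(x %% (2 * D) > D, 2 * D - x %% (2 * D), x %% (2 * D))
    }
    l <- refl(l); r <- refl(r); b <- refl(b); t <- refl(t)
  } else {
    l <- pmin(pmax(l, 0), D)
    r <- pmin(pmax(r, 0), D)
    b <- pmin(pmax(b, 0), D)
    t <- pmin(pmax(t, 0), D)
  }
  list(l = l, r = r, b = b, t = t)
}

#' Advance a range box one time step
#'
#' Adds four independent normal deviates to the box edges using the outward
#' sign convention (a positive mean expands the range), then clamps the box
#' to the domain. A box whose width or height has shrunk to zero or below
#' is extinct.
#'
#' @param box A [range_box()].
#' @param movement_mean,movement_sd Deviate mean and standard deviation.
#' @param config A [sim_config()] supplying the domain and boundary rule.
#' @return The moved [range_box()]; check [box_extinct()] on the result.
#' @export
step_move <- function(box, movement_mean = 0, movement_sd = 0.5,
                      config = sim_config()) {
  if (box_extinct(box)) stop("cannot move an extinct range", call. = FALSE)
  e <- step_edges(
    box$left, box$right, box$bottom, box$top,
    movement_mean, movement_sd, config$domain_size, config$boundary
  )
  range_box(e$l, e$r, e$b, e$t)
}

# Vectorised engine: simulate m sister pairs to completion.
# modes: character vector (length m); n_steps: integer vector (length m).
# Returns list(overlap = numeric(m), restarts = total restart count).
sim_pairs_core <- function(modes, n_steps, config) {
  m <- length(modes)
  stopifnot(length(n_steps) == m)
  D <- config$domain_size
  total_area <- config$ancestral_fraction * D^2

  init <- function(which_idx) {
    sp <- split_area_vec(
      length(which_idx), total_area, modes[which_idx], config$peripatric_ratio
    )
    place_daughters_vec(modes[which_idx], sp$large, sp$small, config)
  }

  p <- init(seq_len(m))
  l <- p$l; r <- p$r; b <- p$b; t <- p$t
  steps_done <- integer(m)
  restarts <- integer(m)

  active <- which(steps_done < n_steps)
  while (length(active) > 0) {
    k <- length(active)
    e1 <- step_edges(
      l[active, 1], r[active, 1], b[active, 1], t[active, 1],
      config$movement_mean, config$movement_sd, D, config$boundary
    )
    e2 <- step_edges(
      l[active, 2], r[active, 2], b[active, 2], t[active, 2],
      config$movement_mean, config$movement_sd, D, config$boundary
    )
    l[active, 1] <- e1$l; r[active, 1] <- e1$r
    b[active, 1] <- e1$b; t[active, 1] <- e1$t
    l[active, 2] <- e2$l; r[active, 2] <- e2$r
    b[active, 2] <- e2$b; t[active, 2] <- e2$t

    dead <- (e1$r <= e1$l) | (e1$t <= e1$b) | (e2$r <= e2$l) | (e2$t <= e2$b)
    if (any(dead)) {
      idx <- active[dead]
      restarts[idx] <- restarts[idx] + 1L
      if (any(restarts[idx] > config$max_restarts)) {
        stop(
          "restart cap exceeded (movement_sd = ", config$movement_sd,
          ", ancestral_fraction = ", config$ancestral_fraction,
          ", steps = ", max(n_steps[idx]), ")",
          call. = FALSE
        )
      }
      pr <- init(idx)
      l[idx, ] <- pr$l; r[idx, ] <- pr$r; b[idx, ] <- pr$b; t[idx, ] <- pr$t
      steps_done[idx] <- 0L
    }
    alive <- active[!dead]
    steps_done[alive] <- steps_done[alive] + 1L
    active <- which(steps_done < n_steps)
  }

  wa <- pmax(r[, 1] - l[, 1], 0) * pmax(t[, 1] - b[, 1], 0)
  wb <- pmax(r[, 2] - l[, 2], 0) * pmax(t[, 2] - b[, 2], 0)
  iw <- pmax(0, pmin(r[, 1], r[, 2]) - pmax(l[, 1], l[, 2]))
  ih <- pmax(0, pmin(t[, 1], t[, 2]) - pmax(b[, 1], b[, 2]))
  list(
    overlap = overlap_index(wa, wb, iw * ih),
    restarts = sum(restarts)
  )
}

branch_steps <- function(branch_length, steps_per_branch_unit) {
  pmax(1L, as.integer(round(branch_length * steps_per_branch_unit)))
}

#' Simulate one sister pair
#'
#' Splits an ancestral range, places the daughters according to the
#' speciation geometry, and advances both ranges independently for
#' `round(branch_length * steps_per_branch_unit)` steps (at least one).
#' If either daughter dwindles to zero range the whole pair restarts from
#' the split, so every returned value comes from two surviving species.
#'
#' @param mode Speciation geometry.
#' @param branch_length Time since divergence (My); must be positive.
#' @param config A [sim_config()].
#' @return The final overlap index of the pair (a single number).
#' @export
simulate_pair <- function(mode = SPECIATION_MODES, branch_length,
                          config = sim_config()) {
  mode <- match.arg(mode)
  if (branch_length <= 0) {
    stop("`branch_length` must be positive", call. = FALSE)
  }
  n_steps <- branch_steps(branch_length, config$steps_per_branch_unit)
  sim_pairs_core(mode, n_steps, config)$overlap
}

#' Simulate one replicate set of sister pairs
#'
#' Branch lengths are assigned to pairs by permutation (sampling without
#' replacement); `n_sympatric` of the pairs speciate sympatrically and the
#' rest use the configured non-sympatric geometry.
#'
#' @param branch_lengths Vector of sister-pair branch lengths (My).
#' @param n_sympatric Number of sympatric speciation events, between 0 and
#'   `length(branch_lengths)`.
#' @param config A [sim_config()].
#' @return A list of class `sim_replicate` with elements `overlaps` (one
#'   final overlap index per pair) and `summary` (the one-row tibble from
#'   [summarize_overlaps()]).
#' @export
run_replicate <- function(branch_lengths, n_sympatric, config = sim_config()) {
  n <- length(branch_lengths)
  if (n == 0) stop("`branch_lengths` must be non-empty", call. = FALSE)
  if (any(branch_lengths <= 0)) {
    stop("branch lengths must be positive", call. = FALSE)
  }
  if (n_sympatric < 0 || n_sympatric > n) {
    stop("`n_sympatric` must be between 0 and the number of pairs",
      call. = FALSE
    )
  }
  modes <- c(
    rep("sympatric", n_sympatric),
    rep(config$nonsympatric_geometry, n - n_sympatric)
  )
  bl <- sample(branch_lengths)
  res <- sim_pairs_core(modes, branch_steps(bl, config$steps_per_branch_unit),
    config = config
  )
  structure(
    list(
      overlaps = res$overlap,
      summary = summarize_overlaps(res$overlap),
      restarts = res$restarts
    ),
    class = "sim_replicate"
  )
}

#' @export
print.sim_replicate <- function(x, ...) {
  cat("<sim_replicate> ", length(x$overlaps), " pairs\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Sweep the simulator over a parameter grid
#'
#' Runs `n_replicates` replicate sets for every combination of the supplied
#' parameter values and every number of sympatric speciation events from 0
#' to the number of pairs, recording the three summary indices (z, c,
#' bimodality) of every replicate. Deterministic given `seed`.
#'
#' All simulated pairs of a cell's replicates are advanced together by the
#' vectorised engine, so the sweep stays fast at study scale.
#'
#' @param branch_lengths Sister-pair branch lengths (My).
#' @param movement_sd,movement_mean,ancestral_fraction,geometry Vectors of
#'   parameter values to cross.
#' @param n_sympatric Numbers of sympatric events to explore; defaults to
#'   `0:length(branch_lengths)`.
#' @param n_replicates Replicates per cell.
#' @param seed Integer seed; the sweep is reproducible bit-for-bit.
#' @param config Base [sim_config()] supplying the remaining parameters.
#' @param progress Print one line per cell as it completes.
#' @return A tibble of class `sweep_result` with one row per replicate per
#'   cell: `movement_sd`, `movement_mean`, `ancestral_fraction`, `geometry`,
#'   `n_sympatric`, `replicate`, `n`, `z`, `c`, `bimodality`, `restarts`.
#' @export
run_sweep <- function(branch_lengths,
                      movement_sd = c(0.25, 0.5, 0.75, 1, 1.5, 2),
                      movement_mean = 0,
                      ancestral_fraction = 0.16,
                      geometry = "vicariant",
                      n_sympatric = NULL,
                      n_replicates = 1000,
                      seed = 1,
                      config = sim_config(),
                      progress = FALSE) {
  n <- length(branch_lengths)
  if (n == 0) stop("`branch_lengths` must be non-empty", call. = FALSE)
  if (is.null(n_sympatric)) n_sympatric <- 0:n
  grid <- tidyr::expand_grid(
    movement_sd = movement_sd,
    movement_mean = movement_mean,
    ancestral_fraction = ancestral_fraction,
    geometry = geometry,
    n_sympatric = n_sympatric
  )
  set.seed(seed)
  out <- purrr::pmap(grid, function(movement_sd, movement_mean,
                                    ancestral_fraction, geometry,
                                    n_sympatric) {
    cfg <- config
    cfg$movement_sd <- movement_sd
    cfg$movement_mean <- movement_mean
    cfg$ancestral_fraction <- ancestral_fraction
    cfg$nonsympatric_geometry <- geometry
    # all replicates of the cell advance together: m = n * n_replicates
    modes <- rep(
      c(
        rep("sympatric", n_sympatric),
        rep(geometry, n - n_sympatric)
      ),
      n_replicates
    )
    bl <- as.vector(vapply(
      seq_len(n_replicates), function(i) sample(branch_lengths), numeric(n)
    ))
    res <- sim_pairs_core(
      modes, branch_steps(bl, cfg$steps_per_branch_unit), cfg
    )
    ov <- matrix(res$overlap, nrow = n)
    zc <- apply(ov, 2, function(v) {
      cl <- classify_overlap(v)
      c(sum(cl == "sympatric"), sum(cl == "allopatric"))
    })
    if (progress) {
      message(
        "cell sd=", movement_sd, " mean=", movement_mean,
        " frac=", ancestral_fraction, " geom=", geometry,
        " k=", n_sympatric, ": ", n_replicates, " replicates, ",
        res$restarts, " restarts"
      )
    }
    tibble::tibble(
      replicate = seq_len(n_replicates),
      n = n,
      z = zc[1, ],
      c = zc[2, ],
      bimodality = bimodality(zc[1, ], zc[2, ], n),
      restarts = res$restarts
    )
  })
  res <- dplyr::bind_cols(
    grid[rep(seq_len(nrow(grid)), vapply(out, nrow, 1L)), ],
    dplyr::bind_rows(out)
  )
  class(res) <- c("sweep_result", class(res))
  res
}
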