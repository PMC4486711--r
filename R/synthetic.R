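# Seed-deterministic generators of synthetic study inputs: sister-pair
# tables with known speciation-mode mixtures, trait profiles with
# controlled sharing, and bioclim-like raster stacks with species
# occurrences. Every generator stores the generating truth beside its
# output, so parameter-recovery tests can compare estimate to truth.

#' Generate sister-pair branch lengths
#'
#' Draws divergence times uniformly between `min_age` and `max_age`,
#' emulating the 0-10 My scale of heliconiine sister splits.
#'
#' @param n Number of sister pairs.
#' @param max_age,min_age Age bounds (My).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` branch lengths.
#' @examples
#' gen_branch_lengths(22, seed = 1)
#' @export
gen_branch_lengths <- function(n, max_age = 10, min_age = 0.1, seed = NULL) {
  stopifnot(n >= 1, max_age > min_age, min_age > 0)
  if (!is.null(seed)) set.seed(seed)
  stats::runif(n, min_age, max_age)
}

#' Generate a synthetic sister-pair table with known truth
#'
#' Simulates one replicate set of sister pairs with a known fraction of
#' sympatric speciation events and packages the result as a standard pair
#' table. The generating parameters are stored in the `truth` attribute.
#'
#' @param n_pairs Number of sister pairs.
#' @param sympatric_fraction True fraction of sympatric speciation events;
#'   the realised count is `round(sympatric_fraction * n_pairs)`.
#' @param config A [sim_config()].
#' @param branch_lengths Optional branch lengths; generated uniformly when
#'   `NULL`.
#' @param seed Optional integer seed.
#' @return A tibble with columns `pair_id`, `species_a`, `species_b`,
#'   `branch_length_my`, `overlap_index`, `category`, carrying a `truth`
#'   attribute (list of generating parameters).
#' @examples
#' gen_pair_table(22, 0.5, sim_config(movement_sd = 0.5), seed = 1)
#' @export
gen_pair_table <- function(n_pairs, sympatric_fraction,
                           config = sim_config(), branch_lengths = NULL,
                           seed = NULL) {
  stopifnot(sympatric_fraction >= 0, sympatric_fraction <= 1, n_pairs >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(branch_lengths)) branch_lengths <- gen_branch_lengths(n_pairs)
  n_sympatric <- round(sympatric_fraction * n_pairs)
  rep_res <- run_replicate(branch_lengths, n_sympatric, config)
  out <- tibble::tibble(
    pair_id = sprintf("pair_%02d", seq_len(n_pairs)),
    species_a = sprintf("sp_%02da", seq_len(n_pairs)),
    species_b = sprintf("sp_%02db", seq_len(n_pairs)),
    branch_length_my = branch_lengths,
    overlap_index = rep_res$overlaps,
    category = classify_overlap(rep_res$overlaps)
  )
  attr(out, "truth") <- list(
    sympatric_fraction = sympatric_fraction,
    n_sympatric = n_sympatric,
    movement_sd = config$movement_sd,
    movement_mean = config$movement_mean,
    ancestral_fraction = config$ancestral_fraction,
    nonsympatric_geometry = config$nonsympatric_geometry
  )
  out
}

#' Generate trait profiles with controlled sharing
#'
#' Gives each sister a trait repertoire (mimicry rings or host plants) of
#' size drawn uniformly from `richness_range`; each trait of the smaller
#' repertoire is shared with its sister with probability `sharing_prob`,
#' so the expected pairwise similarity equals `sharing_prob`.
#'
#' @param n_pairs Number of sister pairs.
#' @param richness_range Integer range of repertoire sizes.
#' @param sharing_prob Probability that a trait of the smaller repertoire
#'   is shared.
#' @param prefix Label prefix (e.g. `"ring"` or `"host"`).
#' @param seed Optional integer seed.
#' @return A list: `profiles` (tibble `species`, `trait`, long format),
#'   `pairs` (tibble `pair_id`, `species_a`, `species_b`, `x_shared`,
#'   `y_min`, `similarity`), and `truth`.
#' @export
gen_trait_profiles <- function(n_pairs, richness_range = c(1, 8),
                               sharing_prob = 0.5, prefix = "trait",
                               seed = NULL) {
  stopifnot(
    n_pairs >= 1, sharing_prob >= 0, sharing_prob <= 1,
    length(richness_range) == 2, richness_range[1] >= 1
  )
  if (!is.null(seed)) set.seed(seed)
  rows <- purrr::map(seq_len(n_pairs), function(i) {
    ra <- sample(richness_range[1]:richness_range[2], 1)
    rb <- sample(richness_range[1]:richness_range[2], 1)
    m <- min(ra, rb)
    shared <- stats::rbinom(1, m, sharing_prob)
    sp_a <- sprintf("sp_%02da", i)
    sp_b <- sprintf("sp_%02db", i)
    shared_labels <- if (shared > 0) {
      sprintf("%s_%02d_s%d", prefix, i, seq_len(shared))
    } else {
      character(0)
    }
    a_only <- if (ra - shared > 0) {
      sprintf("%s_%02d_a%d", prefix, i, seq_len(ra - shared))
    } else {
      character(0)
    }
    b_only <- if (rb - shared > 0) {
      sprintf("%s_%02d_b%d", prefix, i, seq_len(rb - shared))
    } else {
      character(0)
    }
    list(
      profiles = tibble::tibble(
        species = c(
          rep(sp_a, ra), rep(sp_b, rb)
        ),
        trait = c(shared_labels, a_only, shared_labels, b_only)
      ),
      pair = tibble::tibble(
        pair_id = sprintf("pair_%02d", i),
        species_a = sp_a, species_b = sp_b,
        x_shared = shared, y_min = m, similarity = shared / m
      )
    )
  })
  list(
    profiles = dplyr::bind_rows(purrr::map(rows, "profiles")),
    pairs = dplyr::bind_rows(purrr::map(rows, "pair")),
    truth = list(
      sharing_prob = sharing_prob, richness_range = richness_range
    )
  )
}

# Separable Gaussian smoothing of a matrix (reflecting edges), used to give
# the synthetic climate layers spatial autocorrelation.
smooth_field <- function(mat, scale) {
  if (scale <= 0) return(mat)
  half <- max(1L, ceiling(3 * scale))
  k <- stats::dnorm(seq(-half, half), sd = scale)
  k <- k / sum(k)
  pad_smooth <- function(v) {
    n <- length(v)
    padded <- c(rev(v[seq_len(half)]), v, rev(v[seq(n - half + 1, n)]))
    stats::filter(padded, k, sides = 2)[(half + 1):(half + n)]
  }
  sm <- apply(mat, 2, pad_smooth)
  t(apply(t(sm), 2, pad_smooth))
}

#' Generate a bioclim-like raster stack with species occurrences
#'
#' Builds `n_layers` spatially autocorrelated Gaussian random fields on a
#' grid. Between-layer correlation is controlled by mixing a shared latent
#' field into every layer with weight `sqrt(cross_corr)`. Species
#' occurrence points are sampled uniformly within assigned range boxes, so
#' climatic niche overlap correlates with range overlap by construction.
#'
#' @param n_layers Number of climate layers (19 mirrors the bioclim set).
#' @param grid_shape Grid dimensions `c(rows, cols)`.
#' @param spatial_scale Gaussian smoothing scale in cells (spatial
#'   autocorrelation range).
#' @param cross_corr Between-layer correlation of the latent fields, in
#'   \[0, 1\].
#' @param species_boxes Optional named list of range boxes, each
#'   `c(left, right, bottom, top)` in cell units; species occurrences are
#'   sampled inside them.
#' @param n_occurrences Occurrence points per species.
#' @param seed Optional integer seed.
#' @return A list: `layers` (rows x cols x n_layers array),
#'   `occurrences` (tibble `species`, `row`, `col`, `cell` where `cell`
#'   indexes the flattened grid), and `truth`.
#' @export
gen_raster_stack <- function(n_layers = 19, grid_shape = c(60, 60),
                             spatial_scale = 4, cross_corr = 0.5,
                             species_boxes = NULL, n_occurrences = 80,
                             seed = NULL) {
  stopifnot(n_layers >= 3, cross_corr >= 0, cross_corr <= 1)
  if (!is.null(seed)) set.seed(seed)
  nr <- grid_shape[1]
  nc <- grid_shape[2]
  common <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), spatial_scale)
  layers <- array(NA_real_, c(nr, nc, n_layers),
    dimnames = list(NULL, NULL, paste0("bio", seq_len(n_layers)))
  )
  for (j in seq_len(n_layers)) {
    own <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), spatial_scale)
    f <- sqrt(cross_corr) * common + sqrt(1 - cross_corr) * own
    # vary the marginal location/scale so layers look like different
    # bioclim variables
    layers[, , j] <- 10 * j + (2 + j / 4) * f / stats::sd(f)
  }
  occurrences <- NULL
  if (!is.null(species_boxes)) {
    occurrences <- purrr::imap(species_boxes, function(bx, sp) {
      rows <- pmin(nr, pmax(1, round(stats::runif(n_occurrences, bx[3], bx[4]))))
      cols <- pmin(nc, pmax(1, round(stats::runif(n_occurrences, bx[1], bx[2]))))
      tibble::tibble(
        species = sp, row = rows, col = cols,
        cell = rows + (cols - 1) * nr
      )
    }) |> dplyr::bind_rows()
  }
  list(
    layers = layers,
    occurrences = occurrences,
    truth = list(
      n_layers = n_layers, grid_shape = grid_shape,
      spatial_scale = spatial_scale, cross_corr = cross_corr,
      species_boxes = species_boxes, n_occurrences = n_occurrences
    )
  )
}

#' Generate a complete synthetic study
#'
#' Bundles the pair table, mimicry and host-plant trait tables and a
#' raster stack with occurrences into one object whose `truth` element
#' records every generating parameter.
#'
#' @param n_pairs Number of sister pairs.
#' @param sympatric_fraction True sympatric-speciation fraction.
#' @param config A [sim_config()].
#' @param mimicry_sharing,host_sharing Sharing probabilities for the two
#'   trait tables.
#' @param seed Integer seed (required: the study is reproducible from
#'   `(seed, truth)`).
#' @return A list of class `synthetic_study` with elements `pairs`,
#'   `mimicry`, `hosts`, `climate`, `truth`.
#' @export
gen_synthetic_study <- function(n_pairs = 22, sympatric_fraction = 0.5,
                                config = sim_config(),
                                mimicry_sharing = 0.4, host_sharing = 0.5,
                                seed = 1) {
  set.seed(seed)
  pairs <- gen_pair_table(n_pairs, sympatric_fraction, config)
  mimicry <- gen_trait_profiles(n_pairs,
    sharing_prob = mimicry_sharing, prefix = "ring"
  )
  hosts <- gen_trait_profiles(n_pairs,
    sharing_prob = host_sharing, prefix = "host"
  )
  # species range boxes on the raster grid loosely follow the pair overlap:
  # sympatric pairs share a box, allopatric pairs get disjoint boxes
  grid <- c(60, 60)
  boxes <- list()
  for (i in seq_len(n_pairs)) {
    w <- stats::runif(1, 10, 20)
    l <- stats::runif(1, 1, grid[2] - 2 * w - 2)
    b <- stats::runif(1, 1, grid[1] - w - 1)
    sp_a <- pairs$species_a[i]
    sp_b <- pairs$species_b[i]
    boxes[[sp_a]] <- c(l, l + w, b, b + w)
    if (pairs$overlap_index[i] > 0.5) {
      boxes[[sp_b]] <- boxes[[sp_a]]
    } else {
      boxes[[sp_b]] <- c(l + w + 2, l + 2 * w + 2, b, b + w)
    }
  }
  climate <- gen_raster_stack(species_boxes = boxes)
  structure(
    list(
      pairs = pairs, mimicry = mimicry, hosts = hosts, climate = climate,
      truth = c(
        attr(pairs, "truth"),
        list(
          mimicry_sharing = mimicry_sharing, host_sharing = host_sharing,
          seed = seed
        )
      )
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(
    "<synthetic_study> ", nrow(x$pairs), " sister pairs (true sympatric ",
    "fraction ", x$truth$sympatric_fraction, ")\n",
    sep = ""
  )
  invisible(x)
}
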