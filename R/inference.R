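# Inference: percentile consistency of observed overlap summaries with
# simulated null distributions, and age-range correlations on the angular
# scale.

#' Angular (arcsine square root) transform of a proportion
#'
#' The variance-stabilising transform used for overlap fractions:
#' `theta = asin(sqrt(p))`, mapping \[0, 1\] onto \[0, pi/2\].
#'
#' @param p Proportions in \[0, 1\].
#' @return Angles in radians.
#' @seealso [back_transform()]
#' @export
angular_transform <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  asin(sqrt(p))
}

#' Back-transform from the angular scale
#'
#' Inverse of [angular_transform()]: `sin(theta)^2` on \[0, pi/2\].
#'
#' @param theta Angles in radians in \[0, pi/2\].
#' @return Proportions in \[0, 1\].
#' @examples
#' back_transform(0.67) # angular-scale intercept -> proportion
#' @export
back_transform <- function(theta) {
  if (any(is.na(theta)) || any(theta < 0) || any(theta > pi / 2 + 1e-12)) {
    stop("angles must lie in [0, pi/2]", call. = FALSE)
  }
  sin(theta)^2
}

#' Two-tailed percentile consistency test
#'
#' An observed value is consistent with a simulated distribution when it
#' lies inside the central 95% band, i.e. between the 2.5th and 97.5th
#' percentiles (linear-interpolation quantiles); values exactly on a
#' percentile count as consistent ("outside" is strict).
#'
#' @param observed A single observed value.
#' @param simulated Numeric vector of simulated values (at least 40 for
#'   stable percentiles; fewer triggers a warning).
#' @param probs Lower and upper percentile bounds.
#' @return Logical: `TRUE` if the observed value is consistent.
#' @examples
#' percentile_consistency(5, 0:100)
#' @export
percentile_consistency <- function(observed, simulated,
                                   probs = c(0.025, 0.975)) {
  if (length(simulated) == 0) {
    stop("`simulated` must be non-empty", call. = FALSE)
  }
  if (length(simulated) < 40) {
    warning("fewer than 40 simulated values; percentile bounds are unstable",
      call. = FALSE
    )
  }
  q <- stats::quantile(simulated, probs = probs, names = FALSE, type = 7)
  observed >= q[1] && observed <= q[2]
}

#' Sympatric-speciation fractions consistent with observed overlap data
#'
#' Compares an observed overlap summary (counts of completely sympatric and
#' completely allopatric pairs and the bimodality score) against a
#' simulated sweep, cell by cell, using the two-tailed percentile test.
#' For each index the consistent sympatric fractions are those consistent
#' in at least one parameter combination; the joint result requires all
#' three indices to be consistent in the same combination.
#'
#' @param observed A one-row data frame with columns `n`, `z`, `c`,
#'   `bimodality` (e.g. from [summarize_overlaps()]).
#' @param sweep A [run_sweep()] result covering `n_sympatric` from 0 to
#'   `observed$n`.
#' @return An object of class `sympatry_inference`: a list with
#'   * `cells`: tibble of per-cell, per-index consistency booleans,
#'   * `per_index`: tibble of min/max consistent fraction per index,
#'   * `joint`: one-row tibble with the jointly consistent fraction range,
#'   * `observed`: the observed summary.
#'   `tidy()` returns `cells`, `glance()` returns `joint`.
#' @examples
#' \donttest{
#' bl <- gen_branch_lengths(10, seed = 1)
#' sw <- run_sweep(bl, movement_sd = 0.5, n_replicates = 50, seed = 1)
#' obs <- summarize_overlaps(run_replicate(bl, 5, sim_config())$overlaps)
#' consistent_sympatric_range(obs, sw)
#' }
#' @export
consistent_sympatric_range <- function(observed, sweep) {
  req <- c("n", "z", "c", "bimodality")
  if (!all(req %in% names(observed))) {
    stop("`observed` needs columns n, z, c, bimodality", call. = FALSE)
  }
  observed <- tibble::as_tibble(observed)[1, req]
  n <- observed$n

  params <- c("movement_sd", "movement_mean", "ancestral_fraction", "geometry")
  cells <- sweep |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(params, "n_sympatric")))) |>
    dplyr::summarise(
      z_ok = percentile_consistency(observed$z, z),
      c_ok = percentile_consistency(observed$c, c),
      bimodality_ok = percentile_consistency(observed$bimodality, bimodality),
      .groups = "drop"
    ) |>
    dplyr::mutate(joint_ok = z_ok & c_ok & bimodality_ok)

  range_of <- function(flag) {
    ks <- sort(unique(cells$n_sympatric[flag]))
    if (length(ks) == 0) {
      tibble::tibble(min_fraction = NA_real_, max_fraction = NA_real_)
    } else {
      tibble::tibble(min_fraction = min(ks) / n, max_fraction = max(ks) / n)
    }
  }
  per_index <- dplyr::bind_rows(
    dplyr::mutate(range_of(cells$z_ok), index = "z", .before = 1),
    dplyr::mutate(range_of(cells$c_ok), index = "c", .before = 1),
    dplyr::mutate(range_of(cells$bimodality_ok), index = "bimodality",
      .before = 1
    )
  )
  joint <- range_of(cells$joint_ok)

  structure(
    list(
      cells = cells, per_index = per_index, joint = joint,
      observed = observed
    ),
    class = "sympatry_inference"
  )
}

#' @export
print.sympatry_inference <- function(x, ...) {
  cat("<sympatry_inference>\n")
  cat(
    "  observed: n =", x$observed$n, " z =", x$observed$z,
    " c =", x$observed$c,
    " bimodality =", format(round(x$observed$bimodality, 3)), "\n"
  )
  if (is.na(x$joint$min_fraction)) {
    cat("  no sympatric fraction jointly consistent with the data\n")
  } else {
    cat(sprintf(
      "  jointly consistent sympatric fraction: %.0f%% - %.0f%%\n",
      100 * x$joint$min_fraction, 100 * x$joint$max_fraction
    ))
  }
  invisible(x)
}

#' @method tidy sympatry_inference
#' @export
tidy.sympatry_inference <- function(x, ...) x$cells

#' @method glance sympatry_inference
#' @export
glance.sympatry_inference <- function(x, ...) x$joint

#' Age-range correlation
#'
#' Ordinary least squares regression of the angular-transformed overlap
#' index on phylogenetic branch length, fitted to sister pairs only. The
#' intercept estimates the fraction of speciation events that were
#' sympatric (after back-transforming with `sin^2`); the slope measures the
#' drift of overlap with age.
#'
#' @param data Optional sister-pair data frame with columns
#'   `branch_length_my` and `overlap_index`; alternatively supply the two
#'   vectors directly.
#' @param branch_lengths,overlaps Vectors used when `data` is `NULL`.
#' @return An object of class `arc_fit` wrapping the `lm` fit, with
#'   `tidy()`, `glance()` and `autoplot()` methods. `glance()` includes the
#'   back-transformed intercept.
#' @examples
#' pairs <- gen_pair_table(22, sympatric_fraction = 0.5, seed = 2)
#' fit <- arc_regression(pairs)
#' glance(fit)
#' @export
arc_regression <- function(data = NULL, branch_lengths = NULL,
                           overlaps = NULL) {
  if (!is.null(data)) {
    branch_lengths <- data$branch_length_my
    overlaps <- data$overlap_index
  }
  if (length(branch_lengths) != length(overlaps)) {
    stop("branch lengths and overlaps must have equal length", call. = FALSE)
  }
  if (length(overlaps) < 3) {
    stop("at least 3 sister pairs are required", call. = FALSE)
  }
  if (stats::sd(branch_lengths) == 0) {
    stop("singular fit: branch lengths are constant", call. = FALSE)
  }
  theta <- angular_transform(overlaps)
  fit <- stats::lm(theta ~ branch_lengths)
  structure(
    list(
      fit = fit,
      data = tibble::tibble(
        branch_length_my = branch_lengths, overlap_index = overlaps,
        theta = theta
      )
    ),
    class = "arc_fit"
  )
}

arc_coef_table <- function(x) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("(Intercept)", "branch_length_my"),
    estimate = unname(s[, 1]), std.error = unname(s[, 2]),
    statistic = unname(s[, 3]), p.value = unname(s[, 4])
  )
}

#' @export
print.arc_fit <- function(x, ...) {
  co <- arc_coef_table(x)
  cat("<arc_fit> age-range correlation (angular scale), n =",
    nrow(x$data), "pairs\n"
  )
  cat(sprintf(
    "  intercept %.2f +/- %.2f  (back-transformed %.2f)\n",
    co$estimate[1], co$std.error[1],
    back_transform(min(max(co$estimate[1], 0), pi / 2))
  ))
  cat(sprintf(
    "  slope     %.2f +/- %.2f  (P = %.2f)\n",
    co$estimate[2], co$std.error[2], co$p.value[2]
  ))
  invisible(x)
}

#' @method tidy arc_fit
#' @export
tidy.arc_fit <- function(x, ...) arc_coef_table(x)

#' @method glance arc_fit
#' @export
glance.arc_fit <- function(x, ...) {
  co <- arc_coef_table(x)
  s <- summary(x$fit)
  tibble::tibble(
    intercept = co$estimate[1],
    intercept_se = co$std.error[1],
    slope = co$estimate[2],
    slope_se = co$std.error[2],
    slope_p = co$p.value[2],
    intercept_backtransformed =
      back_transform(min(max(co$estimate[1], 0), pi / 2)),
    r.squared = s$r.squared,
    n = nrow(x$data)
  )
}
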