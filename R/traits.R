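# Trait divergence: mimicry-ring and host-plant similarity between sister
# species, quasi-binomial regressions of similarity on divergence time,
# angular-scale regressions for climatic niche overlap, and the multiple
# regression of range overlap on ecological similarity.

#' Similarity of two trait sets
#'
#' The number of traits (mimicry rings, host plants) shared by the two
#' sisters divided by the number used by the sister with the smaller
#' repertoire, so a species whose traits are a subset of its sister's
#' scores 1. Labels are case-normalised before comparison.
#'
#' @param set_a,set_b Non-empty character vectors of trait labels.
#' @return Similarity fraction in \[0, 1\].
#' @examples
#' trait_similarity(c("a", "b", "c"), c("b", "c", "d", "e"))
#' @export
trait_similarity <- function(set_a, set_b) {
  set_a <- unique(tolower(trimws(as.character(set_a))))
  set_b <- unique(tolower(trimws(as.character(set_b))))
  if (length(set_a) == 0 || length(set_b) == 0) {
    stop("trait sets must be non-empty (similarity denominator undefined)",
      call. = FALSE
    )
  }
  length(intersect(set_a, set_b)) / min(length(set_a), length(set_b))
}

#' Shared and total trait counts for a sister pair
#'
#' Returns the numerator and denominator of [trait_similarity()] — the
#' counts needed by the binomial regression of similarity on branch length.
#'
#' @inheritParams trait_similarity
#' @return A one-row tibble with `x_shared`, `y_min` and `similarity`.
#' @export
trait_sharing_counts <- function(set_a, set_b) {
  set_a <- unique(tolower(trimws(as.character(set_a))))
  set_b <- unique(tolower(trimws(as.character(set_b))))
  if (length(set_a) == 0 || length(set_b) == 0) {
    stop("trait sets must be non-empty", call. = FALSE)
  }
  x <- length(intersect(set_a, set_b))
  y <- min(length(set_a), length(set_b))
  tibble::tibble(x_shared = x, y_min = y, similarity = x / y)
}

#' Inverse logit
#'
#' `1 / (1 + exp(-b))`, mapping a logit-scale coefficient to a proportion.
#'
#' @param b Finite numeric vector on the logit scale.
#' @return Proportions in (0, 1).
#' @examples
#' inverse_logit(-0.57)
#' @export
inverse_logit <- function(b) {
  if (any(!is.finite(b))) stop("input must be finite", call. = FALSE)
  stats::plogis(b)
}

#' Quasi-binomial regression of trait sharing on branch length
#'
#' Fits a binomial GLM with logit link of shared-trait counts (out of the
#' smaller sister's repertoire size) on branch length. The dispersion
#' parameter phi is estimated as the Pearson chi-square divided by the
#' residual degrees of freedom; when overdispersion is detected (phi > 1)
#' the standard errors are scaled by sqrt(phi), leaving the coefficient
#' estimates untouched (quasi-GLM with variance phi * mu).
#'
#' @param x_shared Integer vector: traits shared by each sister pair.
#' @param y_denominator Integer vector: repertoire size of the sister with
#'   fewer traits (so `x_shared <= y_denominator`).
#' @param branch_lengths Predictor: time since divergence (My).
#' @return An object of class `quasibin_fit` with `tidy()` and `glance()`
#'   methods. Fields include `dispersion`, `overdispersed`, corrected and
#'   naive standard errors, the back-transformed intercept and flags for
#'   separation or non-convergence.
#' @examples
#' fit <- quasibinomial_regression(c(1, 2, 0, 3), c(3, 4, 2, 3),
#'   c(0.5, 1.2, 2.0, 3.1))
#' tidy(fit)
#' @export
quasibinomial_regression <- function(x_shared, y_denominator, branch_lengths) {
  n <- length(x_shared)
  if (length(y_denominator) != n || length(branch_lengths) != n) {
    stop("all inputs must have equal length", call. = FALSE)
  }
  if (n < 3) stop("at least 3 pairs are required", call. = FALSE)
  if (any(x_shared < 0) || any(x_shared > y_denominator)) {
    stop("`x_shared` must lie between 0 and `y_denominator`", call. = FALSE)
  }
  fit <- suppressWarnings(stats::glm(
    cbind(x_shared, y_denominator - x_shared) ~ branch_lengths,
    family = stats::binomial()
  ))
  mu <- stats::fitted(fit)
  degenerate <- all(x_shared == y_denominator) || all(x_shared == 0)
  separation <- degenerate || any(abs(stats::coef(fit)) > 15) ||
    !fit$converged
  pearson <- sum(stats::residuals(fit, type = "pearson")^2)
  df <- n - 2
  phi <- pearson / df
  s <- summary(fit)$coefficients
  naive_se <- s[, 2]
  overdispersed <- is.finite(phi) && phi > 1
  corrected_se <- if (overdispersed) naive_se * sqrt(phi) else naive_se
  est <- s[, 1]
  stat <- est / corrected_se
  # quasi-GLM inference: t distribution on the residual df
  pval <- 2 * stats::pt(-abs(stat), df = df)
  structure(
    list(
      fit = fit,
      coefficients = tibble::tibble(
        term = c("(Intercept)", "branch_length"),
        estimate = unname(est),
        naive_se = unname(naive_se),
        std.error = unname(corrected_se),
        statistic = unname(stat),
        p.value = unname(pval)
      ),
      dispersion = phi,
      overdispersed = overdispersed,
      separation = separation,
      converged = fit$converged,
      intercept_backtransformed = inverse_logit(unname(est[1])),
      n = n
    ),
    class = "quasibin_fit"
  )
}

#' @export
print.quasibin_fit <- function(x, ...) {
  cat("<quasibin_fit> trait sharing ~ branch length, n =", x$n, "pairs\n")
  if (x$separation) {
    cat("  WARNING: separation or non-convergence; estimates unreliable\n")
  }
  co <- x$coefficients
  cat(sprintf(
    "  intercept %.2f +/- %.2f (logit scale; %.2f as a proportion)\n",
    co$estimate[1], co$std.error[1], x$intercept_backtransformed
  ))
  cat(sprintf(
    "  slope     %.2f +/- %.2f\n", co$estimate[2], co$std.error[2]
  ))
  cat(sprintf(
    "  dispersion phi = %.2f%s\n", x$dispersion,
    if (x$overdispersed) " (overdispersed; SEs corrected by sqrt(phi))" else ""
  ))
  invisible(x)
}

#' @method tidy quasibin_fit
#' @export
tidy.quasibin_fit <- function(x, ...) x$coefficients

#' @method glance quasibin_fit
#' @export
glance.quasibin_fit <- function(x, ...) {
  tibble::tibble(
    dispersion = x$dispersion,
    overdispersed = x$overdispersed,
    separation = x$separation,
    converged = x$converged,
    intercept_backtransformed = x$intercept_backtransformed,
    n = x$n
  )
}

#' Regression of climatic niche overlap on branch length
#'
#' Simple linear regression with angular-transformed niche overlap as the
#' response, mirroring the age-range correlation machinery.
#'
#' @param niche_overlaps Niche overlap fractions in \[0, 1\].
#' @param branch_lengths Time since divergence (My).
#' @return An `arc_fit` object (see [arc_regression()]).
#' @export
climate_regression <- function(niche_overlaps, branch_lengths) {
  arc_regression(
    branch_lengths = branch_lengths,
    overlaps = niche_overlaps
  )
}

#' Multiple regression of range overlap on ecological similarity
#'
#' OLS of angular-transformed geographic range overlap on branch length and
#' the three ecological similarity measures (mimicry, host plant, climatic
#' niche), using complete cases only.
#'
#' @param data A sister-pair data frame with columns `overlap_index`,
#'   `branch_length_my`, `mimicry_similarity`, `host_similarity`,
#'   `climate_overlap` (alternatively supply the vectors).
#' @param range_overlap,branch_length,mimicry_sim,host_sim,climate_sim
#'   Vectors used when `data` is `NULL`.
#' @return A tibble with one row per model term: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`. A rank-deficient design triggers
#'   a warning and drops aliased terms from the table.
#' @export
overlap_multiple_regression <- function(data = NULL, range_overlap = NULL,
                                        branch_length = NULL,
                                        mimicry_sim = NULL, host_sim = NULL,
                                        climate_sim = NULL) {
  if (!is.null(data)) {
    range_overlap <- data$overlap_index
    branch_length <- data$branch_length_my
    mimicry_sim <- data$mimicry_similarity
    host_sim <- data$host_similarity
    climate_sim <- data$climate_overlap
  }
  d <- tibble::tibble(
    theta = NA_real_,
    branch_length = branch_length,
    mimicry_overlap = mimicry_sim,
    host_plant_overlap = host_sim,
    climatic_niche_overlap = climate_sim,
    .rows = length(range_overlap)
  )
  keep <- stats::complete.cases(d[-1]) & !is.na(range_overlap)
  d <- d[keep, ]
  range_overlap <- range_overlap[keep]
  if (nrow(d) < 6) {
    stop("need more complete cases than predictors plus intercept",
      call. = FALSE
    )
  }
  d$theta <- angular_transform(range_overlap)
  fit <- stats::lm(
    theta ~ branch_length + mimicry_overlap + host_plant_overlap +
      climatic_niche_overlap,
    data = d
  )
  if (any(is.na(stats::coef(fit)))) {
    warning("rank-deficient design: aliased terms dropped from the fit",
      call. = FALSE
    )
  }
  s <- summary(fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}
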