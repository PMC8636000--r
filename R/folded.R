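#' Moments of the folded normal distribution
#'
#' If `X ~ Normal(mu, sigma^2)`, then `|X|` follows a folded normal with
#' mean `sigma * sqrt(2/pi) * exp(-mu^2 / (2 sigma^2)) + mu * (1 - 2 *
#' pnorm(-mu/sigma))` and variance `mu^2 + sigma^2 - mean^2`. These moments
#' assign the correct sampling variance to absolute-value effect sizes: an
#' estimated selection gradient `delta_beta` with standard error `se` yields
#' `|delta_beta|` with sampling variance `folded_moments(delta_beta, se)$variance`,
#' which is never larger than `se^2`.
#'
#' @param mu Numeric vector of normal means.
#' @param sigma Numeric vector of normal SDs, all `> 0` (recycled).
#' @return A tibble with columns `mu`, `sigma`, `mean`, `variance`.
#' @export
#' @examples
#' folded_moments(0, 1)  # mean sqrt(2/pi), variance 1 - 2/pi
folded_moments <- function(mu, sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    abort("sigma must be positive and finite", class = "florsel_domain_error")
  }
  k <- vctrs_recycle(mu, sigma)
  mu <- k[[1]]; sigma <- k[[2]]
  m <- sigma * sqrt(2 / pi) * exp(-mu^2 / (2 * sigma^2)) +
    mu * (1 - 2 * pnorm(-mu / sigma))
  v <- mu^2 + sigma^2 - m^2
  tibble::tibble(mu = mu, sigma = sigma, mean = m, variance = pmax(v, 0))
}

vctrs_recycle <- function(a, b) {
  n <- max(length(a), length(b))
  list(rep_len(a, n), rep_len(b, n))
}

#' Fold mediated-selection estimates into meta-regression points
#'
#' Takes per-population herbivore-mediated selection estimates and the
#' population herbivory intensities and builds the summary-level points for
#' the across-population measurement-error regressions: `y = |delta_beta|`
#' with known sampling SE equal to the square root of the folded-normal
#' variance at `(delta_beta, se)`, and `x` the population mean
#' herbivore-present intensity (original scale, untransformed).
#'
#' @param mediated A [mediated_selection()] tibble (needs `population_id`,
#'   `trait`, `delta_beta`, `se`).
#' @param intensity A [population_intensity()] tibble for the HP treatment
#'   (needs `population_id`, `mean`).
#' @return A tibble with columns `population`, `trait`, `x`, `y`, `se`.
#' @export
fold_points <- function(mediated, intensity) {
  if (nrow(mediated) == 0) {
    abort("no mediated-selection estimates to fold",
          class = "florsel_domain_error")
  }
  fm <- folded_moments(mediated$delta_beta, mediated$se)
  out <- tibble::tibble(
    population = mediated$population_id,
    trait = mediated$trait,
    y = abs(mediated$delta_beta),
    se = sqrt(fm$variance)
  )
  ix <- dplyr::select(intensity, population = "population_id", x = "mean")
  out <- dplyr::inner_join(out, ix, by = "population")
  dplyr::select(out, "population", "trait", "x", "y", "se")
}
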