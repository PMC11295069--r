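#' Poisson droplet-occupancy probability
#'
#' Probability that a droplet contains exactly `k` cells when cells are loaded
#' at random into monodisperse droplets, so that occupancy follows a Poisson
#' distribution with mean `lam` cells per droplet:
#' \deqn{p(k, \lambda) = \lambda^k e^{-\lambda} / k!}
#'
#' @param lam mean number of cells per droplet (\eqn{\lambda \ge 0}).
#' @param k integer cell count (vectorized, each \eqn{\ge 0}).
#' @return probability (or vector of probabilities) in \[0, 1\].
#' @export
#' @examples
#' occupancy_pmf(0.1, 0) # ~0.905: ~90.5% of droplets empty at lambda = 0.1
occupancy_pmf <- function(lam, k) {
  check_number(lam, "lam", lower = 0)
  if (length(k) < 1L || !is.numeric(k) || any(is.na(k)) ||
      any(k < 0) || any(k != floor(k))) {
    stopf("`k` must be non-negative integer(s)")
  }
  stats::dpois(k, lam)
}

#' Droplet occupancy profile at a loading density
#'
#' Splits a Poisson-loaded droplet population into the three fractions that
#' matter for single-cell screening: empty droplets, droplets with exactly one
#' cell (the genotype-phenotype-coupled events), and droplets with more than
#' one cell (co-encapsulation events to be minimized).
#'
#' @param lam mean cells per droplet.
#' @return an `occupancy_profile` object with fields `lam`, `p_empty`,
#'   `p_single`, `p_multi` (probabilities summing to 1). `p_single + p_multi`
#'   is the overall droplet occupancy (fraction of cell-laden droplets).
#' @seealso [occupancy_percents()] for the rounded percentage report.
#' @export
#' @examples
#' occupancy_fractions(0.1)
occupancy_fractions <- function(lam) {
  check_number(lam, "lam", lower = 0)
  p0 <- stats::dpois(0, lam)
  p1 <- stats::dpois(1, lam)
  structure(
    list(lam = lam, p_empty = p0, p_single = p1, p_multi = 1 - p0 - p1),
    class = "occupancy_profile"
  )
}

#' @export
print.occupancy_profile <- function(x, ...) {
  pct <- occupancy_percents(x)
  cat(sprintf("Droplet occupancy at lambda = %g cells/droplet\n", x$lam))
  cat(sprintf("  empty   : %5.1f%%\n", pct[["empty"]]))
  cat(sprintf("  single  : %5.1f%%\n", pct[["single"]]))
  cat(sprintf("  multi   : %5.1f%%\n", pct[["multi"]]))
  cat(sprintf("  occupied: %5.1f%%\n", pct[["occupied"]]))
  invisible(x)
}

#' Occupancy profile as rounded percentages
#'
#' Reports an [occupancy_fractions()] profile as percentages rounded half-up
#' to `digits` decimals. Both single-cell occupancy (`single`) and overall
#' occupancy (`occupied` = 100 - empty) are reported, since design targets are
#' quoted both ways (e.g. ~9.0% single-cell vs ~9.5% occupied at lambda 0.1).
#'
#' @param profile an `occupancy_profile`.
#' @param digits decimal places for the half-up rounding (default 1).
#' @return named numeric: `empty`, `single`, `multi`, `occupied` (percent).
#' @export
occupancy_percents <- function(profile, digits = 1) {
  stopifnot(inherits(profile, "occupancy_profile"))
  round_half_up(100 * c(
    empty = profile$p_empty,
    single = profile$p_single,
    multi = profile$p_multi,
    occupied = 1 - profile$p_empty
  ), digits)
}

#' Estimate lambda from the empty-droplet fraction
#'
#' Inverts the Poisson zero term: if a fraction `empty_fraction` of droplets
#' is empty, the loading density is \eqn{\lambda = -\ln(p_0)}.
#'
#' @param empty_fraction observed fraction of empty droplets, in (0, 1\].
#' @return estimated mean cells per droplet.
#' @export
estimate_lambda <- function(empty_fraction) {
  check_number(empty_fraction, "empty_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  -log(empty_fraction)
}

#' Droplet volume in millilitres
#'
#' Volume of a spherical droplet of the given diameter.
#'
#' @param diameter_um droplet diameter in micrometres (> 0).
#' @return volume in mL.
#' @export
droplet_volume_ml <- function(diameter_um) {
  check_number(diameter_um, "diameter_um", lower = 0, strict_lower = TRUE)
  # 1 mL = 1 cm^3 = 1e12 um^3
  (pi / 6) * diameter_um^3 * 1e-12
}

#' Convert a cell concentration to mean cells per droplet
#'
#' The loading density is the expected number of cells in one droplet volume:
#' \eqn{\lambda = c \cdot \pi d^3 / 6} (with the volume in mL). At the 49 um
#' droplets used for single-cell screening, ~1.6 million CFU/mL gives
#' \eqn{\lambda \approx 0.1}.
#'
#' @param conc cell concentration in CFU per mL (>= 0).
#' @param droplet_diameter droplet diameter in micrometres (> 0).
#' @return mean cells per droplet.
#' @export
#' @examples
#' concentration_to_lambda(1.6e6, 49) # ~0.1
concentration_to_lambda <- function(conc, droplet_diameter) {
  check_number(conc, "conc", lower = 0)
  conc * droplet_volume_ml(droplet_diameter)
}

#' Convert a target lambda to the required cell concentration
#'
#' Inverse of [concentration_to_lambda()].
#'
#' @param lam target mean cells per droplet (>= 0).
#' @param droplet_diameter droplet diameter in micrometres (> 0).
#' @return concentration in CFU per mL.
#' @export
lambda_to_concentration <- function(lam, droplet_diameter) {
  check_number(lam, "lam", lower = 0)
  lam / droplet_volume_ml(droplet_diameter)
}
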