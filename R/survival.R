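# CFU serial-dilution math and UV dose-survival statistics.

#' Dilution-plate record
#'
#' One plated dilution: the dilution factor, the plated drop volume, and the
#' replicate colony counts.
#'
#' @param dilution dilution factor in (0, 1\].
#' @param counts non-negative integer colony counts (one per replicate drop).
#' @param drop_volume_ml plated drop volume in mL (default 0.005 = 5 uL).
#' @return a `dilution_plate` list.
#' @export
dilution_plate <- function(dilution, counts, drop_volume_ml = 0.005) {
  check_number(dilution, "dilution", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(drop_volume_ml, "drop_volume_ml", lower = 0, strict_lower = TRUE)
  if (length(counts) < 1 || any(counts < 0) || any(counts != floor(counts))) {
    stopf("`counts` must be non-negative integers")
  }
  structure(
    list(dilution = dilution, counts = as.integer(counts),
         drop_volume_ml = drop_volume_ml, n_replicates = length(counts)),
    class = "dilution_plate"
  )
}

#' Back-calculate stock concentration from a dilution plate
#'
#' Averages the replicate colony counts and back-calculates the stock
#' concentration: `mean(counts) / (drop_volume_ml * dilution)`. An all-zero
#' plate returns 0 CFU/mL flagged as below detection (attribute
#' `below_detection`), rather than an imputed value.
#'
#' @param plate a [dilution_plate()].
#' @return CFU per mL, with attribute `below_detection` (logical).
#' @export
#' @examples
#' cfu_from_dilution(dilution_plate(1e-3, c(11, 12, 13, 12, 11, 13))) # 2.4e6
cfu_from_dilution <- function(plate) {
  stopifnot(inherits(plate, "dilution_plate"))
  m <- mean(plate$counts)
  structure(m / (plate$drop_volume_ml * plate$dilution),
            below_detection = (m == 0))
}

#' Pick the countable dilution
#'
#' From a series of plates, selects the most concentrated dilution whose mean
#' count lies in a countable window (default 3 to 30 colonies per drop) —
#' dense plates are uncountable, sparse ones noisy.
#'
#' @param plates list of [dilution_plate()] objects.
#' @param min_count,max_count countable-window bounds on the mean count.
#' @return the selected `dilution_plate`.
#' @export
select_countable <- function(plates, min_count = 3, max_count = 30) {
  if (length(plates) == 0) stopf("no plates supplied")
  means <- vapply(plates, function(p) mean(p$counts), numeric(1))
  dils <- vapply(plates, function(p) p$dilution, numeric(1))
  ok <- which(means >= min_count & means <= max_count)
  if (length(ok) == 0) {
    stopf("no dilution has a countable mean in [%g, %g]", min_count, max_count)
  }
  plates[[ok[which.max(dils[ok])]]]
}

#' Survival rate relative to an unexposed control
#'
#' `100 * exposed_cfu / control_cfu`, in percent; can exceed 100 when the
#' exposed culture outgrows the control.
#'
#' @param exposed_cfu CFU/mL of the exposed culture (>= 0).
#' @param control_cfu CFU/mL of the unexposed control (> 0).
#' @return survival in percent.
#' @export
survival_rate <- function(exposed_cfu, control_cfu) {
  check_number(exposed_cfu, "exposed_cfu", lower = 0)
  check_number(control_cfu, "control_cfu", lower = 0, strict_lower = TRUE)
  100 * exposed_cfu / control_cfu
}

#' Fold change in concentration
#'
#' `after / before`; reports round half-up to the nearest integer fold
#' (e.g. recovery growth from 4.7 to 38.7 million CFU/mL is an ~8-fold
#' increase).
#'
#' @param before starting concentration (> 0).
#' @param after final concentration (>= 0).
#' @return exact fold change.
#' @export
#' @examples
#' fold_change(4.7e6, 38.7e6) # 8.23..., reported as 8-fold
fold_change <- function(before, after) {
  check_number(before, "before", lower = 0, strict_lower = TRUE)
  check_number(after, "after", lower = 0)
  after / before
}

#' Log-linear dose-survival slope
#'
#' Least-squares slope of `ln(survival)` against dose across survival points,
#' summarizing the kill curve as a single exponential decay rate. Points with
#' zero survival carry no log information and are dropped.
#'
#' @param points data frame with columns `dose` (mJ/cm2) and `survival`
#'   (fraction of control, > 0 to be usable); at least 2 usable points.
#' @return list with `slope` (per mJ/cm2; negative for decaying survival),
#'   `intercept`, and the fitted `lm` object as `model`.
#' @export
survival_curve <- function(points) {
  if (!all(c("dose", "survival") %in% names(points))) {
    stopf("`points` must have columns `dose` and `survival`")
  }
  use <- points$survival > 0
  if (sum(use) < 2) stopf("need at least 2 points with survival > 0")
  fit <- stats::lm(log(survival) ~ dose, data = points[use, , drop = FALSE])
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       model = fit)
}
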