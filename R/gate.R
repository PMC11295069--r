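# FADS gate statistics: voltage gating of event streams, sort summaries,
# threshold derivation for a target top fraction.

#' Sorting-gate configuration
#'
#' @param threshold sorting threshold, volts; droplets with cellulose-channel
#'   signal strictly above it are sorted.
#' @param baseline_target fluorescein detection floor, volts (default 0.05,
#'   the sorting-run baseline).
#' @return a `gate_config` list.
#' @export
gate_config <- function(threshold, baseline_target = 0.05) {
  check_number(baseline_target, "baseline_target", lower = 0)
  check_number(threshold, "threshold", lower = baseline_target,
               strict_lower = TRUE)
  structure(list(threshold = threshold, baseline_target = baseline_target),
            class = "gate_config")
}

#' Apply a voltage gate to an event stream
#'
#' Sorts every droplet whose `cellulose_v` strictly exceeds the gate
#' threshold and summarizes the sort. Occupied droplets are counted from the
#' `true_occupancy` column when present (simulation mode); otherwise any
#' droplet above `occupied_cut` (default twice the fluorescein baseline) is
#' counted as cell-laden.
#'
#' @param events event tibble with a `cellulose_v` column (see
#'   [generate_event_stream()]).
#' @param config a [gate_config()].
#' @param occupied_cut signal cut used to count cell-laden droplets when no
#'   ground truth is available.
#' @return list with `sorted` (the gated subset, same columns) and `summary`
#'   (a [sort_statistics()] object).
#' @export
gate_events <- function(events, config,
                        occupied_cut = 2 * config$baseline_target) {
  stopifnot(inherits(config, "gate_config"))
  if (!"cellulose_v" %in% names(events) || nrow(events) == 0) {
    stopf("`events` must be a non-empty stream with a `cellulose_v` column")
  }
  hit <- events$cellulose_v > config$threshold
  n_occupied <- if ("true_occupancy" %in% names(events)) {
    sum(events$true_occupancy >= 1)
  } else {
    sum(events$cellulose_v > occupied_cut)
  }
  list(
    sorted = events[hit, , drop = FALSE],
    summary = sort_statistics(sum(hit), nrow(events), n_occupied)
  )
}

#' Sort summary statistics
#'
#' Exact ratio arithmetic for a sort: the sorted fraction of all droplets and
#' of cell-laden ("mutant-laden") droplets, both as percentages.
#'
#' @param n_sorted droplets pulled by the gate (>= 0).
#' @param n_total droplets screened (> 0).
#' @param n_occupied cell-laden droplets among them (> 0).
#' @return a `sort_summary` with fields `n_sorted`, `n_total`, `n_occupied`,
#'   `frac_of_all`, `frac_of_occupied` (exact percents; the print method
#'   rounds half-up to 2 decimals).
#' @export
#' @examples
#' sort_statistics(500, 430000, 40000) # 0.12% of all, 1.25% of occupied
sort_statistics <- function(n_sorted, n_total, n_occupied) {
  check_number(n_sorted, "n_sorted", lower = 0)
  check_number(n_total, "n_total", lower = 0, strict_lower = TRUE)
  check_number(n_occupied, "n_occupied", lower = 0, strict_lower = TRUE)
  structure(
    list(n_sorted = n_sorted, n_total = n_total, n_occupied = n_occupied,
         frac_of_all = 100 * n_sorted / n_total,
         frac_of_occupied = 100 * n_sorted / n_occupied),
    class = "sort_summary"
  )
}

#' @export
print.sort_summary <- function(x, ...) {
  cat(sprintf("Sorted %d of %d droplets (%0.2f%% of all, %0.2f%% of %d cell-laden)\n",
              x$n_sorted, x$n_total,
              round_half_up(x$frac_of_all, 2),
              round_half_up(x$frac_of_occupied, 2),
              x$n_occupied))
  invisible(x)
}

#' Gate threshold for a target top fraction
#'
#' The voltage at which a strict gate passes the top `target` percent of
#' occupied-droplet signals: the lower empirical (type-1) quantile at
#' probability `1 - target/100`, so the sorted count never exceeds the target
#' count. Re-gating at the returned threshold recovers the target fraction to
#' within one droplet.
#'
#' @param events event tibble with `true_occupancy` ground truth, or a
#'   numeric vector of occupied-droplet signals.
#' @param target_fraction_of_occupied target percent of occupied droplets to
#'   sort, in (0, 100\].
#' @return threshold in volts.
#' @export
#' @examples
#' threshold_for_top_fraction(1:100, 10) # 90: ten signals exceed it
threshold_for_top_fraction <- function(events, target_fraction_of_occupied) {
  check_number(target_fraction_of_occupied, "target_fraction_of_occupied",
               lower = 0, upper = 100, strict_lower = TRUE)
  s <- if (is.numeric(events)) {
    events
  } else {
    if (!"true_occupancy" %in% names(events)) {
      stopf("`events` needs `true_occupancy` to identify occupied droplets")
    }
    events$cellulose_v[events$true_occupancy >= 1]
  }
  if (length(s) == 0) stopf("no occupied droplets in the stream")
  p <- 1 - target_fraction_of_occupied / 100
  if (p <= 0) {
    # top 100%: gate strictly below the weakest occupied signal
    return(min(s) - max(1e-9, 1e-9 * abs(min(s))))
  }
  unname(stats::quantile(s, p, type = 1))
}

#' Selection enrichment factor
#'
#' Ratio of the mean phenotype after versus before a selection gate.
#'
#' @param pre_mean mean phenotype before selection (> 0).
#' @param post_mean mean phenotype after selection.
#' @return dimensionless fold enrichment.
#' @export
enrichment_factor <- function(pre_mean, post_mean) {
  check_number(pre_mean, "pre_mean", lower = 0, strict_lower = TRUE)
  check_number(post_mean, "post_mean")
  post_mean / pre_mean
}
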