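# Droplet detector-event streams: Poisson encapsulation of library cells,
# fluorescein baseline channel, cellulose-dye channel in volts.

#' Event-stream generator configuration
#'
#' The detector model: every droplet carries a fluorescein baseline adjusted
#' to `baseline_mean` volts (0.1 V in screening runs, 0.05 V in sorting runs).
#' An occupied droplet adds, on the cellulose channel, the summed production
#' of its occupants over the incubation time, mapped to volts by a single
#' scale constant:
#' \deqn{V = V_{baseline} + s \cdot \sum_i r_i \cdot t + \epsilon}
#' with \eqn{r_i} the occupants' production rates (units/h), \eqn{t} the
#' incubation (h), \eqn{s} = `volts_per_rate_hour` and Gaussian noise
#' \eqn{\epsilon}. The default scale 0.012 V per unit-hour anchors a native
#' single cell (rate 1, 24 h) at 0.388 V over a 0.1 V baseline — the
#' native-strain middle-component mean on the normalized screening scale.
#'
#' @param n_events number of droplets in the stream (> 0).
#' @param lam mean cells per droplet (>= 0).
#' @param baseline_mean fluorescein baseline, volts.
#' @param baseline_sd detector noise on empty-droplet signals, volts.
#' @param signal_sd within-strain noise on occupied-droplet signals, volts.
#' @param incubation_hours droplet incubation time, hours.
#' @param volts_per_rate_hour volts per (production-rate unit x hour).
#' @param seed integer seed or NULL.
#' @return a `stream_config` list.
#' @export
stream_config <- function(n_events,
                          lam = 0.1,
                          baseline_mean = 0.1,
                          baseline_sd = 0.01,
                          signal_sd = 0.05,
                          incubation_hours = 24,
                          volts_per_rate_hour = 0.012,
                          seed = NULL) {
  check_number(n_events, "n_events", lower = 1)
  check_number(lam, "lam", lower = 0)
  check_number(baseline_mean, "baseline_mean", lower = 0)
  check_number(baseline_sd, "baseline_sd", lower = 0)
  check_number(signal_sd, "signal_sd", lower = 0)
  check_number(incubation_hours, "incubation_hours", lower = 0)
  check_number(volts_per_rate_hour, "volts_per_rate_hour", lower = 0)
  structure(
    list(n_events = as.integer(n_events), lam = lam,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         signal_sd = signal_sd, incubation_hours = incubation_hours,
         volts_per_rate_hour = volts_per_rate_hour, seed = seed),
    class = "stream_config"
  )
}

#' Generate a droplet detector-event stream
#'
#' Encapsulates cells from a library into droplets with Poisson(`lam`)
#' occupancy, occupants drawn (with replacement) from the library's viable
#' cells, optionally weighted by relative abundance. Empty droplets emit only
#' the fluorescein baseline; occupied droplets add their occupants' summed
#' cellulose signal (see [stream_config()]).
#'
#' @param variants library tibble ([generate_library()] or
#'   [clonal_library()]).
#' @param config a [stream_config()].
#' @param weights optional non-negative relative abundance for each row of
#'   `variants` (defaults to uniform over viable cells).
#' @return tibble with columns `droplet_id`, `baseline_v`, `cellulose_v`,
#'   `true_occupancy`, `variant_ids` (";"-joined, "" when empty). The
#'   droplet-by-occupant table is attached as attribute `"occupants"`
#'   (columns `droplet_id`, `variant_id`, `production_rate`), and the config
#'   as `"config"`.
#' @export
generate_event_stream <- function(variants, config, weights = NULL) {
  stopifnot(inherits(config, "stream_config"))
  if (config$lam < 0) stopf("`lam` must be >= 0")
  viable_idx <- which(variants$viable)
  if (config$lam > 0 && length(viable_idx) == 0) {
    stopf("no viable variants to encapsulate at lam > 0")
  }
  if (!is.null(weights)) {
    if (length(weights) != nrow(variants) || any(weights < 0)) {
      stopf("`weights` must be non-negative, one per variant")
    }
    w <- weights[viable_idx]
    if (sum(w) <= 0) stopf("all viable-variant weights are zero")
  } else {
    w <- NULL
  }

  local_seed_if(config$seed)
  n <- config$n_events
  occ <- stats::rpois(n, config$lam)
  total <- sum(occ)

  baseline_v <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)

  signal_scale <- config$incubation_hours * config$volts_per_rate_hour
  if (total > 0) {
    pick <- if (is.null(w)) {
      viable_idx[sample.int(length(viable_idx), total, replace = TRUE)]
    } else {
      viable_idx[sample.int(length(viable_idx), total, replace = TRUE, prob = w)]
    }
    droplet_of <- rep.int(seq_len(n), occ)
    rate_sum <- numeric(n)
    agg <- rowsum(variants$production_rate[pick], droplet_of)
    rate_sum[as.integer(rownames(agg))] <- agg[, 1]
    ids_by_droplet <- split(variants$id[pick], droplet_of)
    variant_ids <- character(n)
    variant_ids[as.integer(names(ids_by_droplet))] <-
      vapply(ids_by_droplet, paste, character(1), collapse = ";")
    occupants <- tibble::tibble(
      droplet_id = droplet_of,
      variant_id = variants$id[pick],
      production_rate = variants$production_rate[pick]
    )
  } else {
    rate_sum <- numeric(n)
    variant_ids <- character(n)
    occupants <- tibble::tibble(
      droplet_id = integer(0), variant_id = character(0),
      production_rate = numeric(0)
    )
  }

  occupied <- occ > 0
  cellulose_v <- numeric(n)
  # empty droplets: baseline with detector noise only
  cellulose_v[!occupied] <- stats::rnorm(
    sum(!occupied), config$baseline_mean, config$baseline_sd
  )
  # occupied droplets: baseline + deposited signal + within-strain noise
  cellulose_v[occupied] <- config$baseline_mean +
    rate_sum[occupied] * signal_scale +
    stats::rnorm(sum(occupied), 0, config$signal_sd)

  out <- tibble::tibble(
    droplet_id = seq_len(n),
    baseline_v = baseline_v,
    cellulose_v = cellulose_v,
    true_occupancy = occ,
    variant_ids = variant_ids
  )
  attr(out, "occupants") <- occupants
  attr(out, "config") <- config
  out
}

#' Production rate that maps to a target middle mean
#'
#' Inverts the signal model of [stream_config()]: the production rate whose
#' single-occupant droplets average `middle_mean_v` volts under `config`.
#' Useful for calibrating clonal strain pools to published strain means.
#'
#' @param middle_mean_v target occupied-peak mean, volts.
#' @param config a [stream_config()].
#' @return production rate in units/h.
#' @export
#' @examples
#' rate_for_middle_mean(0.388, stream_config(1000)) # 1: the native rate
rate_for_middle_mean <- function(middle_mean_v, config) {
  stopifnot(inherits(config, "stream_config"))
  check_number(middle_mean_v, "middle_mean_v", lower = config$baseline_mean)
  scale <- config$incubation_hours * config$volts_per_rate_hour
  if (scale <= 0) stopf("signal scale is zero; rate is unidentifiable")
  (middle_mean_v - config$baseline_mean) / scale
}

#' Sample from a finite Gaussian mixture
#'
#' Draws `n` values from the mixture with the given component weights, means,
#' and SDs. The generating component of each draw is returned alongside the
#' value, so fits can be checked against ground truth.
#'
#' @param n sample size.
#' @param weights component weights (summing to 1).
#' @param means component means.
#' @param sds component SDs (>= 0).
#' @param seed integer seed or NULL.
#' @return tibble with columns `value` and `component` (1-based index).
#' @export
sample_mixture <- function(n, weights, means, sds, seed = NULL) {
  check_number(n, "n", lower = 1)
  k <- length(weights)
  if (length(means) != k || length(sds) != k) {
    stopf("`weights`, `means`, `sds` must have equal length")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stopf("`weights` must be non-negative and sum to 1")
  }
  if (any(sds < 0)) stopf("`sds` must be >= 0")
  local_seed_if(seed)
  comp <- sample.int(k, n, replace = TRUE, prob = weights)
  tibble::tibble(
    value = stats::rnorm(n, means[comp], sds[comp]),
    component = comp
  )
}
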