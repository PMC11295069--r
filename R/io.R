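# File interfaces: event CSV, 16-bit TIFF images with ground-truth sidecars,
# YAML campaign configs, mixture-fit JSON.

#' Write / read a droplet event stream as CSV
#'
#' Columns: `droplet_id`, `baseline_v`, `cellulose_v`, `true_occupancy`,
#' `variant_ids` (";"-joined, empty string for empty droplets).
#'
#' @param events event tibble ([generate_event_stream()]).
#' @param path CSV file path.
#' @return `write_events_csv()` returns `path` invisibly; `read_events_csv()`
#'   returns the event tibble.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(
    as.data.frame(events[, c("droplet_id", "baseline_v", "cellulose_v",
                             "true_occupancy", "variant_ids")]),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(variant_ids = "character"))
  df$variant_ids[is.na(df$variant_ids)] <- ""
  tibble::as_tibble(df)
}

#' Write / read a droplet image as 16-bit TIFF
#'
#' Intensities are scaled by `max_value` into the 16-bit range on write and
#' scaled back on read, so values round-trip to within 1/65535 of
#' `max_value`. Values above `max_value` clip.
#'
#' @param image numeric matrix of intensities (>= 0).
#' @param path TIFF file path.
#' @param max_value intensity mapped to the top of the 16-bit range
#'   (default: the image maximum).
#' @return `write_droplet_tiff()` returns `max_value` invisibly;
#'   `read_droplet_tiff()` returns the image matrix (scaled by `max_value`).
#' @export
write_droplet_tiff <- function(image, path, max_value = max(image)) {
  stopifnot(is.matrix(image))
  check_number(max_value, "max_value", lower = 0, strict_lower = TRUE)
  scaled <- pmin(pmax(image / max_value, 0), 1)
  tiff::writeTIFF(scaled, path, bits.per.sample = 16)
  invisible(max_value)
}

#' @rdname write_droplet_tiff
#' @export
read_droplet_tiff <- function(path, max_value = 1) {
  tiff::readTIFF(path) * max_value
}

#' Write / read an image ground-truth sidecar CSV
#'
#' Columns: `droplet_id`, `center_x_px`, `center_y_px`, `radius_px`,
#' `occupancy`, `intensity` (see [generate_droplet_image()]).
#'
#' @param ground_truth ground-truth tibble.
#' @param path CSV file path.
#' @return `write_ground_truth_csv()` returns `path` invisibly;
#'   `read_ground_truth_csv()` returns the tibble.
#' @export
write_ground_truth_csv <- function(ground_truth, path) {
  utils::write.csv(as.data.frame(ground_truth), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth_csv
#' @export
read_ground_truth_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Read a campaign configuration from YAML
#'
#' Expects top-level keys `n_rounds`, `seed`, `recovery_hours`,
#' `n_colonies_picked`, and nested `library`, `stream`, and `gates` (a list
#' of `{threshold, baseline_target}` entries, one per round or a single
#' entry recycled). Missing fields fall back to the package defaults. A
#' `library$survival_curve` mapping uses doses as keys.
#'
#' @param path YAML file path.
#' @return a [campaign_config()].
#' @export
read_campaign_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  lib_args <- y$library %||% list()
  if (!is.null(lib_args$survival_curve)) {
    sc <- unlist(lib_args$survival_curve)
    lib_args$survival_curve <- stats::setNames(as.numeric(sc), names(sc))
  }
  lib <- do.call(library_config, lib_args)
  stream <- do.call(stream_config, y$stream %||% list())
  gates_raw <- y$gates
  if (is.null(gates_raw)) stopf("campaign YAML must define `gates`")
  gates <- lapply(gates_raw, function(g) do.call(gate_config, g))
  if (length(gates) == 1) gates <- gates[[1]]
  campaign_config(
    n_rounds = y$n_rounds %||% length(gates_raw),
    library = lib, stream = stream, gates = gates,
    recovery_hours = y$recovery_hours %||% 50,
    n_colonies_picked = y$n_colonies_picked %||% 5,
    seed = y$seed %||% 1
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a mixture fit as JSON
#'
#' Serializes weights, means, SDs, the baseline anchor, and fit metadata.
#'
#' @param fit a [fit_mixture()] result.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "mixture_fit"))
  jsonlite::write_json(
    list(weights = fit$weights, means = fit$means, sds = fit$sds,
         fluorescein_mean = fit$fluorescein_mean,
         normalized = fit$normalized, n_events = fit$n_events,
         loglik = fit$loglik, seed = fit$seed),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
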