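# Synthetic confocal-like droplet micrographs: fluorescent disks on a dark
# field, non-overlapping monolayer placement, per-droplet ground truth.

#' Droplet-image generator specification
#'
#' Emulates a sum-projected confocal frame of a droplet monolayer: droplets
#' appear as disks of near-uniform brightness `background_level` (the
#' fluorescein fill), occupied droplets additionally carry deposited
#' cellulose-dye intensity spread over the disk, and the whole frame has
#' additive Gaussian pixel noise. Droplet diameters are Gaussian with a small
#' coefficient of variation, reflecting the low polydispersity of step
#' emulsification.
#'
#' @param width,height image size in pixels.
#' @param pixel_size micrometres per pixel.
#' @param droplet_diameter_mean mean droplet diameter, um (default 49).
#' @param droplet_diameter_cv diameter coefficient of variation
#'   (default 0.02).
#' @param n_droplets droplets to place (> 0).
#' @param background_level in-droplet brightness, intensity units.
#' @param noise_sd additive Gaussian pixel noise SD, intensity units.
#' @param lam mean cells per droplet (Poisson occupancy).
#' @param intensity_per_rate total deposited intensity per occupant per unit
#'   production rate (integrated over the disk).
#' @param rate_per_cell production rate of each encapsulated cell, units/h
#'   (default 1, the native rate).
#' @param min_gap_px minimum gap between droplet rims, pixels.
#' @param max_place_tries rejection-sampling budget for non-overlapping
#'   placement before erroring.
#' @param seed integer seed or NULL.
#' @return an `image_spec` list.
#' @export
image_spec <- function(width = 600, height = 600,
                       pixel_size = 2,
                       droplet_diameter_mean = 49,
                       droplet_diameter_cv = 0.02,
                       n_droplets = 200,
                       background_level = 0.2,
                       noise_sd = 0.01,
                       lam = 0.1,
                       intensity_per_rate = 150,
                       rate_per_cell = 1,
                       min_gap_px = 2,
                       max_place_tries = 10000,
                       seed = NULL) {
  check_number(width, "width", lower = 8)
  check_number(height, "height", lower = 8)
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_number(droplet_diameter_mean, "droplet_diameter_mean", lower = 0,
               strict_lower = TRUE)
  check_number(droplet_diameter_cv, "droplet_diameter_cv", lower = 0)
  check_number(n_droplets, "n_droplets", lower = 1)
  check_number(background_level, "background_level", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(lam, "lam", lower = 0)
  check_number(intensity_per_rate, "intensity_per_rate", lower = 0)
  check_number(rate_per_cell, "rate_per_cell", lower = 0)
  structure(
    list(width = as.integer(width), height = as.integer(height),
         pixel_size = pixel_size,
         droplet_diameter_mean = droplet_diameter_mean,
         droplet_diameter_cv = droplet_diameter_cv,
         n_droplets = as.integer(n_droplets),
         background_level = background_level, noise_sd = noise_sd,
         lam = lam, intensity_per_rate = intensity_per_rate,
         rate_per_cell = rate_per_cell, min_gap_px = min_gap_px,
         max_place_tries = max_place_tries, seed = seed),
    class = "image_spec"
  )
}

# Disk membership: 0-based pixel centers within radius (inclusive).
disk_pixels <- function(cx, cy, r, width, height) {
  x0 <- max(0L, floor(cx - r)); x1 <- min(width - 1L, ceiling(cx + r))
  y0 <- max(0L, floor(cy - r)); y1 <- min(height - 1L, ceiling(cy + r))
  xs <- x0:x1; ys <- y0:y1
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  keep <- (gx - cx)^2 + (gy - cy)^2 <= r^2
  cbind(row = gy[keep] + 1L, col = gx[keep] + 1L)
}

#' Generate a synthetic droplet micrograph
#'
#' Places `n_droplets` non-overlapping disks in the field by rejection
#' sampling (droplets fully inside the frame), assigns each a Poisson
#' occupancy, and renders the frame per [image_spec()]'s model. Fails with a
#' placement error when the field cannot host the requested droplets within
#' the retry budget.
#'
#' @param spec an [image_spec()].
#' @return list of class `droplet_image` with elements `image` (height x
#'   width numeric matrix) and `ground_truth` (tibble: `droplet_id`,
#'   `center_x_px`, `center_y_px` (0-based), `radius_px`, `occupancy`,
#'   `intensity` — the total deposited dye intensity over the disk).
#' @export
generate_droplet_image <- function(spec) {
  stopifnot(inherits(spec, "image_spec"))
  local_seed_if(spec$seed)
  n <- spec$n_droplets

  r_mean <- spec$droplet_diameter_mean / 2 / spec$pixel_size
  r_sd <- r_mean * spec$droplet_diameter_cv
  radius <- pmax(1, stats::rnorm(n, r_mean, r_sd))

  cx <- numeric(n); cy <- numeric(n)
  tries <- 0L
  for (i in seq_len(n)) {
    repeat {
      tries <- tries + 1L
      if (tries > spec$max_place_tries) {
        stopf(paste0("could not place %d droplets of ~%.1f px radius in a ",
                     "%d x %d field within %d tries"),
              n, r_mean, spec$width, spec$height, spec$max_place_tries)
      }
      x <- stats::runif(1, radius[i], spec$width - 1 - radius[i])
      y <- stats::runif(1, radius[i], spec$height - 1 - radius[i])
      if (i == 1L) break
      j <- seq_len(i - 1L)
      if (all((cx[j] - x)^2 + (cy[j] - y)^2 >
              (radius[j] + radius[i] + spec$min_gap_px)^2)) break
    }
    cx[i] <- x; cy[i] <- y
  }

  occupancy <- stats::rpois(n, spec$lam)
  intensity <- occupancy * spec$rate_per_cell * spec$intensity_per_rate

  img <- matrix(0, nrow = spec$height, ncol = spec$width)
  for (i in seq_len(n)) {
    px <- disk_pixels(cx[i], cy[i], radius[i], spec$width, spec$height)
    img[px] <- img[px] + spec$background_level + intensity[i] / nrow(px)
  }
  if (spec$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
  }

  structure(
    list(
      image = img,
      ground_truth = tibble::tibble(
        droplet_id = seq_len(n),
        center_x_px = cx, center_y_px = cy,
        radius_px = radius,
        occupancy = occupancy,
        intensity = intensity
      ),
      spec = spec
    ),
    class = "droplet_image"
  )
}

#' Sum-project an image stack
#'
#' Collapses a confocal z-stack (height x width x slices array) into one 2D
#' frame by summing slices, the projection expected by [detect_droplets()]
#' and [measure_droplets()].
#'
#' @param stack 3D numeric array (or a matrix, returned unchanged).
#' @return height x width numeric matrix.
#' @export
sum_projection <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (length(dim(stack)) != 3) stopf("`stack` must be a matrix or 3D array")
  rowSums(stack, dims = 2)
}
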