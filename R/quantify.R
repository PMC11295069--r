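# Droplet micrograph quantification: circle detection, per-droplet intensity
# integration, edge exclusion, Day-0-maximum occupancy calling.

#' Detect droplets in a micrograph
#'
#' Two detectors over a single-channel frame, both returning circles with
#' radii inside `radius_range`:
#'
#' * `"threshold"` (default): global threshold (Otsu unless `threshold` is
#'   given) followed by connected-component labeling; each component yields a
#'   centroid and an equivalent-area radius. Exact on monolayer images where
#'   droplets do not touch.
#' * `"hough"`: gradient-based circular Hough voting — edge pixels vote along
#'   their gradient direction at every candidate radius, and vote peaks are
#'   kept by non-maximum suppression. Slower, but tolerant of touching or
#'   partially merged components.
#'
#' Detections whose disk, grown by `edge_margin` pixels, crosses the image
#' boundary are flagged `on_edge` (and excluded later by
#' [measure_droplets()]).
#'
#' @param image numeric matrix (rows = y, columns = x); use
#'   [sum_projection()] first for stacks.
#' @param radius_range length-2 numeric, min and max radius in pixels.
#' @param method `"threshold"` or `"hough"`.
#' @param edge_margin extra margin (px) for the edge flag (default 0: any
#'   boundary contact).
#' @param threshold optional absolute intensity threshold overriding Otsu.
#' @return tibble with columns `center_x`, `center_y` (0-based pixel
#'   coordinates), `radius`, `on_edge`.
#' @export
detect_droplets <- function(image, radius_range,
                            method = c("threshold", "hough"),
                            edge_margin = 0, threshold = NULL) {
  method <- match.arg(method)
  if (!is.matrix(image) || length(image) == 0) {
    stopf("`image` must be a non-empty numeric matrix")
  }
  if (length(radius_range) != 2 || radius_range[1] <= 0 ||
      radius_range[2] <= radius_range[1]) {
    stopf("`radius_range` must be (r_min, r_max) with 0 < r_min < r_max")
  }
  det <- switch(method,
    threshold = detect_threshold_cc(image, radius_range, threshold),
    hough = detect_hough(image, radius_range, threshold)
  )
  width <- ncol(image); height <- nrow(image)
  det$on_edge <- (det$center_x - det$radius - edge_margin < 0) |
    (det$center_x + det$radius + edge_margin > width - 1) |
    (det$center_y - det$radius - edge_margin < 0) |
    (det$center_y + det$radius + edge_margin > height - 1)
  det
}

detect_threshold_cc <- function(image, radius_range, threshold) {
  rng <- range(image)
  if (is.null(threshold)) {
    if (diff(rng) <= 0) { # flat image: nothing to segment
      return(tibble::tibble(center_x = numeric(0), center_y = numeric(0),
                            radius = numeric(0)))
    }
    norm <- (image - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(norm))
    mask <- norm > th
  } else {
    mask <- image > threshold
  }
  lab <- EBImage::bwlabel(mask)
  lab <- as.numeric(lab)
  idx <- which(lab > 0)
  if (length(idx) == 0) {
    return(tibble::tibble(center_x = numeric(0), center_y = numeric(0),
                          radius = numeric(0)))
  }
  l <- lab[idx]
  height <- nrow(image)
  row0 <- (idx - 1) %% height       # 0-based y
  col0 <- (idx - 1) %/% height      # 0-based x
  cx <- tapply(col0, l, mean)
  cy <- tapply(row0, l, mean)
  area <- tapply(l, l, length)
  r <- sqrt(area / pi)
  keep <- r >= radius_range[1] & r <= radius_range[2]
  tibble::tibble(
    center_x = unname(cx[keep]),
    center_y = unname(cy[keep]),
    radius = unname(r[keep])
  )
}

detect_hough <- function(image, radius_range, threshold) {
  height <- nrow(image); width <- ncol(image)
  # central-difference gradients (zero at the border)
  gx <- matrix(0, height, width); gy <- matrix(0, height, width)
  gx[, 2:(width - 1)] <- (image[, 3:width] - image[, 1:(width - 2)]) / 2
  gy[2:(height - 1), ] <- (image[3:height, ] - image[1:(height - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) <= 0) {
    return(tibble::tibble(center_x = numeric(0), center_y = numeric(0),
                          radius = numeric(0)))
  }
  edge_cut <- if (is.null(threshold)) {
    stats::quantile(mag[mag > 0], 0.9)
  } else {
    threshold
  }
  e <- which(mag >= edge_cut)
  ey <- (e - 1) %% height
  ex <- (e - 1) %/% height
  ux <- gx[e] / mag[e]; uy <- gy[e] / mag[e]

  radii <- seq(floor(radius_range[1]), ceiling(radius_range[2]), by = 1)
  best_votes <- matrix(0, height, width)
  best_r <- matrix(0, height, width)
  for (r in radii) {
    acc <- matrix(0L, height, width)
    # vote on both sides of each edge pixel along the gradient
    for (s in c(-1, 1)) {
      vx <- round(ex + s * r * ux); vy <- round(ey + s * r * uy)
      ok <- vx >= 0 & vx < width & vy >= 0 & vy < height
      vi <- vy[ok] + 1L + vx[ok] * height
      tab <- tabulate(vi, nbins = height * width)
      acc <- acc + matrix(tab, height, width)
    }
    # light 3x3 box smoothing to pool votes from rasterized circles
    accs <- box3(acc)
    upd <- accs > best_votes
    best_votes[upd] <- accs[upd]
    best_r[upd] <- r
  }

  # candidate peaks: enough votes to be a meaningful arc
  min_votes <- 0.25 * 2 * pi * radius_range[1]
  cand <- which(best_votes >= min_votes)
  if (length(cand) == 0) {
    return(tibble::tibble(center_x = numeric(0), center_y = numeric(0),
                          radius = numeric(0)))
  }
  cand <- cand[order(best_votes[cand], decreasing = TRUE)]
  cy <- (cand - 1) %% height
  cx <- (cand - 1) %/% height
  rr <- best_r[cand]
  keep_x <- numeric(0); keep_y <- numeric(0); keep_r <- numeric(0)
  for (i in seq_along(cand)) { # greedy NMS at min-radius separation
    if (length(keep_x) == 0 ||
        all((keep_x - cx[i])^2 + (keep_y - cy[i])^2 > radius_range[1]^2)) {
      keep_x <- c(keep_x, cx[i])
      keep_y <- c(keep_y, cy[i])
      keep_r <- c(keep_r, rr[i])
    }
  }
  tibble::tibble(center_x = keep_x, center_y = keep_y, radius = keep_r)
}

box3 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  out <- m
  out[2:(n - 1), ] <- m[1:(n - 2), ] + m[2:(n - 1), ] + m[3:n, ]
  out2 <- out
  out2[, 2:(p - 1)] <- out[, 1:(p - 2)] + out[, 2:(p - 1)] + out[, 3:p]
  out2
}

#' Integrate per-droplet fluorescence
#'
#' Drops edge-flagged detections, then sums pixel intensities inside each
#' remaining disk (pixel centers within the radius, inclusive).
#'
#' @param image numeric matrix.
#' @param detections tibble from [detect_droplets()].
#' @return tibble with the detection columns plus `area_px`,
#'   `total_intensity`, `mean_intensity`, and `occupied` (NA until
#'   [call_occupied()] runs).
#' @export
measure_droplets <- function(image, detections) {
  stopifnot(is.matrix(image))
  need <- c("center_x", "center_y", "radius")
  if (!all(need %in% names(detections))) {
    stopf("`detections` must have columns center_x, center_y, radius")
  }
  if ("on_edge" %in% names(detections)) {
    detections <- detections[!detections$on_edge, , drop = FALSE]
  }
  n <- nrow(detections)
  total <- numeric(n); area <- numeric(n)
  for (i in seq_len(n)) {
    px <- disk_pixels(detections$center_x[i], detections$center_y[i],
                      detections$radius[i], ncol(image), nrow(image))
    area[i] <- nrow(px)
    total[i] <- sum(image[px])
  }
  out <- tibble::tibble(
    center_x = detections$center_x,
    center_y = detections$center_y,
    radius = detections$radius,
    area_px = area,
    total_intensity = total,
    mean_intensity = ifelse(area > 0, total / area, NA_real_),
    occupied = NA
  )
  out$occupied <- as.logical(out$occupied)
  out
}

#' Call droplet occupancy against the Day-0 maximum
#'
#' A droplet is called occupied when its measured cellulose fluorescence
#' strictly exceeds the maximum fluorescence observed across droplets on
#' Day 0 (before any cellulose could be produced). The comparison statistic
#' defaults to the per-droplet total; `"mean"` uses the area-normalized mean
#' instead, which is insensitive to droplet-size variation.
#'
#' @param measurements tibble from [measure_droplets()].
#' @param day0_max Day-0 maximum of the same statistic (>= 0).
#' @param statistic `"total"` or `"mean"`.
#' @return `measurements` with the `occupied` column set.
#' @export
call_occupied <- function(measurements, day0_max,
                          statistic = c("total", "mean")) {
  statistic <- match.arg(statistic)
  check_number(day0_max, "day0_max", lower = 0)
  v <- switch(statistic,
    total = measurements$total_intensity,
    mean = measurements$mean_intensity
  )
  measurements$occupied <- v > day0_max
  measurements
}

#' Per-droplet fluorescence histogram
#'
#' Equal-width histogram of a droplet fluorescence statistic; counts sum to
#' the number of (non-edge) measurements.
#'
#' @param measurements tibble from [measure_droplets()], or a numeric vector.
#' @param bins number of equal-width bins (> 0).
#' @param statistic which measurement column to bin (ignored for vectors).
#' @return tibble with columns `bin_left`, `bin_right`, `count`.
#' @export
fluorescence_histogram <- function(measurements, bins = 30,
                                   statistic = c("total", "mean")) {
  statistic <- match.arg(statistic)
  v <- if (is.numeric(measurements)) {
    measurements
  } else {
    switch(statistic,
      total = measurements$total_intensity,
      mean = measurements$mean_intensity
    )
  }
  if (length(v) == 0) stopf("no measurements to histogram")
  check_number(bins, "bins", lower = 1)
  bins <- as.integer(bins)
  rng <- range(v)
  if (diff(rng) <= 0) rng <- rng + c(-0.5, 0.5) # single value: unit-wide bin
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  h <- graphics::hist(v, breaks = breaks, include.lowest = TRUE,
                      right = TRUE, plot = FALSE)
  tibble::tibble(
    bin_left = h$breaks[-length(h$breaks)],
    bin_right = h$breaks[-1],
    count = h$counts
  )
}
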