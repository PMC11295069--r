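# Shared fixture builders for the dropevo test suite.

# A disk painted directly into a matrix (bypasses the generator, so tests can
# construct edge cases the generator forbids, e.g. corner-clipped droplets).
paint_disk <- function(img, cx, cy, r, value) {
  height <- nrow(img); width <- ncol(img)
  for (row in seq_len(height)) {
    for (col in seq_len(width)) {
      if ((col - 1 - cx)^2 + (row - 1 - cy)^2 <= r^2) {
        img[row, col] <- img[row, col] + value
      }
    }
  }
  img
}

# Match detections to ground truth by nearest center within `tol` px;
# returns the number of ground-truth droplets recovered.
match_detections <- function(detections, ground_truth, tol = 2) {
  hits <- 0L
  for (i in seq_len(nrow(ground_truth))) {
    d2 <- (detections$center_x - ground_truth$center_x_px[i])^2 +
      (detections$center_y - ground_truth$center_y_px[i])^2
    if (length(d2) > 0 && min(d2) <= tol^2) hits <- hits + 1L
  }
  hits
}

# Small calibrated clonal-strain stream for mixture tests.
strain_stream <- function(rate, n = 15000, seed = 1) {
  lib <- clonal_library(500, production_rate = rate)
  generate_event_stream(lib, stream_config(n, lam = 0.1, seed = seed))
}
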