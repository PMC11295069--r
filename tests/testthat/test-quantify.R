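# Droplet detection, intensity measurement, occupancy calling.

test_that("threshold detection recovers synthetic disks to sub-2-px accuracy", {
  spec <- image_spec(width = 200, height = 200, pixel_size = 1,
                     droplet_diameter_mean = 49, droplet_diameter_cv = 0,
                     n_droplets = 3, lam = 0, noise_sd = 0.002,
                     background_level = 0.2, seed = 21)
  di <- generate_droplet_image(spec)
  det <- detect_droplets(di$image, c(20, 30))
  expect_equal(nrow(det), 3)
  expect_equal(match_detections(det, di$ground_truth, tol = 2), 3)
  expect_true(all(abs(det$radius - 24.5) < 2))
  expect_false(any(det$on_edge))
})

test_that("blank images yield no detections", {
  expect_equal(nrow(detect_droplets(matrix(0, 50, 50), c(5, 10))), 0)
  expect_equal(nrow(detect_droplets(matrix(0.3, 50, 50), c(5, 10))), 0)
})

test_that("corner-clipped disks are flagged on_edge", {
  img <- paint_disk(matrix(0, 80, 80), cx = 0, cy = 0, r = 10, value = 1)
  img <- paint_disk(img, cx = 40, cy = 40, r = 10, value = 1)
  det <- detect_droplets(img, c(4, 12))
  expect_equal(nrow(det), 2)
  corner <- which.min(det$center_x + det$center_y)
  expect_true(det$on_edge[corner])
  expect_false(det$on_edge[-corner])
  # a margin can flag interior droplets near the border too
  det_m <- detect_droplets(img, c(4, 12), edge_margin = 40)
  expect_true(all(det_m$on_edge))
})

test_that("hough detection finds circles from gradient votes", {
  spec <- image_spec(width = 150, height = 150, pixel_size = 2,
                     droplet_diameter_mean = 49, droplet_diameter_cv = 0,
                     n_droplets = 3, lam = 0, noise_sd = 0.002,
                     background_level = 0.3, seed = 22)
  di <- generate_droplet_image(spec)
  det <- detect_droplets(di$image, c(8, 16), method = "hough")
  expect_equal(match_detections(det, di$ground_truth, tol = 2), 3)
})

test_that("measurement integrates disk intensity and drops edge droplets", {
  img <- matrix(0.4, 100, 100)
  det <- tibble::tibble(center_x = 50, center_y = 50, radius = 20,
                        on_edge = FALSE)
  m <- measure_droplets(img, det)
  expect_equal(m$total_intensity, 0.4 * pi * 20^2, tolerance = 0.02)
  expect_equal(m$total_intensity, 0.4 * m$area_px, tolerance = 1e-12)
  expect_equal(m$mean_intensity, 0.4, tolerance = 1e-12)
  expect_true(is.na(m$occupied))

  det$on_edge <- TRUE
  expect_equal(nrow(measure_droplets(img, det)), 0)
})

test_that("measured totals match ground truth deposit plus background", {
  spec <- image_spec(width = 300, height = 300, n_droplets = 30, lam = 0.5,
                     noise_sd = 0.002, seed = 23)
  di <- generate_droplet_image(spec)
  det <- detect_droplets(di$image, c(8, 18))
  m <- measure_droplets(di$image, det)
  gt <- di$ground_truth
  for (i in seq_len(nrow(m))) {
    j <- which.min((gt$center_x_px - m$center_x[i])^2 +
                     (gt$center_y_px - m$center_y[i])^2)
    expected <- gt$intensity[j] + spec$background_level * m$area_px[i]
    expect_equal(m$total_intensity[i], expected,
                 tolerance = 0.05 * max(expected, 1))
  }
})

test_that("occupancy calls use strict exceedance of the Day-0 maximum", {
  m <- tibble::tibble(center_x = 1:3, center_y = 1:3, radius = 1,
                      area_px = 1, total_intensity = c(5, 12, 10),
                      mean_intensity = c(5, 12, 10), occupied = NA)
  expect_equal(call_occupied(m, 10)$occupied, c(FALSE, TRUE, FALSE))
  expect_true(all(call_occupied(m, 0)$occupied))
  expect_error(call_occupied(m, -1), "day0_max")
  # monotone: raising the threshold never flips FALSE -> TRUE
  for (cut in c(0, 4, 5, 9, 11, 13)) {
    lo <- call_occupied(m, cut)$occupied
    hi <- call_occupied(m, cut + 2)$occupied
    expect_true(all(hi <= lo))
  }
  # mean statistic switch
  m$mean_intensity <- c(1, 3, 2)
  expect_equal(call_occupied(m, 2, statistic = "mean")$occupied,
               c(FALSE, TRUE, FALSE))
})

test_that("measurements are invariant to off-edge translation", {
  spec <- image_spec(width = 160, height = 160, n_droplets = 4, lam = 1,
                     noise_sd = 0, seed = 24)
  di <- generate_droplet_image(spec)
  gt <- di$ground_truth
  big <- matrix(0, 200, 200)
  big[21:180, 21:180] <- di$image
  det0 <- tibble::tibble(center_x = gt$center_x_px, center_y = gt$center_y_px,
                         radius = gt$radius_px)
  det1 <- tibble::tibble(center_x = gt$center_x_px + 20,
                         center_y = gt$center_y_px + 20,
                         radius = gt$radius_px)
  expect_equal(measure_droplets(di$image, det0)$total_intensity,
               measure_droplets(big, det1)$total_intensity, tolerance = 1e-12)
})

test_that("fluorescence histograms conserve counts", {
  v <- c(stats::rnorm(800, 10, 1), stats::rnorm(400, 30, 1))
  h <- fluorescence_histogram(v, bins = 40)
  expect_equal(sum(h$count), 1200)
  expect_equal(nrow(h), 40)
  # bimodal input: both modes present, separated by an empty gap
  occupied_mode <- h$count[h$bin_left > 20]
  empty_mode <- h$count[h$bin_right < 20]
  expect_gt(max(occupied_mode), 0)
  expect_gt(max(empty_mode), 0)
  expect_true(any(h$count[h$bin_left > 15 & h$bin_right < 25] == 0))

  h1 <- fluorescence_histogram(rep(3.3, 7), bins = 5)
  expect_equal(sum(h1$count), 7)
  expect_equal(sum(h1$count > 0), 1)
  expect_error(fluorescence_histogram(numeric(0)), "no measurements")
  expect_error(fluorescence_histogram(v, bins = 0), "bins")
})
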