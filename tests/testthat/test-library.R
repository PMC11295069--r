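# Mutant-library generation, genotype edit arithmetic, dilution counts.

test_that("viable fraction tracks the survival curve within binomial error", {
  cfg <- library_config(n_variants = 10000, dose = 10,
                        survival_curve = c(`10` = 0.17), seed = 41)
  lib <- generate_library(cfg)
  p <- 0.17
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(mean(lib$viable) - p), 3 * se)
  expect_true(all(lib$production_rate[!lib$viable] == 0))
})

test_that("a dose-0 control library is fully viable with noise-only rates", {
  cfg <- library_config(n_variants = 2000, dose = 0, beneficial_fraction = 0,
                        neutral_sd = 0.1, seed = 42)
  lib <- generate_library(cfg)
  expect_true(all(lib$viable))
  expect_false(any(lib$beneficial))
  expect_true(all(lengths(lib$genotype) == 0))
  # lognormal spread around the native rate, mean preserved
  expect_equal(mean(lib$production_rate), 1,
               tolerance = 3 * 0.1 / sqrt(2000))
})

test_that("beneficial variants carry the configured multiplicative effect", {
  cfg <- library_config(n_variants = 10000, dose = 10,
                        survival_curve = c(`10` = 1),
                        beneficial_fraction = 0.2, beneficial_effect = 1.6,
                        seed = 43)
  lib <- generate_library(cfg)
  ratio <- mean(lib$production_rate[lib$beneficial]) /
    mean(lib$production_rate[!lib$beneficial])
  expect_equal(ratio, 1.6, tolerance = 0.05 * 1.6)
})

test_that("library generation is reproducible and dose-checked", {
  cfg <- library_config(n_variants = 500, seed = 7)
  expect_identical(generate_library(cfg), generate_library(cfg))
  expect_error(
    generate_library(library_config(10, dose = 500)),
    "outside the tabulated"
  )
})

test_that("survival curve interpolates between tabulated doses", {
  curve <- default_survival_curve()
  expect_equal(survival_at_dose(curve, 10), 0.17)
  expect_equal(survival_at_dose(curve, 0), 1)
  # log-linear between 0.5 and 10
  s5 <- survival_at_dose(curve, 5)
  expect_true(s5 < 0.98 && s5 > 0.17)
  w <- (5 - 0.5) / (10 - 0.5)
  expect_equal(s5, exp((1 - w) * log(0.98) + w * log(0.17)), tolerance = 1e-12)
  # linear into the zero-survival endpoint
  expect_equal(survival_at_dose(curve, 55), 0.17 * (1 - 45 / 90),
               tolerance = 1e-12)
  expect_error(survival_at_dose(curve, 200), "outside")
})

test_that("in-frame deletion arithmetic removes whole codons", {
  expect_equal(apply_inframe_deletion(edit_descriptor("deletion", 100, 12)),
               list(frameshift = FALSE, aa_removed = 4L))
  expect_equal(apply_inframe_deletion(edit_descriptor("deletion", 0, 3)),
               list(frameshift = FALSE, aa_removed = 1L))
  res11 <- apply_inframe_deletion(edit_descriptor("deletion", 5, 11))
  expect_true(res11$frameshift)
  expect_true(is.na(res11$aa_removed))
  expect_error(
    apply_inframe_deletion(edit_descriptor("substitution", 5, 1)),
    "deletion"
  )
  expect_false(edit_descriptor("deletion", 0, 11)$in_frame)
  expect_true(edit_descriptor("deletion", 0, 12)$in_frame)
})

test_that("library genotypes reflect variant class", {
  cfg <- library_config(n_variants = 4000, dose = 10,
                        survival_curve = c(`10` = 0.5),
                        beneficial_fraction = 0.1, seed = 13)
  lib <- generate_library(cfg)
  kinds <- vapply(lib$genotype, function(g) g[[1]]$kind, character(1))
  lens <- vapply(lib$genotype, function(g) g[[1]]$length, integer(1))
  expect_true(all(kinds[!lib$viable] == "deletion" & lens[!lib$viable] %% 3 != 0))
  expect_true(all(kinds[lib$beneficial] == "deletion" &
                    lens[lib$beneficial] == 12))
  neutral <- lib$viable & !lib$beneficial
  expect_true(all(kinds[neutral] == "substitution"))
})

test_that("dilution counts are Poisson around conc x dilution x volume", {
  # expected count 1e7 * 1e-4 * 0.005 = 5
  tab <- generate_dilution_counts(1e7, 1e-4, n_replicates = 2000, seed = 3)
  expect_equal(mean(tab$count), 5, tolerance = 3 * sqrt(5 / 2000) / 5)
  expect_true(all(generate_dilution_counts(0, c(1e-2, 1e-3), seed = 1)$count == 0))
  # expected count 2.4e6 * 1e-3 * 0.005 = 12
  tab2 <- generate_dilution_counts(2.4e6, 1e-3, n_replicates = 3000, seed = 4)
  expect_equal(mean(tab2$count), 12, tolerance = 3 * sqrt(12 / 3000) / 12)
  expect_identical(generate_dilution_counts(1e6, 1e-3, seed = 9),
                   generate_dilution_counts(1e6, 1e-3, seed = 9))
  expect_error(generate_dilution_counts(-1, 1e-3), "true_conc")
  expect_error(generate_dilution_counts(1e6, 2), "dilutions")
})
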