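# End-to-end in-silico directed-evolution rounds.

make_campaign <- function(n_rounds = 1, n_events = 40000, threshold = 0.55,
                          beneficial_fraction = 0.01, seed = 90, ...) {
  campaign_config(
    n_rounds = n_rounds,
    library = library_config(n_variants = 5000, dose = 10,
                             survival_curve = c(`10` = 0.17),
                             beneficial_fraction = beneficial_fraction,
                             beneficial_effect = 1.6, ...),
    stream = stream_config(n_events, lam = 0.1),
    gates = gate_config(threshold, baseline_target = 0.05),
    seed = seed
  )
}

test_that("a screening-scale round yields ~40,900 occupied droplets", {
  cfg <- make_campaign(n_events = 430000)
  lib <- generate_library(local({ l <- cfg$library; l$seed <- 91; l }))
  rr <- run_round(lib, cfg, seed = 92)
  p <- 1 - exp(-0.1)
  n_occ <- rr$occupancy[["single"]] + rr$occupancy[["multi"]]
  expect_lt(abs(n_occ - 430000 * p), 3 * sqrt(430000 * p * (1 - p)))
  expect_equal(rr$n_droplets_screened, 430000)
  expect_equal(sum(rr$occupancy), 430000)
})

test_that("a gate below all signals applies no selection pressure", {
  cfg <- make_campaign(n_events = 50000, threshold = 0.051)
  cfg$n_colonies_picked <- 200L
  lib <- generate_library(local({ l <- cfg$library; l$seed <- 93; l }))
  rr <- run_round(lib, cfg, seed = 94)
  # everything occupied is sorted, so selection cannot shift the mean
  expect_equal(rr$summary$n_sorted, rr$n_droplets_screened)
  se <- rr$phenotype_before[["sd"]] / sqrt(nrow(rr$picked))
  expect_lt(abs(mean(rr$picked$production_rate) -
                  rr$phenotype_before[["mean"]]), 3 * se)
  expect_equal(rr$enrichment, 1, tolerance = 1e-6)
})

test_that("a stringent gate enriches the beneficial class among picks", {
  # screen scaled so the sorted pool is large enough (~250 occupants) that
  # the beneficial share is measured well above its sampling noise
  cfg <- make_campaign(n_events = 100000, beneficial_fraction = 0.01,
                       seed = 95)
  cfg$n_colonies_picked <- 10000L # pick every colony the sorted pool grows
  lib <- generate_library(local({ l <- cfg$library; l$seed <- 96; l }))
  ev_probe <- generate_event_stream(
    lib, local({ s <- cfg$stream; s$seed <- 97; s })
  )
  thr <- threshold_for_top_fraction(ev_probe, 1.25)
  cfg$gates[[1]] <- gate_config(thr, baseline_target = 0.05)
  rr <- run_round(lib, cfg, seed = 98)
  expect_gt(mean(rr$picked$beneficial), 0.01)
  expect_gt(rr$enrichment, 1)
  expect_gte(rr$phenotype_after[["mean"]], rr$phenotype_before[["mean"]])
})

test_that("campaigns chain rounds and are bit-reproducible", {
  cfg <- make_campaign(n_rounds = 2, n_events = 30000, threshold = 0.55,
                       seed = 99)
  cfg$gates <- list(gate_config(0.55, 0.05), gate_config(0.60, 0.05))
  res1 <- run_campaign(cfg)
  res2 <- run_campaign(cfg)
  expect_length(res1, 2)
  expect_equal(res1[[1]]$round_index, 1)
  expect_equal(res1[[2]]$round_index, 2)
  expect_identical(
    lapply(res1, function(r) r[setdiff(names(r), "picked")]),
    lapply(res2, function(r) r[setdiff(names(r), "picked")])
  )
  expect_identical(as.data.frame(res1[[1]]$picked[, 1:5]),
                   as.data.frame(res2[[1]]$picked[, 1:5]))
  # round 2 screens only variants picked in round 1
  occ2 <- attr(res1[[2]]$sorted, "occupants")
  expect_true(all(res1[[2]]$picked$id %in% res1[[1]]$picked$id))
})

test_that("selection saturates once the pool is a single effect class", {
  # round-1 picks are clones of one strain, so a second identical round
  # cannot shift the mean phenotype beyond sampling error
  clone <- clonal_library(50, production_rate = 1.6)
  cfg <- make_campaign(n_rounds = 1, n_events = 30000, threshold = 0.55)
  rr1 <- run_round(clone, cfg, seed = 100)
  rr2 <- run_round(clone, cfg, seed = 101)
  expect_equal(rr1$phenotype_after[["mean"]], 1.6, tolerance = 1e-9)
  expect_equal(rr2$phenotype_after[["mean"]], rr1$phenotype_after[["mean"]],
               tolerance = 1e-9)
})

test_that("identical phenotypes gate at the noise-tail probability", {
  clone <- clonal_library(20, production_rate = 1)
  cfg <- campaign_config(
    n_rounds = 1, library = library_config(10),
    stream = stream_config(200000, lam = 0.1, signal_sd = 0.05),
    gates = gate_config(0.388 + 2 * 0.05, baseline_target = 0.05),
    seed = 102
  )
  rr <- run_round(clone, cfg, seed = 103)
  # single-occupancy signals are N(0.388, 0.05); the gate sits at +2 sd.
  # multi-occupancy droplets all exceed it, so compare on singles only.
  sorted_single <- sum(rr$sorted$true_occupancy == 1)
  n_single <- rr$occupancy[["single"]]
  p_tail <- stats::pnorm(2, lower.tail = FALSE)
  expect_lt(abs(sorted_single - n_single * p_tail),
            3 * sqrt(n_single * p_tail * (1 - p_tail)))
})

test_that("empty selections and exhausted libraries fail loudly", {
  clone <- clonal_library(10)
  cfg <- make_campaign(n_events = 1000, threshold = 3)
  expect_error(run_round(clone, cfg, seed = 104), "zero droplets")
  dead <- clone
  dead$viable <- FALSE
  expect_error(run_round(dead, cfg, seed = 105), "no viable")
  expect_error(run_round(clone, cfg, round_index = 5), "no configured gate")
})
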