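# End-to-end in-silico directed-evolution rounds: recovery growth,
# encapsulation, incubation signal, gating, colony picking, chaining.

#' Campaign configuration
#'
#' @param n_rounds number of directed-evolution rounds (>= 1).
#' @param library a [library_config()] for the round-1 mutant library.
#' @param stream a [stream_config()] describing each round's encapsulation
#'   and detector run.
#' @param gates a single [gate_config()] (recycled) or a list with one gate
#'   per round.
#' @param recovery_hours post-mutagenesis recovery growth time, hours
#'   (default 50: long recovery enriches fast growers before encapsulation).
#' @param n_colonies_picked colonies picked from the sorted pool per round
#'   (default 5).
#' @param seed master seed; per-round seeds are derived from it.
#' @return a `campaign_config` list.
#' @export
campaign_config <- function(n_rounds, library, stream, gates,
                            recovery_hours = 50, n_colonies_picked = 5,
                            seed = 1) {
  check_number(n_rounds, "n_rounds", lower = 1)
  stopifnot(inherits(library, "library_config"),
            inherits(stream, "stream_config"))
  if (inherits(gates, "gate_config")) {
    gates <- rep(list(gates), n_rounds)
  }
  if (length(gates) != n_rounds ||
      !all(vapply(gates, inherits, logical(1), "gate_config"))) {
    stopf("`gates` must supply one gate_config per round")
  }
  check_number(recovery_hours, "recovery_hours", lower = 0)
  check_number(n_colonies_picked, "n_colonies_picked", lower = 1)
  structure(
    list(n_rounds = as.integer(n_rounds), library = library, stream = stream,
         gates = gates, recovery_hours = recovery_hours,
         n_colonies_picked = as.integer(n_colonies_picked),
         seed = as.integer(seed)),
    class = "campaign_config"
  )
}

#' Run one directed-evolution round
#'
#' One full wet-lab cycle in silico: deterministic exponential recovery
#' growth weights each viable variant by `2^(growth_rate * recovery_hours)`;
#' cells are Poisson-encapsulated and incubated (signal model of
#' [stream_config()]); the gate sorts the stream; colonies are picked
#' uniformly without replacement from the sorted droplets' occupants (every
#' occupant of a sorted multi-occupancy droplet enters the pool — clonality
#' is restored at picking).
#'
#' @param variants library tibble (viable rows are used).
#' @param config a [campaign_config()].
#' @param round_index which round's gate to apply.
#' @param seed round seed (NULL uses the current RNG stream).
#' @return a `round_result`: `round_index`, `n_droplets_screened`,
#'   `occupancy` (empirical empty/single/multi counts), `summary`
#'   (sort summary), `phenotype_before` / `phenotype_after` (mean and SD of
#'   occupant production rates over occupied vs sorted droplets),
#'   `enrichment` (after/before mean ratio), `picked` (tibble of picked
#'   variants), and the gated `sorted` stream.
#' @export
run_round <- function(variants, config, round_index = 1, seed = NULL) {
  stopifnot(inherits(config, "campaign_config"))
  if (round_index < 1 || round_index > length(config$gates)) {
    stopf("`round_index` %d has no configured gate", round_index)
  }
  viable <- variants[variants$viable, , drop = FALSE]
  if (nrow(viable) == 0) stopf("round %d: no viable variants", round_index)
  local_seed_if(seed) # one seed covers the stream and the colony picks

  # recovery growth: relative abundance after t hours of exponential growth,
  # rescaled by the fastest grower to stay finite at long recovery times
  g <- variants$growth_rate * config$recovery_hours
  w <- ifelse(variants$viable, 2^(g - max(g[variants$viable])), 0)

  stream_cfg <- config$stream
  stream_cfg$seed <- NULL # draw from the round-seeded RNG stream
  events <- generate_event_stream(variants, stream_cfg, weights = w)
  occupants <- attr(events, "occupants")

  gate <- config$gates[[round_index]]
  res <- gate_events(events, gate)
  if (res$summary$n_sorted == 0) {
    stopf("round %d: gate at %.2f V sorted zero droplets (empty selection)",
          round_index, gate$threshold)
  }

  sorted_ids <- res$sorted$droplet_id
  pool <- occupants[occupants$droplet_id %in% sorted_ids, , drop = FALSE]
  n_pick <- min(config$n_colonies_picked, nrow(pool))
  pick_rows <- sample.int(nrow(pool), n_pick)
  picked_ids <- pool$variant_id[pick_rows]
  picked <- variants[match(picked_ids, variants$id), , drop = FALSE]

  occ <- events$true_occupancy
  structure(
    list(
      round_index = round_index,
      n_droplets_screened = nrow(events),
      occupancy = c(empty = sum(occ == 0), single = sum(occ == 1),
                    multi = sum(occ > 1)),
      summary = res$summary,
      phenotype_before = c(mean = mean(occupants$production_rate),
                           sd = stats::sd(occupants$production_rate)),
      phenotype_after = c(mean = mean(pool$production_rate),
                          sd = stats::sd(pool$production_rate)),
      enrichment = enrichment_factor(mean(occupants$production_rate),
                                     mean(pool$production_rate)),
      picked = picked,
      sorted = res$sorted,
      seed = seed
    ),
    class = "round_result"
  )
}

#' @export
print.round_result <- function(x, ...) {
  cat(sprintf("Round %d: %d droplets (%d empty / %d single / %d multi)\n",
              x$round_index, x$n_droplets_screened,
              x$occupancy[["empty"]], x$occupancy[["single"]],
              x$occupancy[["multi"]]))
  print(x$summary)
  cat(sprintf("  phenotype mean %.3f -> %.3f (enrichment %.2fx); %d picked\n",
              x$phenotype_before[["mean"]], x$phenotype_after[["mean"]],
              x$enrichment, nrow(x$picked)))
  invisible(x)
}

#' Run a multi-round directed-evolution campaign
#'
#' Generates the round-1 library from the campaign's [library_config()], then
#' chains rounds: the variants picked in each round (clonally expanded, i.e.
#' reused as the strain pool) seed the next round's encapsulation. Per-round
#' seeds are drawn from the master seed, making the whole campaign
#' reproducible bit-for-bit.
#'
#' @param config a [campaign_config()].
#' @return list of `round_result` objects (class `campaign_result`).
#' @export
run_campaign <- function(config) {
  stopifnot(inherits(config, "campaign_config"))
  local_seed_if(config$seed)
  round_seeds <- sample.int(.Machine$integer.max - 1, config$n_rounds)

  lib_cfg <- config$library
  if (is.null(lib_cfg$seed)) {
    lib_cfg$seed <- sample.int(.Machine$integer.max - 1, 1)
  }
  variants <- generate_library(lib_cfg)

  results <- vector("list", config$n_rounds)
  for (r in seq_len(config$n_rounds)) {
    results[[r]] <- tryCatch(
      run_round(variants, config, round_index = r, seed = round_seeds[r]),
      error = function(e) {
        stopf("campaign failed in round %d: %s", r, conditionMessage(e))
      }
    )
    variants <- results[[r]]$picked
  }
  structure(results, class = "campaign_result")
}

#' @export
print.campaign_result <- function(x, ...) {
  cat(sprintf("Directed-evolution campaign: %d round(s)\n", length(x)))
  for (r in x) print(r)
  invisible(x)
}
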