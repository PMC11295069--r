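# Mutant-library generation: UV dose -> viability, plus lethal / neutral /
# rare beneficial production-rate phenotypes.

GENOME_LENGTH_BP <- 2.95e6 # single circular genome, ~2.95 Mbp

#' Default UV-C dose-survival curve
#'
#' Survival fractions (relative to an unexposed control) at the UV-C doses
#' with quantified survival: 98% at 0.5 mJ/cm2 falling to 17% at 10 mJ/cm2,
#' and complete death at 100 mJ/cm2. Intermediate doses are interpolated by
#' [survival_at_dose()].
#'
#' @return named numeric vector mapping dose (mJ/cm2, as names) to survival
#'   fraction in \[0, 1\].
#' @export
default_survival_curve <- function() {
  c(`0` = 1, `0.5` = 0.98, `10` = 0.17, `100` = 0)
}

#' Survival fraction at a UV dose
#'
#' Looks the dose up in a dose-survival mapping; doses between tabulated
#' points are log-linearly interpolated on survival (linearly when a bracketing
#' survival is 0, where the log is undefined). Doses outside the tabulated
#' range are an error: extrapolating a kill curve is not meaningful.
#'
#' @param curve named numeric vector, names = doses in mJ/cm2, values =
#'   survival fractions in \[0, 1\].
#' @param dose dose in mJ/cm2.
#' @return survival fraction in \[0, 1\].
#' @export
#' @examples
#' survival_at_dose(default_survival_curve(), 10) # 0.17
survival_at_dose <- function(curve, dose) {
  if (is.null(names(curve)) || anyNA(suppressWarnings(as.numeric(names(curve))))) {
    stopf("`curve` must be a named vector with numeric dose names")
  }
  if (any(curve < 0 | curve > 1)) stopf("survival fractions must lie in [0, 1]")
  check_number(dose, "dose", lower = 0)
  doses <- as.numeric(names(curve))
  ord <- order(doses)
  doses <- doses[ord]
  surv <- unname(curve[ord])
  hit <- which(abs(doses - dose) < 1e-12)
  if (length(hit) > 0) return(surv[hit[1]])
  if (dose < min(doses) || dose > max(doses)) {
    stopf("dose %g mJ/cm2 is outside the tabulated survival curve [%g, %g]",
          dose, min(doses), max(doses))
  }
  i <- max(which(doses < dose))
  d0 <- doses[i]; d1 <- doses[i + 1]
  s0 <- surv[i]; s1 <- surv[i + 1]
  w <- (dose - d0) / (d1 - d0)
  if (s0 <= 0 || s1 <= 0) {
    (1 - w) * s0 + w * s1
  } else {
    exp((1 - w) * log(s0) + w * log(s1))
  }
}

#' Mutant-library generator configuration
#'
#' @param n_variants number of mutagenized cells in the library.
#' @param dose UV-C dose in mJ/cm2 applied to the library.
#' @param survival_curve dose -> survival mapping (see
#'   [default_survival_curve()]).
#' @param beneficial_fraction probability that a viable mutant carries a
#'   production-enhancing mutation.
#' @param beneficial_effect multiplicative effect (> 1) of a beneficial
#'   mutation on the production rate.
#' @param neutral_sd relative standard deviation of the production rate among
#'   neutral viable mutants (log-normal spread around the native rate).
#' @param native_rate native-strain cellulose production rate, in
#'   fluorescence-units per hour. The default of 1 is the unit in which all
#'   phenotypes are expressed.
#' @param native_growth_rate native growth rate in divisions per hour.
#' @param growth_sd relative SD of the growth rate among viable mutants.
#' @param seed integer seed for reproducible generation, or NULL.
#' @return a `library_config` list.
#' @export
library_config <- function(n_variants,
                           dose = 10,
                           survival_curve = default_survival_curve(),
                           beneficial_fraction = 0.01,
                           beneficial_effect = 1.6,
                           neutral_sd = 0.1,
                           native_rate = 1,
                           native_growth_rate = 0.25,
                           growth_sd = 0.05,
                           seed = NULL) {
  check_number(n_variants, "n_variants", lower = 1)
  check_number(dose, "dose", lower = 0)
  check_number(beneficial_fraction, "beneficial_fraction", lower = 0, upper = 1)
  check_number(beneficial_effect, "beneficial_effect", lower = 0, strict_lower = TRUE)
  check_number(neutral_sd, "neutral_sd", lower = 0)
  check_number(native_rate, "native_rate", lower = 0)
  check_number(native_growth_rate, "native_growth_rate", lower = 0)
  structure(
    list(n_variants = as.integer(n_variants), dose = dose,
         survival_curve = survival_curve,
         beneficial_fraction = beneficial_fraction,
         beneficial_effect = beneficial_effect,
         neutral_sd = neutral_sd, native_rate = native_rate,
         native_growth_rate = native_growth_rate, growth_sd = growth_sd,
         seed = seed),
    class = "library_config"
  )
}

#' Genome-edit descriptor
#'
#' @param kind one of `"substitution"`, `"deletion"`, `"insertion"`.
#' @param position 0-based genome coordinate of the edit.
#' @param length length of the edit in base pairs (> 0).
#' @return an `edit_descriptor` list with an `in_frame` flag for deletions
#'   (TRUE iff `length %% 3 == 0`).
#' @export
edit_descriptor <- function(kind, position, length) {
  kind <- match.arg(kind, c("substitution", "deletion", "insertion"))
  check_number(position, "position", lower = 0)
  check_number(length, "length", lower = 0, strict_lower = TRUE)
  if (length != floor(length)) stopf("`length` must be an integer bp count")
  out <- list(kind = kind, position = position, length = as.integer(length))
  if (kind == "deletion") out$in_frame <- (length %% 3 == 0)
  structure(out, class = "edit_descriptor")
}

#' Protein-level consequence of a deletion
#'
#' Translates a genomic deletion inside a reading frame into its amino-acid
#' consequence: a deletion whose length is a multiple of 3 removes
#' `length / 3` whole codons (e.g. a 12-bp in-frame deletion removes 4
#' adjacent amino acids); any other length shifts the reading frame.
#'
#' @param edit an [edit_descriptor()] with `kind = "deletion"`.
#' @return list with `frameshift` (logical) and `aa_removed` (integer codon
#'   count; NA when the deletion causes a frameshift).
#' @export
#' @examples
#' apply_inframe_deletion(edit_descriptor("deletion", 1000, 12)) # 4 aa removed
apply_inframe_deletion <- function(edit) {
  if (!inherits(edit, "edit_descriptor")) {
    stopf("`edit` must be an `edit_descriptor`")
  }
  if (edit$kind != "deletion") {
    stopf("amino-acid deletion arithmetic applies to deletions, not %ss",
          edit$kind)
  }
  if (edit$length %% 3 == 0) {
    list(frameshift = FALSE, aa_removed = as.integer(edit$length / 3))
  } else {
    list(frameshift = TRUE, aa_removed = NA_integer_)
  }
}

# Random edit positions on the genome (0-based).
random_positions <- function(n) {
  floor(stats::runif(n, 0, GENOME_LENGTH_BP))
}

#' Generate a UV-mutagenized library
#'
#' Draws `n_variants` mutant cells. Each cell survives the UV dose with the
#' probability given by the survival curve. Among survivors, a
#' `beneficial_fraction` subset carries a beneficial mutation multiplying the
#' production rate by `beneficial_effect`; the rest are neutral, with rates
#' log-normally spread around the native rate (mean preserved) with relative
#' SD `neutral_sd`. Genotypes follow a minimal descriptive model: lethal
#' variants carry a frameshift deletion, beneficial variants a 12-bp in-frame
#' deletion, neutral mutants a single substitution (no edit at dose 0).
#'
#' @param config a [library_config()].
#' @return tibble with columns `id`, `production_rate` (units/h),
#'   `growth_rate` (divisions/h), `viable`, `beneficial`, and a `genotype`
#'   list-column of [edit_descriptor()] lists. The config (including its seed)
#'   is attached as attribute `"config"`.
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "library_config"))
  local_seed_if(config$seed)
  n <- config$n_variants
  s <- survival_at_dose(config$survival_curve, config$dose)
  viable <- stats::runif(n) < s
  beneficial <- viable & (stats::runif(n) < config$beneficial_fraction)

  # log-normal spread with mean exactly native_rate
  sdlog <- sqrt(log1p(config$neutral_sd^2))
  rate <- config$native_rate *
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  rate[beneficial] <- rate[beneficial] * config$beneficial_effect
  rate[!viable] <- 0

  gsdlog <- sqrt(log1p(config$growth_sd^2))
  growth <- config$native_growth_rate *
    stats::rlnorm(n, meanlog = -gsdlog^2 / 2, sdlog = gsdlog)
  growth[!viable] <- 0

  pos <- random_positions(n)
  genotype <- vector("list", n)
  for (i in seq_len(n)) {
    genotype[[i]] <- if (config$dose == 0) {
      list()
    } else if (!viable[i]) {
      list(edit_descriptor("deletion", pos[i], 11L)) # frameshift, lethal
    } else if (beneficial[i]) {
      list(edit_descriptor("deletion", pos[i], 12L)) # in-frame, 4 codons
    } else {
      list(edit_descriptor("substitution", pos[i], 1L))
    }
  }

  out <- tibble::tibble(
    id = sprintf("mut%06d", seq_len(n)),
    production_rate = rate,
    growth_rate = growth,
    viable = viable,
    beneficial = beneficial,
    genotype = genotype
  )
  attr(out, "config") <- config
  out
}

#' Clonal (single-strain) library
#'
#' A pool of `n` genetically identical cells with a common production and
#' growth rate, used to screen a named strain (native, control, or an evolved
#' isolate) without mutational heterogeneity.
#'
#' @param n number of cells.
#' @param production_rate production rate in units/h.
#' @param growth_rate growth rate in divisions/h.
#' @param id_prefix prefix for cell ids (default "clone").
#' @return tibble in the same shape as [generate_library()].
#' @export
clonal_library <- function(n, production_rate = 1, growth_rate = 0.25,
                           id_prefix = "clone") {
  check_number(n, "n", lower = 1)
  check_number(production_rate, "production_rate", lower = 0)
  tibble::tibble(
    id = sprintf("%s%06d", id_prefix, seq_len(n)),
    production_rate = production_rate,
    growth_rate = growth_rate,
    viable = TRUE,
    beneficial = FALSE,
    genotype = replicate(n, list(), simplify = FALSE)
  )
}

#' Serial-dilution drop-plate counts
#'
#' Simulates colony counts from plating `drop_volume_ml` drops of serially
#' diluted culture: each replicate count is Poisson with mean
#' `true_conc * dilution * drop_volume_ml`.
#'
#' @param true_conc true stock concentration in CFU/mL (>= 0).
#' @param dilutions vector of dilution factors in (0, 1\].
#' @param drop_volume_ml plated drop volume in mL (default 0.005, i.e. 5 uL).
#' @param n_replicates drops per dilution (default 6).
#' @param seed integer seed or NULL.
#' @return tibble with columns `dilution`, `replicate`, `count`.
#' @export
generate_dilution_counts <- function(true_conc, dilutions,
                                     drop_volume_ml = 0.005,
                                     n_replicates = 6, seed = NULL) {
  check_number(true_conc, "true_conc", lower = 0)
  if (length(dilutions) < 1 || any(dilutions <= 0) || any(dilutions > 1)) {
    stopf("`dilutions` must lie in (0, 1]")
  }
  check_number(drop_volume_ml, "drop_volume_ml", lower = 0, strict_lower = TRUE)
  check_number(n_replicates, "n_replicates", lower = 1)
  local_seed_if(seed)
  n_rep <- as.integer(n_replicates)
  tab <- expand.grid(replicate = seq_len(n_rep), dilution = dilutions)
  mu <- true_conc * tab$dilution * drop_volume_ml
  tibble::tibble(
    dilution = tab$dilution,
    replicate = tab$replicate,
    count = stats::rpois(nrow(tab), mu)
  )
}
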