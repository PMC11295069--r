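#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves going up, the convention used
#' for all reported percentages (base R's `round()` rounds halves to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.125, 2) # 0.13, where round() gives 0.12
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Seed the RNG for the calling frame when `seed` is given, restoring the
# previous RNG state on exit; NULL leaves the RNG stream untouched.
local_seed_if <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) {
    withr::local_seed(as.integer(seed), .local_envir = envir)
  }
  invisible(seed)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be a single number", name)
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    stopf("`%s` = %g is outside its valid range", name, x)
  }
  invisible(x)
}
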