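# Three-component Gaussian-mixture strain statistics: baseline normalization,
# EM fit, middle-component mean, strain comparison.

#' Normalize signals to the fluorescein baseline
#'
#' Rescales screening signals so the fluorescein (empty-droplet) peak lands
#' at a common target voltage across runs: each value is multiplied by
#' `target / fluorescein_mean`. With the screening baseline adjusted to
#' 0.1 V, runs recorded at other baselines become directly comparable.
#'
#' @param values signals in volts.
#' @param fluorescein_mean mean of the fluorescein (lowest) peak, volts (> 0).
#' @param target baseline voltage to normalize to (default 0.1).
#' @return normalized signals, volts.
#' @export
#' @examples
#' normalize_baseline(c(0.05, 1.5), 0.05) # doubled: 0.05 V -> 0.1 V baseline
normalize_baseline <- function(values, fluorescein_mean, target = 0.1) {
  check_number(fluorescein_mean, "fluorescein_mean", lower = 0,
               strict_lower = TRUE)
  check_number(target, "target", lower = 0, strict_lower = TRUE)
  values * target / fluorescein_mean
}

#' Fit a Gaussian mixture to droplet signals
#'
#' Maximum-likelihood fit of an `n_components` Gaussian mixture by
#' expectation-maximization with unequal variances. Initialization is
#' k-means++ seeding on the data; `n_restarts` short EM runs are scored and
#' the best is polished to convergence, which makes the fit robust to the
#' strongly unbalanced mixtures typical of droplet screens (a ~90% narrow
#' baseline peak next to minority signal peaks). Values are sorted internally
#' so the fit is invariant to input order, and a small variance floor
#' prevents collapse onto single points.
#'
#' @param values signals in volts (length >= 10 x `n_components`, not all
#'   equal).
#' @param n_components number of Gaussian components (default 3: fluorescein
#'   baseline, majority cellulose peak, high producers).
#' @param seed integer seed making the fit deterministic.
#' @param n_restarts number of initializations (default 10).
#' @param max_iter EM iteration cap for the polishing run.
#' @param tol relative log-likelihood convergence tolerance.
#' @return a `mixture_fit` with `weights`, `means`, `sds` (components sorted
#'   by ascending mean, ties broken by larger weight first),
#'   `fluorescein_mean` (lowest-component mean), `normalized` flag,
#'   `n_events`, `loglik`, `seed`.
#' @export
fit_mixture <- function(values, n_components = 3, seed = NULL,
                        n_restarts = 10, max_iter = 500, tol = 1e-8) {
  check_number(n_components, "n_components", lower = 1)
  k <- as.integer(n_components)
  x <- as.numeric(values)
  if (anyNA(x)) stopf("`values` must not contain NA")
  n <- length(x)
  if (n < 10 * k) {
    stopf("need at least %d values to fit %d components, got %d", 10 * k, k, n)
  }
  if (stats::sd(x) == 0) stopf("all values are equal; mixture is degenerate")
  x <- sort(x) # order invariance for the RNG-driven seeding
  sd_floor <- 1e-3 * stats::sd(x)

  local_seed_if(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- kmeanspp_init(x, k, sd_floor)
    fit <- em_gauss(x, init, max_iter = 25, tol = 1e-6, sd_floor = sd_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  fit <- em_gauss(x, best, max_iter = max_iter, tol = tol, sd_floor = sd_floor)

  ord <- order(fit$means, -fit$weights)
  structure(
    list(weights = fit$weights[ord], means = fit$means[ord],
         sds = fit$sds[ord], fluorescein_mean = fit$means[ord][1],
         normalized = FALSE, n_events = n, loglik = fit$loglik,
         n_iter = fit$n_iter, converged = fit$converged, seed = seed),
    class = "mixture_fit"
  )
}

# k-means++ seeding: centers drawn with probability proportional to squared
# distance from the nearest already-chosen center, then one hard assignment.
kmeanspp_init <- function(x, k, sd_floor) {
  n <- length(x)
  centers <- x[sample.int(n, 1)]
  d2 <- (x - centers[1])^2
  for (j in seq_len(k - 1)) {
    nxt <- if (sum(d2) <= 0) {
      x[sample.int(n, 1)]
    } else {
      x[sample.int(n, 1, prob = d2)]
    }
    centers <- c(centers, nxt)
    d2 <- pmin(d2, (x - nxt)^2)
  }
  cl <- max.col(-abs(outer(x, centers, "-")), ties.method = "first")
  means <- numeric(k); sds <- numeric(k); w <- numeric(k)
  for (j in seq_len(k)) {
    xj <- x[cl == j]
    if (length(xj) == 0) xj <- centers[j]
    means[j] <- mean(xj)
    sds[j] <- max(stats::sd(c(xj, xj[1])), sd_floor, na.rm = TRUE)
    w[j] <- max(length(xj), 1) / n
  }
  list(weights = w / sum(w), means = means, sds = sds)
}

em_gauss <- function(x, init, max_iter, tol, sd_floor) {
  n <- length(x); k <- length(init$means)
  w <- init$weights; mu <- init$means; s <- pmax(init$sds, sd_floor)
  prev_ll <- -Inf; ll <- -Inf; converged <- FALSE; it <- 0
  for (it in seq_len(max_iter)) {
    # E-step in log space
    lp <- vapply(seq_len(k),
                 function(j) log(w[j]) + stats::dnorm(x, mu[j], s[j], log = TRUE),
                 numeric(n))
    m <- do.call(pmax, as.data.frame(lp))
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    z <- exp(lp - lse)
    # M-step
    nk <- colSums(z)
    nk <- pmax(nk, 1e-10)
    w <- nk / n
    mu <- colSums(z * x) / nk
    s <- sqrt(colSums(z * (x - rep(mu, each = n))^2) / nk)
    s <- pmax(s, sd_floor)
    if (is.finite(prev_ll) && abs(ll - prev_ll) <= tol * (abs(prev_ll) + 1)) {
      converged <- TRUE
      break
    }
    prev_ll <- ll
  }
  list(weights = w, means = mu, sds = s, loglik = ll, n_iter = it,
       converged = converged)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit (%d components, n = %d%s)\n",
              length(x$means), x$n_events,
              if (x$normalized) ", baseline-normalized" else ""))
  for (j in seq_along(x$means)) {
    cat(sprintf("  comp %d: weight %.4f  mean %.3f V  sd %.4f V\n",
                j, x$weights[j], x$means[j], x$sds[j]))
  }
  cat(sprintf("  loglik %.2f (%s in %d iterations)\n", x$loglik,
              if (isTRUE(x$converged)) "converged" else "not converged",
              x$n_iter))
  invisible(x)
}

#' Rescale a mixture fit to the normalized baseline
#'
#' Multiplies the fitted means and SDs by `target / fluorescein_mean`
#' (the same linear map [normalize_baseline()] applies to raw signals; a
#' Gaussian-mixture MLE is equivariant under it), putting the lowest
#' component exactly at `target`.
#'
#' @param fit a [fit_mixture()] result.
#' @param target baseline voltage to normalize to (default 0.1).
#' @return the rescaled `mixture_fit` with `normalized = TRUE`.
#' @export
normalize_fit <- function(fit, target = 0.1) {
  stopifnot(inherits(fit, "mixture_fit"))
  f <- target / fit$fluorescein_mean
  fit$means <- fit$means * f
  fit$sds <- fit$sds * f
  fit$fluorescein_mean <- fit$means[1]
  fit$normalized <- TRUE
  fit
}

#' Middle-component mean: the strain statistic
#'
#' The mean of the middle component (by ascending mean) of a three-component
#' fit — the cellulose-fluorescence of the majority occupied-droplet
#' population, used to compare strains.
#'
#' @param fit a 3-component [fit_mixture()] result.
#' @return middle mean in volts.
#' @export
middle_mean <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (length(fit$means) != 3) {
    stopf("middle mean is defined for 3-component fits, got %d",
          length(fit$means))
  }
  fit$means[2]
}

#' Screen a strain: fit, normalize, summarize
#'
#' Convenience wrapper for one screening run: fits the three-component
#' mixture to the raw signals, normalizes to the target baseline, and
#' returns the normalized fit.
#'
#' @inheritParams fit_mixture
#' @param target baseline normalization target, volts.
#' @return a normalized `mixture_fit`.
#' @export
screen_strain <- function(values, target = 0.1, seed = NULL, ...) {
  normalize_fit(fit_mixture(values, n_components = 3, seed = seed, ...),
                target = target)
}

#' Percent increase over a reference strain
#'
#' `100 * (test / reference - 1)`; the exact value is returned, and reports
#' round half-up to the nearest integer (use [round_half_up()]).
#'
#' @param reference_mean reference (native) middle mean (> 0).
#' @param test_mean test-strain middle mean.
#' @return percent increase (negative for a decrease).
#' @export
#' @examples
#' percent_increase(0.388, 0.527) # ~36
#' percent_increase(0.388, 0.590) # ~52
percent_increase <- function(reference_mean, test_mean) {
  check_number(reference_mean, "reference_mean", lower = 0,
               strict_lower = TRUE)
  check_number(test_mean, "test_mean")
  100 * (test_mean / reference_mean - 1)
}

#' Fraction of signals above a cut
#'
#' Percent of values strictly above `cut`, the high-producer tail statistic
#' (e.g. the percent of droplets above 3 V).
#'
#' @param values signals in volts (non-empty).
#' @param cut voltage cut.
#' @return percent in \[0, 100\] (exact; report at 2 decimals with
#'   [round_half_up()]).
#' @export
fraction_above <- function(values, cut) {
  if (length(values) == 0) stopf("`values` must be non-empty")
  check_number(cut, "cut")
  100 * mean(values > cut)
}
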