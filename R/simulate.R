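# run `expr` under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required; generators keep no global random state",
         call. = FALSE)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate factorial design responses
#'
#' Generates a 2^2 + center point design and a response following the
#' first-order model with interaction in physical units,
#' `y = B0 + B1*u1 + B2*u2 + B3*u1*u2 + e`, with i.i.d. Gaussian noise
#' `e ~ N(0, sigma^2)`.  With `sigma = 0`, [fit_first_order()] recovers the
#' coefficients exactly; the generator is the round-trip partner of the
#' estimator.
#'
#' @param factors list of two [factor_spec()] objects (default: the inulin /
#'   xanthan factors of the reference study).
#' @param coef_physical numeric length-4 vector `(B0, B1, B2, B3)` in
#'   physical units.
#' @param sigma response noise standard deviation (>= 0).
#' @param n_center number of center replicates (default 3, as in the
#'   reference design).
#' @param seed required integer seed; the caller's RNG state is untouched.
#' @param response name of the generated response column.
#' @return A `design_table` with the generated response column and the true
#'   coefficients attached as `attr(, "truth")`.
#' @examples
#' sim <- simulate_design_responses(coef_physical = c(-0.287, -0.0003,
#'                                                    0.9067, 0.1267),
#'                                  sigma = 0, seed = 1)
#' coef(fit_first_order(sim, "response"))
#' @export
simulate_design_responses <- function(factors = petit_suisse_factors(),
                                      coef_physical, sigma, n_center = 3L,
                                      seed, response = "response") {
  stopifnot(is.numeric(coef_physical), length(coef_physical) == 4L,
            is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  design <- full_factorial(factors, n_center = n_center)
  factors <- design_factors(design)
  nms <- names(factors)
  u1 <- design[[nms[1]]]; u2 <- design[[nms[2]]]
  B <- unname(coef_physical)
  mean_y <- B[1] + B[2] * u1 + B[3] * u2 + B[4] * u1 * u2
  noise <- with_local_seed(seed, stats::rnorm(nrow(design), 0, sigma))
  design[[response]] <- mean_y + noise
  attr(design, "truth") <- stats::setNames(
    B, c("intercept", nms, paste(nms, collapse = ":")))
  design
}

#' Simulate a viable-count storage series
#'
#' Generates `N(t) = N0 * exp(integral of mu)` with a piecewise-constant
#' specific growth rate (e.g. growth early in storage, decline later, as seen
#' in fermented products), multiplied by lognormal noise with coefficient of
#' variation `cv`.  Lognormal noise keeps counts positive.  With `cv = 0` the
#' kinetics estimators invert the generator exactly.
#'
#' @param n0 initial count (CFU/mL, > 0).
#' @param mu specific growth rate(s) per day: a scalar, or one rate per
#'   phase.
#' @param phase_ends increasing days at which each phase ends; the last must
#'   cover `max(days)`.  Defaults to a single phase.
#' @param days sampling days starting at 0 (default `c(0, 7, 14, 21, 28)`).
#' @param cv multiplicative noise coefficient of variation (>= 0).
#' @param seed required integer seed.
#' @param trial trial label.
#' @return A [viability_series()] with the noiseless log-counts attached as
#'   `attr(, "truth")`.
#' @examples
#' s <- simulate_viability(1.14e6, mu = 0.00426, cv = 0, seed = 1)
#' specific_growth_rate(s, c(0, 14))
#' @export
simulate_viability <- function(n0, mu, phase_ends = max(days),
                               days = c(0, 7, 14, 21, 28), cv = 0, seed,
                               trial = "sim") {
  stopifnot(is.numeric(n0), length(n0) == 1L, n0 > 0,
            is.numeric(mu), length(mu) >= 1L,
            is.numeric(cv), length(cv) == 1L, cv >= 0,
            is.numeric(days), length(days) >= 2L, days[1] == 0)
  if (length(phase_ends) != length(mu)) {
    stop("'phase_ends' must give one end day per growth phase", call. = FALSE)
  }
  if (any(diff(phase_ends) <= 0) || max(phase_ends) < max(days)) {
    stop("'phase_ends' must be increasing and cover the sampling days",
         call. = FALSE)
  }
  # integrate the piecewise-constant rate from 0 to each sampling day
  starts <- c(0, phase_ends[-length(phase_ends)])
  log_n <- vapply(days, function(t) {
    spans <- pmax(0, pmin(t, phase_ends) - starts)
    log(n0) + sum(mu * spans)
  }, numeric(1))
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    noise <- with_local_seed(seed,
                             stats::rnorm(length(days), -sdlog^2 / 2, sdlog))
  } else {
    noise <- numeric(length(days))
  }
  out <- viability_series(trial, days, exp(log_n + noise))
  attr(out, "truth") <- log_n
  out
}

#' Simulate storage pH / acidity series and syneresis measurements
#'
#' pH decays exponentially from `ph_start` towards `ph_end`
#' (`ph(t) = ph_end + (ph_start - ph_end) * exp(-rate * t)`), titratable
#' acidity rises complementarily from `tta_start` to `tta_end`, and the
#' syneresis percentage follows `baseline + drift * day` plus Gaussian noise,
#' truncated at 0 (a gel cannot expel negative whey).  Syneresis is returned
#' as whey/cheese weight pairs so that [syneresis_percent()] round-trips the
#' generated percentage.
#'
#' @param ph_start,ph_end pH at day 0 and the asymptote approached by the end
#'   of storage.
#' @param tta_start,tta_end titratable acidity (% lactic acid) endpoints.
#' @param rate exponential approach rate (day^-1, > 0).
#' @param days sampling days (default `c(0, 7, 14, 21, 28)`).
#' @param syneresis_baseline,syneresis_drift,syneresis_sd linear drift model
#'   of the syneresis percentage and its noise sd.
#' @param cheese_g initial cheese weight used to convert percentages to whey
#'   weights (default 100 g).
#' @param seed required integer seed.
#' @param trial trial label.
#' @return List with `ph` and `tta` ([storage_series()]) and `syneresis`, a
#'   `data.frame` of `day`, `whey_g`, `cheese_g`.
#' @export
simulate_storage_series <- function(ph_start = 3.82, ph_end = 2.96,
                                    tta_start = 1.22, tta_end = 1.50,
                                    rate = 0.1, days = c(0, 7, 14, 21, 28),
                                    syneresis_baseline = 0,
                                    syneresis_drift = 0,
                                    syneresis_sd = 0,
                                    cheese_g = 100, seed, trial = "sim") {
  stopifnot(rate > 0, syneresis_sd >= 0, cheese_g > 0,
            is.numeric(days), length(days) >= 2L)
  decay <- exp(-rate * days)
  ph <- ph_end + (ph_start - ph_end) * decay
  tta <- tta_end + (tta_start - tta_end) * decay
  syn <- syneresis_baseline + syneresis_drift * days
  if (syneresis_sd > 0) {
    syn <- syn + with_local_seed(seed,
                                 stats::rnorm(length(days), 0, syneresis_sd))
  }
  syn <- pmin(100, pmax(0, syn))
  list(
    ph = storage_series(trial, days, ph, measure = "pH"),
    tta = storage_series(trial, days, tta, measure = "tta_percent"),
    syneresis = data.frame(day = days, whey_g = syn / 100 * cheese_g,
                           cheese_g = cheese_g)
  )
}
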