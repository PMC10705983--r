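#' Viability time series of a stored product
#'
#' A series of viable cell counts (CFU/mL) at increasing storage days,
#' starting at day 0, for one formulation trial.
#'
#' @param trial trial identifier (coerced to character).
#' @param days numeric storage days, strictly increasing, first equal to 0.
#' @param cfu positive viable counts (CFU/mL), one per day.
#' @return Object of class `"viability_series"`.
#' @export
viability_series <- function(trial, days, cfu) {
  trial <- as.character(trial)
  stopifnot(length(trial) == 1L, is.numeric(days), is.numeric(cfu))
  if (length(days) != length(cfu) || length(days) < 2L) {
    stop("'days' and 'cfu' must have equal length >= 2", call. = FALSE)
  }
  if (anyNA(days) || anyNA(cfu)) stop("missing values not allowed", call. = FALSE)
  if (days[1] != 0) stop("the series must start at day 0", call. = FALSE)
  if (any(diff(days) <= 0)) stop("'days' must be strictly increasing", call. = FALSE)
  if (any(cfu <= 0)) stop("viable counts must be positive", call. = FALSE)
  structure(list(trial = trial, days = days, cfu = cfu),
            class = "viability_series")
}

#' @export
print.viability_series <- function(x, ...) {
  cat(sprintf("Viability series, trial %s: %d points over %g days\n",
              x$trial, length(x$days), max(x$days)))
  print(data.frame(day = x$days, cfu_per_ml = x$cfu))
  invisible(x)
}

count_at <- function(series, day) {
  i <- match(day, series$days)
  if (is.na(i)) {
    stop("day ", day, " is not a sampling point of trial ", series$trial,
         call. = FALSE)
  }
  series$cfu[i]
}

#' Specific rate of cell death
#'
#' First-order inactivation rate over storage,
#' `k = ln(N0 / N(t_end)) / t_end` per day, with `N0` the day-0 count.
#' Negative `k` means the population grew over the interval; over the same
#' window `k` equals exactly `-mu` from [specific_growth_rate()].
#'
#' @param series a [viability_series()].
#' @param t_end storage day to evaluate at; must be a sampling day > 0
#'   (default: the last day of the series).
#' @return `k` in day^-1.
#' @examples
#' vb <- petit_suisse_viability()
#' cell_death_rate(vb[["4"]])  # -0.00271 day^-1
#' @export
cell_death_rate <- function(series, t_end = max(series$days)) {
  stopifnot(inherits(series, "viability_series"))
  if (length(t_end) != 1L || !is.finite(t_end) || t_end <= 0) {
    stop("'t_end' must be a single positive day", call. = FALSE)
  }
  # computed as a log difference so that k over [0, t] is exactly -mu
  (log(series$cfu[1]) - log(count_at(series, t_end))) / t_end
}

#' Specific growth rate over an exponential window
#'
#' `mu = (ln N(t) - ln N(t0)) / (t - t0)` per day, with both window endpoints
#' sampling days of the series.  The default window of days 0-14 corresponds
#' to the early storage phase in which lactic acid bacteria in the reference
#' study grow exponentially.
#'
#' @param series a [viability_series()].
#' @param window length-2 increasing day interval (default `c(0, 14)`).
#' @return `mu` in day^-1.
#' @examples
#' vb <- petit_suisse_viability()
#' specific_growth_rate(vb[["4"]])  # 0.00426 day^-1
#' @export
specific_growth_rate <- function(series, window = c(0, 14)) {
  stopifnot(inherits(series, "viability_series"))
  if (length(window) != 2L || !all(is.finite(window)) ||
      window[1] >= window[2]) {
    stop("'window' must be an increasing day interval", call. = FALSE)
  }
  n0 <- count_at(series, window[1])
  n1 <- count_at(series, window[2])
  (log(n1) - log(n0)) / (window[2] - window[1])
}

#' Detect the sampling window with the steepest growth
#'
#' Optional alternative to the fixed day 0-14 window: returns the interval
#' between consecutive sampling points that maximizes the per-day log-slope
#' of the counts, extended while the slope stays positive.
#'
#' @param series a [viability_series()].
#' @return Length-2 day interval usable as the `window` argument of
#'   [specific_growth_rate()].
#' @export
growth_window <- function(series) {
  stopifnot(inherits(series, "viability_series"))
  slopes <- diff(log(series$cfu)) / diff(series$days)
  i <- which.max(slopes)
  lo <- i
  hi <- i + 1L
  while (lo > 1L && slopes[lo - 1L] > 0) lo <- lo - 1L
  while (hi <= length(slopes) && slopes[hi] > 0) hi <- hi + 1L
  c(series$days[lo], series$days[hi])
}

#' Percent cell survival over the whole storage period
#'
#' `N(final) / N0 * 100`; values above 100 indicate net growth and
#' correspond exactly to a negative overall death rate.
#'
#' @param series a [viability_series()].
#' @return Survival percentage (> 0).
#' @export
survival_percent <- function(series) {
  stopifnot(inherits(series, "viability_series"))
  series$cfu[length(series$cfu)] / series$cfu[1] * 100
}

#' Kinetic parameter summary for several trials
#'
#' Applies [cell_death_rate()] (full storage span),
#' [specific_growth_rate()] (given window) and [survival_percent()] to a
#' list of series.
#'
#' @param series_list list of [viability_series()].
#' @param window growth window passed to [specific_growth_rate()].
#' @return `data.frame` with columns `trial`, `k`, `mu`, `survival`.
#' @examples
#' kinetics_summary(petit_suisse_viability())
#' @export
kinetics_summary <- function(series_list, window = c(0, 14)) {
  stopifnot(is.list(series_list), length(series_list) >= 1L)
  data.frame(
    trial = vapply(series_list, `[[`, character(1), "trial"),
    k = vapply(series_list, cell_death_rate, numeric(1)),
    mu = vapply(series_list, specific_growth_rate, numeric(1),
                window = window),
    survival = vapply(series_list, survival_percent, numeric(1)),
    row.names = NULL
  )
}

#' Syneresis index of a dairy gel
#'
#' Percentage of whey expelled from the gel,
#' `100 * whey_g / cheese_g`, with `whey_g` the weight of whey separated
#' after centrifugation and `cheese_g` the initial cheese weight.  The index
#' is dimensionless: rescaling both weights by a common factor leaves it
#' unchanged.  A gel that expels no whey scores 0%.
#'
#' @param whey_g whey weight(s) in g, >= 0.
#' @param cheese_g initial cheese weight(s) in g, > 0, with
#'   `whey_g <= cheese_g`.
#' @return Syneresis percentage(s) in `[0, 100]`.
#' @examples
#' syneresis_percent(14.565, 100)  # 14.565 %
#' @export
syneresis_percent <- function(whey_g, cheese_g) {
  stopifnot(is.numeric(whey_g), is.numeric(cheese_g))
  if (any(cheese_g <= 0)) stop("initial cheese weight must be positive",
                               call. = FALSE)
  if (any(whey_g < 0)) stop("whey weight cannot be negative", call. = FALSE)
  if (any(whey_g > cheese_g)) {
    stop("whey weight cannot exceed the initial cheese weight", call. = FALSE)
  }
  whey_g / cheese_g * 100
}

#' Storage measurement series (pH, titratable acidity, ...)
#'
#' @param trial trial identifier.
#' @param days increasing storage days.
#' @param values measurements (pH units, % lactic acid, ...), one per day.
#' @param measure label for the measured quantity (default `"value"`).
#' @return Object of class `"storage_series"`.
#' @export
storage_series <- function(trial, days, values, measure = "value") {
  trial <- as.character(trial)
  stopifnot(length(trial) == 1L, is.numeric(days), is.numeric(values))
  if (length(days) != length(values) || length(days) < 2L) {
    stop("'days' and 'values' must have equal length >= 2", call. = FALSE)
  }
  if (anyNA(days) || anyNA(values)) stop("missing values not allowed", call. = FALSE)
  if (any(diff(days) <= 0)) stop("'days' must be strictly increasing", call. = FALSE)
  structure(list(trial = trial, days = days, values = values,
                 measure = measure),
            class = "storage_series")
}

#' Summarize the trend of a storage series
#'
#' Reports the first and last values, their signed change, whether the series
#' is monotone (`"decreasing"`, `"increasing"`, `"constant"`) or
#' `"non-monotone"`, and the day at which the extremum (the maximum for a net
#' rise, the minimum for a net fall) occurs.
#'
#' @param series a [storage_series()].
#' @return List with `start`, `end`, `delta`, `direction`, `monotone`,
#'   `extremum_day`, `extremum_value`.
#' @examples
#' s <- storage_series("1", c(7, 14, 21), c(3.82, 3.4, 2.96), "pH")
#' storage_trend(s)$direction
#' @export
storage_trend <- function(series) {
  stopifnot(inherits(series, "storage_series"))
  v <- series$values
  delta <- v[length(v)] - v[1]
  steps <- diff(v)
  monotone <- if (all(steps == 0)) "constant"
              else if (all(steps >= 0)) "increasing"
              else if (all(steps <= 0)) "decreasing"
              else "non-monotone"
  direction <- if (delta > 0) "increasing"
               else if (delta < 0) "decreasing"
               else "stable"
  i_ext <- if (delta >= 0) which.max(v) else which.min(v)
  list(start = v[1], end = v[length(v)], delta = delta,
       direction = direction, monotone = monotone,
       extremum_day = series$days[i_ext], extremum_value = v[i_ext])
}
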