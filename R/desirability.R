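#' Derringer-Suich desirability specification for one response
#'
#' Maps a predicted response value onto a 0-1 desirability scale with the
#' classical piecewise power ramps:
#' \describe{
#'   \item{maximize}{0 below `low`, `((y - low)/(target - low))^s` between,
#'     1 at or above `target`.}
#'   \item{minimize}{1 at or below `target`, `((high - y)/(high - target))^s`
#'     between, 0 at or above `high`.}
#'   \item{target}{ramps up from `low` to 1 at `target` (power `s`), then
#'     down to 0 at `high` (power `t`).}
#'   \item{range}{as `target` but with a plateau of 1 on
#'     `[target[1], target[2]]`.}
#' }
#' Bounds left `NULL` are resolved at optimization time from the range of the
#' model's predictions over the search domain.
#'
#' @param response response name the spec applies to (must match a fitted
#'   model).
#' @param kind one of `"maximize"`, `"minimize"`, `"target"`, `"range"`.
#' @param low,high lower/upper bounds of the ramp in response units, or
#'   `NULL` for automatic resolution.
#' @param target the goal value: scalar for `maximize` / `minimize` /
#'   `target`, a length-2 increasing interval for `range`.
#' @param s,t positive shape exponents for the rising and falling ramps
#'   (1 = linear, the default).
#' @param weight positive importance weight used in the composite.
#' @return Object of class `"desirability_spec"`.
#' @examples
#' sp <- desirability_spec("firmness", "range", low = 0, high = 8,
#'                         target = c(3, 6))
#' desirability_value(sp, c(1.5, 4, 7))
#' @export
desirability_spec <- function(response,
                              kind = c("maximize", "minimize", "target", "range"),
                              low = NULL, high = NULL, target = NULL,
                              s = 1, t = 1, weight = 1) {
  kind <- match.arg(kind)
  stopifnot(is.character(response), length(response) == 1L)
  if (s <= 0 || t <= 0) stop("shape exponents must be positive", call. = FALSE)
  if (weight <= 0) stop("weight must be positive", call. = FALSE)
  n_target <- if (kind == "range") 2L else 1L
  if (is.null(target) || length(target) != n_target || !is.numeric(target)) {
    stop("kind '", kind, "' needs a numeric target of length ", n_target,
         call. = FALSE)
  }
  if (kind == "range" && target[1] >= target[2]) {
    stop("range target must be increasing", call. = FALSE)
  }
  spec <- structure(
    list(response = response, kind = kind, low = low, high = high,
         target = target, s = s, t = t, weight = weight),
    class = "desirability_spec"
  )
  validate_desirability_bounds(spec, partial = TRUE)
  spec
}

validate_desirability_bounds <- function(spec, partial = FALSE) {
  L <- spec$low; U <- spec$high; Tg <- spec$target
  if (!partial) {
    need_low <- spec$kind %in% c("maximize", "target", "range")
    need_high <- spec$kind %in% c("minimize", "target", "range")
    if (need_low && is.null(L)) stop("spec for '", spec$response,
                                     "' needs a lower bound", call. = FALSE)
    if (need_high && is.null(U)) stop("spec for '", spec$response,
                                      "' needs an upper bound", call. = FALSE)
  }
  if (!is.null(L) && !is.null(U) && L >= U) {
    stop("lower bound must be below upper bound", call. = FALSE)
  }
  if (!is.null(L) && any(Tg < L)) stop("target below lower bound", call. = FALSE)
  if (!is.null(U) && any(Tg > U)) stop("target above upper bound", call. = FALSE)
  invisible(spec)
}

# fill missing bounds from the prediction range over the search domain,
# widening only a degenerate edge (bound equal to the target) so that every
# ramp keeps a nonzero span
resolve_bounds <- function(spec, pred_range) {
  eps <- 1e-8 * max(1, max(abs(pred_range)))
  if (is.null(spec$low)) {
    spec$low <- min(pred_range[1], min(spec$target))
    if (spec$low == min(spec$target)) spec$low <- spec$low - eps
  }
  if (is.null(spec$high)) {
    spec$high <- max(pred_range[2], max(spec$target))
    if (spec$high == max(spec$target)) spec$high <- spec$high + eps
  }
  validate_desirability_bounds(spec)
  spec
}

#' Evaluate a desirability function
#'
#' @param spec a [desirability_spec()] with resolved (non-`NULL`) bounds as
#'   its kind requires.
#' @param y numeric vector of response values.
#' @return Desirabilities in `[0, 1]`, same length as `y`.
#' @export
desirability_value <- function(spec, y) {
  stopifnot(inherits(spec, "desirability_spec"), is.numeric(y))
  validate_desirability_bounds(spec)
  L <- spec$low; U <- spec$high; Tg <- spec$target
  ramp <- function(num, den, p) pmin(1, pmax(0, num / den))^p
  d <- switch(spec$kind,
    maximize = ramp(y - L, Tg - L, spec$s),
    minimize = ramp(U - y, U - Tg, spec$s),
    target = ifelse(y <= Tg,
                    ramp(y - L, Tg - L, spec$s),
                    ramp(U - y, U - Tg, spec$t)),
    range = ifelse(y < Tg[1],
                   ramp(y - L, Tg[1] - L, spec$s),
                   ifelse(y > Tg[2], ramp(U - y, U - Tg[2], spec$t), 1))
  )
  pmin(1, pmax(0, d))
}

#' Weighted geometric-mean composite desirability
#'
#' `D = (prod d_i^w_i)^(1 / sum w_i)`.  `D` is 0 exactly when some `d_i` is
#' 0, lies between the smallest and largest `d_i`, and is invariant under
#' rescaling all weights by a common constant.
#'
#' @param d numeric vector of individual desirabilities in `[0, 1]`.
#' @param weights positive weights, recycled to `length(d)` (default: equal).
#' @return Composite desirability in `[0, 1]`.
#' @export
composite_desirability <- function(d, weights = 1) {
  if (length(d) == 0L) stop("need at least one desirability", call. = FALSE)
  if (any(d < 0 | d > 1)) stop("desirabilities must lie in [0, 1]", call. = FALSE)
  w <- rep_len(weights, length(d))
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  if (any(d == 0)) return(0)
  exp(sum(w * log(d)) / sum(w))
}

# evaluate every model and individual desirability on a set of points;
# returns list(d = matrix, D = vector, preds = matrix, specs = resolved)
evaluate_desirability <- function(fits, specs, points, domain_ranges) {
  stopifnot(length(fits) == length(specs))
  fit_names <- vapply(fits, `[[`, character(1), "response")
  spec_names <- vapply(specs, `[[`, character(1), "response")
  if (!setequal(fit_names, spec_names)) {
    stop("desirability specs must match the fitted responses one-to-one",
         call. = FALSE)
  }
  specs <- specs[match(fit_names, spec_names)]
  preds <- vapply(fits, function(f) as.numeric(predict(f, points)),
                  numeric(nrow(points)))
  preds <- matrix(preds, nrow = nrow(points),
                  dimnames = list(NULL, fit_names))
  # bounds resolve against the model's prediction range over the full domain
  corners <- expand.grid(domain_ranges, KEEP.OUT.ATTRS = FALSE)
  specs <- lapply(seq_along(specs), function(j) {
    rng <- range(predict(fits[[j]], corners))
    resolve_bounds(specs[[j]], rng)
  })
  d <- vapply(seq_along(specs),
              function(j) desirability_value(specs[[j]], preds[, j]),
              numeric(nrow(points)))
  d <- matrix(d, nrow = nrow(points), dimnames = list(NULL, fit_names))
  w <- vapply(specs, `[[`, numeric(1), "weight")
  D <- apply(d, 1L, composite_desirability, weights = w)
  list(d = d, D = D, preds = preds, specs = specs)
}

check_domain <- function(fits, domain) {
  nms <- names(fits[[1]]$factors)
  if (is.null(domain)) {
    domain <- lapply(fits[[1]]$factors, function(f) c(f$low, f$high))
  }
  if (!all(nms %in% names(domain))) {
    stop("domain must provide an interval per factor: ",
         paste(nms, collapse = ", "), call. = FALSE)
  }
  domain <- domain[nms]
  for (nm in nms) {
    r <- domain[[nm]]
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2]) {
      stop("domain for '", nm, "' must be a finite non-empty interval",
           call. = FALSE)
    }
  }
  domain
}

#' Maximize the composite desirability over the factor space
#'
#' Exhaustively evaluates the composite desirability of all fitted responses
#' on a rectangular grid over `domain` and returns the argmax, optionally
#' polished by a derivative-free Nelder-Mead search clamped to the domain.
#' The refined point is only accepted if it does not decrease `D`.  Grid ties
#' are broken towards the smallest factor values (first factor first), making
#' the result deterministic.
#'
#' @param fits list of [fit_first_order()] models sharing the same factors.
#' @param specs list of [desirability_spec()], one per model, matched by
#'   response name.  `NULL` bounds are resolved from each model's prediction
#'   range over `domain`.
#' @param domain named list of physical search intervals per factor; default
#'   is the design box.  Points outside the design box are permitted and the
#'   optimum is flagged as extrapolated when it lies outside.
#' @param resolution grid points per axis (default 201).
#' @param refine logical: polish the grid argmax with Nelder-Mead (default
#'   `TRUE`).
#' @return Object of class `"desirability_optimum"`: `optimum` (named
#'   physical levels), `coded` (same point in coded units),
#'   `predicted` (each model's prediction there), `d_individual`,
#'   `D`, `extrapolated`, `degenerate` (`TRUE` when `D` is 0 everywhere on
#'   the grid), and search metadata.
#' @examples
#' des <- petit_suisse_design()
#' fits <- lapply(c("firmness", "cohesivity"), fit_first_order, design = des)
#' specs <- list(desirability_spec("firmness", "range", target = c(3, 6)),
#'               desirability_spec("cohesivity", "maximize", target = 1.29))
#' optimize_desirability(fits, specs,
#'                       domain = list(inulin = c(0, 20), xanthan = c(0.3, 1.5)))
#' @export
optimize_desirability <- function(fits, specs, domain = NULL,
                                  resolution = 201L, refine = TRUE) {
  stopifnot(length(fits) >= 1L, length(fits) == length(specs))
  domain <- check_domain(fits, domain)
  nms <- names(domain)
  resolution <- rep_len(as.integer(resolution), length(domain))
  if (any(resolution < 2L)) stop("resolution must be >= 2", call. = FALSE)
  axes <- lapply(seq_along(domain), function(j) {
    seq(domain[[j]][1], domain[[j]][2], length.out = resolution[j])
  })
  names(axes) <- nms
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  ev <- evaluate_desirability(fits, specs, grid, domain)
  Dmax <- max(ev$D)
  cand <- which(ev$D == Dmax)
  # deterministic tie-break: smallest factor values, first factor first
  cand <- cand[order(grid[cand, 1], grid[cand, 2])]
  best_i <- cand[1]
  best <- as.numeric(grid[best_i, nms])
  best_D <- Dmax
  refined <- FALSE
  if (refine && Dmax > 0) {
    lo <- vapply(domain, `[`, numeric(1), 1L)
    hi <- vapply(domain, `[`, numeric(1), 2L)
    obj <- function(par) {
      par <- pmin(hi, pmax(lo, par))
      pt <- as.data.frame(as.list(stats::setNames(par, nms)))
      -evaluate_desirability(fits, specs, pt, domain)$D
    }
    opt <- stats::optim(best, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    par <- pmin(hi, pmax(lo, opt$par))
    if (-opt$value >= best_D) {
      best <- par
      best_D <- -opt$value
      refined <- TRUE
    }
  }
  pt <- as.data.frame(as.list(stats::setNames(best, nms)))
  ev_best <- evaluate_desirability(fits, specs, pt, domain)
  factors <- fits[[1]]$factors
  coded <- vapply(nms, function(nm) encode_level(factors[[nm]], pt[[nm]]),
                  numeric(1))
  structure(
    list(optimum = stats::setNames(best, nms),
         coded = coded,
         predicted = ev_best$preds[1, ],
         d_individual = ev_best$d[1, ],
         D = best_D,
         extrapolated = any(abs(coded) > 1 + 1e-12),
         degenerate = Dmax == 0,
         domain = domain, resolution = resolution, refined = refined,
         specs = ev_best$specs),
    class = "desirability_optimum"
  )
}

#' @export
print.desirability_optimum <- function(x, ...) {
  cat("Composite desirability optimum\n")
  for (nm in names(x$optimum)) {
    cat(sprintf("  %s = %.4g (coded %+.3f)\n", nm, x$optimum[nm], x$coded[nm]))
  }
  cat(sprintf("  D = %.4f%s%s\n", x$D,
              if (x$extrapolated) " [outside tested design region]" else "",
              if (x$degenerate) " [degenerate: D = 0 everywhere]" else ""))
  d <- signif(x$d_individual, 4)
  cat("  individual d:", paste(names(d), d, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Composite desirability grid for contour plotting
#'
#' Evaluates the composite desirability on a rectangular grid (same
#' configuration as [optimize_desirability()] without refinement) and marks
#' the argmax, for export or contour plotting.
#'
#' @inheritParams optimize_desirability
#' @return `data.frame` with one column per factor and a `D` column; the
#'   argmax row index is attached as attribute `"optimum_index"` and the axis
#'   vectors as `"axes"`.
#' @export
desirability_contour <- function(fits, specs, domain = NULL,
                                 resolution = 101L) {
  domain <- check_domain(fits, domain)
  nms <- names(domain)
  resolution <- rep_len(as.integer(resolution), length(domain))
  axes <- lapply(seq_along(domain), function(j) {
    seq(domain[[j]][1], domain[[j]][2], length.out = resolution[j])
  })
  names(axes) <- nms
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  ev <- evaluate_desirability(fits, specs, grid, domain)
  grid$D <- ev$D
  cand <- which(grid$D == max(grid$D))
  cand <- cand[order(grid[cand, 1], grid[cand, 2])]
  attr(grid, "optimum_index") <- cand[1]
  attr(grid, "axes") <- axes
  grid
}

#' Default formulation targets for the Petit Suisse study
#'
#' The four-response desirability configuration used to optimize the
#' reference formulation: total sugars minimized towards 10 g/100 g,
#' firmness in the 3-6 N range, viscosity index at a target of 13, and
#' cohesivity maximized towards 1.29 N.  Ramp bounds are left `NULL` and
#' resolved from each model's prediction range over the search domain; shapes
#' are linear with equal weights.
#'
#' @return Named list of four [desirability_spec()] objects.
#' @export
petit_suisse_desirability_specs <- function() {
  list(
    total_sugars = desirability_spec("total_sugars", "minimize", target = 10),
    firmness = desirability_spec("firmness", "range", target = c(3, 6)),
    viscosity_index = desirability_spec("viscosity_index", "target", target = 13),
    cohesivity = desirability_spec("cohesivity", "maximize", target = 1.29)
  )
}

#' Optimize the reference Petit Suisse formulation
#'
#' Fits the four mechanical/compositional responses of the packaged
#' formulation study (total sugars, firmness, viscosity index, cohesivity),
#' applies the default desirability targets of
#' [petit_suisse_desirability_specs()] and maximizes the composite over an
#' extended search domain (inulin 0-20 g/100 g, xanthan gum 0.3-1.5
#' g/100 g).  The domain deliberately extends beyond the tested design box
#' because the desirable firmness band (3-6 N) lies above every fitted value
#' inside it; the returned optimum is flagged as extrapolated.
#'
#' @param domain named list of search intervals (default as above).
#' @param resolution grid points per axis (default 201).
#' @param refine polish with Nelder-Mead (default `TRUE`).
#' @return A list with `fits` (the four models) and `optimum`
#'   (a `"desirability_optimum"`).
#' @export
petit_suisse_optimization <- function(domain = list(inulin = c(0, 20),
                                                    xanthan = c(0.3, 1.5)),
                                      resolution = 201L, refine = TRUE) {
  design <- petit_suisse_design()
  responses <- c("total_sugars", "firmness", "viscosity_index", "cohesivity")
  fits <- lapply(responses, fit_first_order, design = design)
  names(fits) <- responses
  opt <- optimize_desirability(fits, petit_suisse_desirability_specs(),
                               domain = domain, resolution = resolution,
                               refine = refine)
  list(fits = fits, optimum = opt)
}
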