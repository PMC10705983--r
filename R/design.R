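#' Define a design factor with physical and coded levels
#'
#' A factor in a two-level factorial design is described by its physical low
#' and high settings plus a center setting.  Coded units rescale the factor so
#' that low maps to -1, center to 0 and high to +1; in a balanced design the
#' coded columns (and their pairwise products) are orthogonal, which is what
#' makes factorial contrasts interpretable.
#'
#' @param name factor name, e.g. `"inulin"`.
#' @param low,high physical levels of the low (-1) and high (+1) settings,
#'   in the factor's own units (here g/100 g).  `low` must be `< high`.
#' @param center physical level of the center (0) setting; defaults to the
#'   midpoint `(low + high) / 2` and must lie in `[low, high]`.
#'
#' @return An object of class `"factor_spec"`: a list with elements `name`,
#'   `low`, `high`, `center` and the derived `half_range = (high - low) / 2`.
#' @seealso [encode_level()], [decode_level()], [full_factorial()]
#' @examples
#' inulin <- factor_spec("inulin", low = 6, high = 16)
#' encode_level(inulin, c(6, 11, 16))
#' @export
factor_spec <- function(name, low, high, center = (low + high) / 2) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  for (v in list(low, high, center)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("factor levels must be finite numeric scalars", call. = FALSE)
    }
  }
  if (!(low < high)) stop("'low' must be strictly less than 'high'", call. = FALSE)
  if (center < low || center > high) {
    stop("'center' must lie within [low, high]", call. = FALSE)
  }
  structure(
    list(name = name, low = low, high = high, center = center,
         half_range = (high - low) / 2),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("Factor '%s': low = %g (-1), center = %g (0), high = %g (+1)\n",
              x$name, x$low, x$center, x$high))
  invisible(x)
}

is_factor_spec <- function(x) inherits(x, "factor_spec")

check_factor_list <- function(factors) {
  if (is_factor_spec(factors)) factors <- list(factors)
  if (!is.list(factors) || length(factors) == 0L ||
      !all(vapply(factors, is_factor_spec, logical(1)))) {
    stop("'factors' must be a non-empty list of factor_spec objects",
         call. = FALSE)
  }
  nms <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("factor names must be unique", call. = FALSE)
  names(factors) <- nms
  factors
}

#' Convert between physical and coded factor levels
#'
#' `encode_level()` maps a physical level to coded units,
#' `(physical - center) / half_range`, so that the low, center and high
#' settings map to exactly -1, 0 and +1.  `decode_level()` is the exact
#' inverse.  Levels outside the design region are allowed and yield coded
#' values with `|coded| > 1`.
#'
#' @param spec a [factor_spec()].
#' @param physical,coded numeric vector of levels to convert.
#' @return Numeric vector of the converted levels.
#' @examples
#' xg <- factor_spec("xanthan", 0.5, 0.8)
#' encode_level(xg, 0.65)  # 0
#' decode_level(xg, 2)     # 0.95
#' @export
encode_level <- function(spec, physical) {
  stopifnot(is_factor_spec(spec), is.numeric(physical))
  out <- (physical - spec$center) / spec$half_range
  # anchor the named levels exactly so balanced designs stay orthogonal
  out[physical == spec$low] <- -1
  out[physical == spec$center] <- 0
  out[physical == spec$high] <- 1
  out
}

#' @rdname encode_level
#' @export
decode_level <- function(spec, coded) {
  stopifnot(is_factor_spec(spec), is.numeric(coded))
  spec$center + coded * spec$half_range
}

#' Build a two-level full factorial design with center points
#'
#' Generates the 2^k corner runs followed by `n_center` replicates of the
#' center point.  Corner runs are ordered low/high lexicographically by factor
#' order -- for two factors (-1,-1), (+1,-1), (-1,+1), (+1,+1) -- so that run
#' ids match the conventional trial numbering of such studies.
#'
#' @param factors list of [factor_spec()] objects (or a single spec).
#' @param n_center number of center-point replicates (>= 0).
#' @return A `design_table`: a `data.frame` with a `trial` column and one
#'   physical-level column per factor, carrying the factor specs in
#'   `attr(, "factors")`.  Response columns can be added by name afterwards.
#' @examples
#' des <- full_factorial(list(factor_spec("inulin", 6, 16),
#'                            factor_spec("xanthan", 0.5, 0.8)), n_center = 3)
#' nrow(des)  # 7
#' @export
full_factorial <- function(factors, n_center = 0L) {
  factors <- check_factor_list(factors)
  if (!is.numeric(n_center) || length(n_center) != 1L || n_center < 0 ||
      n_center != round(n_center)) {
    stop("'n_center' must be a non-negative integer", call. = FALSE)
  }
  k <- length(factors)
  # first factor varies fastest: (-1,-1), (+1,-1), (-1,+1), (+1,+1) for k = 2
  corners <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  coded <- rbind(corners, matrix(0, nrow = n_center, ncol = k))
  physical <- vapply(seq_len(k),
                     function(j) decode_level(factors[[j]], coded[, j]),
                     numeric(nrow(coded)))
  physical <- matrix(physical, nrow = nrow(coded))
  colnames(physical) <- names(factors)
  out <- data.frame(trial = seq_len(nrow(coded)), physical,
                    check.names = FALSE)
  design_table(out, factors)
}

#' Construct a design table from a run data frame
#'
#' @param runs `data.frame` with a `trial` column, one physical-level column
#'   per factor, and optionally response columns.
#' @param factors list of [factor_spec()] objects naming columns of `runs`.
#' @param spread optional `data.frame` of replicate spreads (plus/minus
#'   values) matching the response columns; kept as metadata only, never used
#'   in fitting.
#' @return A `design_table` (a classed `data.frame`).
#' @export
design_table <- function(runs, factors, spread = NULL) {
  factors <- check_factor_list(factors)
  stopifnot(is.data.frame(runs))
  if (!"trial" %in% names(runs)) stop("'runs' needs a 'trial' column", call. = FALSE)
  missing_cols <- setdiff(names(factors), names(runs))
  if (length(missing_cols)) {
    stop("design is missing factor columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (nm in names(factors)) {
    if (anyNA(runs[[nm]])) stop("factor column '", nm, "' has missing levels",
                                call. = FALSE)
  }
  structure(as.data.frame(runs), factors = factors, spread = spread,
            class = c("design_table", "data.frame"))
}

design_factors <- function(design) {
  stopifnot(inherits(design, "design_table"))
  attr(design, "factors")
}

#' Response columns of a design table
#'
#' @param design a `design_table`.
#' @return Character vector of column names that are neither `trial` nor a
#'   factor column.
#' @export
design_responses <- function(design) {
  setdiff(names(design), c("trial", names(design_factors(design))))
}

#' Coded model matrix of a design
#'
#' Returns the coded factor levels of each run, one column per factor, using
#' the physical-to-coded map of each [factor_spec()].
#'
#' @param design a `design_table`.
#' @return Numeric matrix, `nrow(design)` rows, one column per factor.
#' @export
coded_matrix <- function(design) {
  factors <- design_factors(design)
  m <- vapply(names(factors),
              function(nm) encode_level(factors[[nm]], design[[nm]]),
              numeric(nrow(design)))
  m <- matrix(m, nrow = nrow(design), dimnames = list(NULL, names(factors)))
  m
}

#' @export
print.design_table <- function(x, ...) {
  factors <- design_factors(x)
  cat(sprintf("Factorial design: %d runs, %d factor(s) [%s], %d response(s)\n",
              nrow(x), length(factors),
              paste(names(factors), collapse = ", "),
              length(design_responses(x))))
  print.data.frame(x, ...)
  invisible(x)
}
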