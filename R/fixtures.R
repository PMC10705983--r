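#' Reference buffalo Petit Suisse formulation dataset
#'
#' The seven-run 2^2 + 3 center point formulation study of buffalo Petit
#' Suisse cheese shipped with the package: inulin (6-16 g/100 g) and xanthan
#' gum (0.5-0.8 g/100 g) as factors, with proximate composition (water, total
#' solids, ash, fat, protein, total sugars) and back-extrusion mechanical
#' responses (firmness, consistency, viscosity index, cohesivity) per run.
#' Values are the replicate means; the replicate spreads are attached as
#' metadata (`attr(, "spread")`) and are never used in fitting.
#'
#' @return A `design_table` with 7 runs, the `inulin` and `xanthan` factor
#'   specs, and ten response columns.
#' @examples
#' des <- petit_suisse_design()
#' fit_first_order(des, "firmness")
#' @export
petit_suisse_design <- function() {
  path <- system.file("extdata", "petit_suisse_design.csv",
                      package = "petitsuisse", mustWork = TRUE)
  spread_path <- system.file("extdata", "petit_suisse_design_spread.csv",
                             package = "petitsuisse", mustWork = TRUE)
  factors <- petit_suisse_factors()
  design <- read_design_csv(path, factors)
  spread <- utils::read.csv(spread_path, check.names = FALSE)
  if (nrow(design) != 7L ||
      !setequal(design_responses(design),
                c("water", "total_solids", "ash", "fat", "protein",
                  "total_sugars", "firmness", "consistency",
                  "viscosity_index", "cohesivity"))) {
    stop("packaged design fixture is corrupted", call. = FALSE)
  }
  attr(design, "spread") <- spread
  design
}

#' Factor specifications of the reference formulation study
#'
#' @return List of two [factor_spec()] objects: inulin 6-16 g/100 g (center
#'   11) and xanthan gum 0.5-0.8 g/100 g (center 0.65).
#' @export
petit_suisse_factors <- function() {
  list(factor_spec("inulin", low = 6, high = 16),
       factor_spec("xanthan", low = 0.5, high = 0.8))
}

#' Reference lactic acid bacteria viability series
#'
#' The 28-day storage series of viable lactic acid bacteria counts (CFU/mL at
#' days 0, 7, 14, 21, 28) for the seven formulation trials, as shipped with
#' the package.
#'
#' @return Named list of seven [viability_series()] objects, `"1"` ... `"7"`.
#' @examples
#' vb <- petit_suisse_viability()
#' survival_percent(vb[["4"]])
#' @export
petit_suisse_viability <- function() {
  path <- system.file("extdata", "petit_suisse_viability.csv",
                      package = "petitsuisse", mustWork = TRUE)
  series <- read_viability_csv(path)
  if (length(series) != 7L ||
      !all(vapply(series, function(s) length(s$days) == 5L, logical(1)))) {
    stop("packaged viability fixture is corrupted", call. = FALSE)
  }
  series
}
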