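model_report <- function(fit) {
  an <- regression_anova(fit)
  list(response = fit$response,
       coefficients_coded = as.list(fit$coef_coded),
       coefficients_physical = as.list(fit$coef_physical),
       anova = an[c("ss_regression", "ss_residual", "ss_total",
                    "df_regression", "df_residual")],
       r_squared = fit$r_squared,
       f_statistic = fit$f_statistic,
       p_value = fit$p_value,
       constant_response = fit$constant_response,
       saturated = fit$saturated,
       residuals = fit$residuals)
}

run_stage <- function(stage, report, keep_going, verbose, expr) {
  if (verbose) message("stage '", stage, "' ...")
  result <- tryCatch(expr, error = function(e) e)
  if (inherits(result, "error")) {
    if (!keep_going) {
      stop("stage '", stage, "' failed: ", conditionMessage(result),
           call. = FALSE)
    }
    report$skipped[[stage]] <- conditionMessage(result)
  }
  list(value = if (!inherits(result, "error")) result, report = report)
}

#' Run the full formulation and shelf-life analysis
#'
#' Orchestrates the pipeline: first-order response fits with regression
#' ANOVA, composite desirability optimization, microbial viability kinetics,
#' syneresis indices, and storage trend summaries.  Every stage is
#' deterministic given its inputs; stages without inputs are recorded as
#' skipped with a reason.
#'
#' @param design a `design_table` or a design CSV path (read with the factor
#'   specs in `factors`); `NULL` skips the fitting and optimization stages.
#' @param viability list of [viability_series()] or a viability CSV path;
#'   `NULL` skips the kinetics stage.
#' @param syneresis `data.frame` with `trial`, `day`, `whey_g`, `cheese_g`
#'   columns or a CSV path; `NULL` skips the syneresis stage.
#' @param storage output of [read_storage_csv()] or a storage CSV path;
#'   `NULL` skips the trend stage.
#' @param packaged_data logical: load the packaged reference formulation
#'   dataset and viability series instead of `design` / `viability`.
#' @param factors factor specs used when `design` is a path.
#' @param responses responses to fit; defaults to every response column when
#'   the design carries the reference responses, restricted to the modelled
#'   ones (`total_sugars`, `firmness`, `consistency`, `viscosity_index`,
#'   `cohesivity`) for the packaged dataset.
#' @param desirability list of [desirability_spec()] (matched to fitted
#'   responses by name) or `NULL` to skip optimization;
#'   `"default"` uses [petit_suisse_desirability_specs()] restricted to the
#'   fitted responses.
#' @param domain optimization search domain (see [optimize_desirability()]);
#'   default for the packaged dataset is inulin 0-20, xanthan 0.3-1.5
#'   g/100 g.
#' @param resolution optimizer grid resolution.
#' @param mu_window growth window for [specific_growth_rate()].
#' @param out_dir if non-`NULL`, write `report.json`, per-model surface
#'   grids and the desirability contour CSV there.
#' @param keep_going log stage failures in the report instead of stopping.
#' @param verbose emit per-stage progress messages.
#' @return Object of class `"analysis_report"`: a list with `models`,
#'   `optimization`, `kinetics`, `syneresis`, `trends`, `skipped` and
#'   `provenance`.
#' @examples
#' \donttest{
#' rep <- run_full_analysis(packaged_data = TRUE, resolution = 61)
#' names(rep$models)
#' }
#' @export
run_full_analysis <- function(design = NULL, viability = NULL,
                              syneresis = NULL, storage = NULL,
                              packaged_data = FALSE,
                              factors = petit_suisse_factors(),
                              responses = NULL,
                              desirability = "default",
                              domain = NULL, resolution = 201L,
                              mu_window = c(0, 14),
                              out_dir = NULL, keep_going = FALSE,
                              verbose = FALSE) {
  if (packaged_data) {
    design <- petit_suisse_design()
    viability <- petit_suisse_viability()
    if (is.null(domain)) domain <- list(inulin = c(0, 20), xanthan = c(0.3, 1.5))
    if (is.null(responses)) {
      responses <- c("total_sugars", "firmness", "consistency",
                     "viscosity_index", "cohesivity")
    }
  }
  if (is.character(design)) design <- read_design_csv(design, factors)
  if (is.character(viability)) viability <- read_viability_csv(viability)
  if (is.character(syneresis)) syneresis <- read_syneresis_csv(syneresis)
  if (is.character(storage)) storage <- read_storage_csv(storage)

  report <- list(models = list(), optimization = NULL, kinetics = NULL,
                 syneresis = NULL, trends = NULL, skipped = list(),
                 provenance = list(
                   package = "petitsuisse",
                   version = as.character(utils::packageVersion("petitsuisse")),
                   mu_window = mu_window, resolution = resolution))
  fits <- list()

  if (is.null(design)) {
    report$skipped[["fit"]] <- "no design table supplied"
  } else {
    if (is.null(responses)) responses <- design_responses(design)
    if (length(responses) == 0L) {
      report$skipped[["fit"]] <- "empty response list"
    } else {
      st <- run_stage("fit", report, keep_going, verbose, {
        fits <- lapply(responses, fit_first_order, design = design)
        names(fits) <- responses
        fits
      })
      report <- st$report
      if (!is.null(st$value)) {
        fits <- st$value
        report$models <- lapply(fits, model_report)
      }
    }
  }

  if (length(fits) == 0L || is.null(desirability)) {
    report$skipped[["optimize"]] <-
      if (length(fits) == 0L) "no fitted models" else "no desirability specs"
  } else {
    st <- run_stage("optimize", report, keep_going, verbose, {
      specs <- desirability
      if (identical(specs, "default")) {
        specs <- petit_suisse_desirability_specs()
      }
      spec_names <- vapply(specs, `[[`, character(1), "response")
      keep <- spec_names %in% names(fits)
      if (!any(keep)) stop("no desirability spec matches a fitted response")
      opt <- optimize_desirability(fits[spec_names[keep]], specs[keep],
                                   domain = domain, resolution = resolution)
      contour <- desirability_contour(fits[spec_names[keep]], specs[keep],
                                      domain = domain,
                                      resolution = min(101L, resolution))
      list(optimum = opt, contour = contour)
    })
    report <- st$report
    if (!is.null(st$value)) {
      opt <- st$value$optimum
      report$optimization <- list(
        optimum = as.list(opt$optimum), coded = as.list(opt$coded),
        D = opt$D, d_individual = as.list(opt$d_individual),
        predicted = as.list(opt$predicted),
        extrapolated = opt$extrapolated, degenerate = opt$degenerate)
      attr(report, "contour") <- st$value$contour
    }
  }

  if (is.null(viability)) {
    report$skipped[["kinetics"]] <- "no viability series supplied"
  } else {
    st <- run_stage("kinetics", report, keep_going, verbose,
                    kinetics_summary(viability, window = mu_window))
    report <- st$report
    report$kinetics <- st$value
  }

  if (is.null(syneresis)) {
    report$skipped[["syneresis"]] <- "no syneresis measurements supplied"
  } else {
    st <- run_stage("syneresis", report, keep_going, verbose, {
      if (!"syneresis_percent" %in% names(syneresis)) {
        syneresis$syneresis_percent <-
          syneresis_percent(syneresis$whey_g, syneresis$cheese_g)
      }
      syneresis
    })
    report <- st$report
    report$syneresis <- st$value
  }

  if (is.null(storage)) {
    report$skipped[["trends"]] <- "no storage series supplied"
  } else {
    st <- run_stage("trends", report, keep_going, verbose, {
      lapply(storage, function(tr) lapply(tr, storage_trend))
    })
    report <- st$report
    report$trends <- st$value
  }

  class(report) <- "analysis_report"
  if (!is.null(out_dir)) write_analysis_report(report, out_dir, fits)
  report
}

#' Write an analysis report to disk
#'
#' Writes `report.json` (full-precision JSON), one `surface_<response>.csv`
#' prediction grid per fitted model, and `desirability_contour.csv` when the
#' optimization stage ran.
#'
#' @param report an `"analysis_report"`.
#' @param out_dir output directory, created if needed.
#' @param fits optional list of the fitted models (for surface grids).
#' @return `out_dir`, invisibly.
#' @export
write_analysis_report <- function(report, out_dir, fits = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json <- unclass(report)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  for (nm in names(fits)) {
    grid <- surface_grid(fits[[nm]])
    utils::write.csv(grid, file.path(out_dir, paste0("surface_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  contour <- attr(report, "contour")
  if (!is.null(contour)) {
    utils::write.csv(contour, file.path(out_dir, "desirability_contour.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Formulation / shelf-life analysis report\n")
  cat(sprintf("  fitted models: %s\n",
              if (length(x$models)) paste(names(x$models), collapse = ", ")
              else "(none)"))
  if (!is.null(x$optimization)) {
    cat(sprintf("  optimum: %s, D = %.4f\n",
                paste(names(x$optimization$optimum),
                      signif(unlist(x$optimization$optimum), 4),
                      sep = " = ", collapse = ", "),
                x$optimization$D))
  }
  if (!is.null(x$kinetics)) {
    cat(sprintf("  kinetics: %d trials\n", nrow(x$kinetics)))
  }
  if (length(x$skipped)) {
    cat("  skipped:", paste(names(x$skipped), unlist(x$skipped),
                            sep = ": ", collapse = "; "), "\n")
  }
  invisible(x)
}
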