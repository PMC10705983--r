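# shared CSV dialect: comma separator, dot decimal, UTF-8, header row

read_csv_strict <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(dat))
  if (length(missing_cols)) {
    stop("'", basename(path), "' is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dat
}

# coerce a column to numeric; a decimal-comma file is reported as a dialect
# error, not silently misparsed
check_numeric_col <- function(dat, col, path) {
  x <- dat[[col]]
  if (is.character(x)) {
    if (any(grepl(",", x, fixed = TRUE))) {
      stop("column '", col, "' of '", basename(path),
           "' uses a decimal comma; this reader expects the dot-decimal ",
           "dialect", call. = FALSE)
    }
    bad <- which(is.na(suppressWarnings(as.numeric(x))))
    if (length(bad)) {
      stop("line ", bad[1] + 1L, ", column '", col, "' of '", basename(path),
           "': not a number", call. = FALSE)
    }
    x <- as.numeric(x)
  }
  if (!is.numeric(x)) {
    stop("column '", col, "' of '", basename(path), "' must be numeric",
         call. = FALSE)
  }
  na <- which(is.na(x))
  if (length(na)) {
    stop("line ", na[1] + 1L, ", column '", col, "' of '", basename(path),
         "': missing value", call. = FALSE)
  }
  x
}

# the on-disk design dialect suffixes factor columns with their units
factor_column <- function(name, columns) {
  hit <- c(name, paste0(name, "_g_per_100g"))
  hit <- hit[hit %in% columns]
  if (length(hit) == 0L) {
    stop("no design column found for factor '", name, "'", call. = FALSE)
  }
  hit[1]
}

#' Read a factorial design table from CSV
#'
#' Expects the dialect `trial,<factor>...,<response>...` with comma
#' separator, dot decimal and a header row.  Factor columns may carry a
#' `_g_per_100g` unit suffix.
#'
#' @param path CSV file path.
#' @param factors list of [factor_spec()] objects describing the design
#'   factors.
#' @return A `design_table`.
#' @export
read_design_csv <- function(path, factors) {
  factors <- check_factor_list(factors)
  dat <- read_csv_strict(path, "trial")
  cols <- vapply(names(factors), factor_column, character(1),
                 columns = names(dat))
  for (i in seq_along(cols)) {
    dat[[cols[i]]] <- check_numeric_col(dat, cols[i], path)
    names(dat)[names(dat) == cols[i]] <- names(factors)[i]
  }
  for (col in setdiff(names(dat), c("trial", names(factors)))) {
    dat[[col]] <- check_numeric_col(dat, col, path)
  }
  design_table(dat, factors)
}

#' Write a design table to CSV
#'
#' Inverse of [read_design_csv()]: factor columns are written with the
#' `_g_per_100g` unit suffix, numeric values at full precision.
#'
#' @param design a `design_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  stopifnot(inherits(design, "design_table"))
  out <- as.data.frame(design)
  for (nm in names(design_factors(design))) {
    names(out)[names(out) == nm] <- paste0(nm, "_g_per_100g")
  }
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}

#' Read viability series from CSV
#'
#' Expects columns `trial,day,cfu_per_ml`.  Rows are grouped by trial and
#' ordered by day; validation failures are reported with their file line
#' number.
#'
#' @param path CSV file path.
#' @return Named list of [viability_series()], one per trial.
#' @export
read_viability_csv <- function(path) {
  dat <- read_csv_strict(path, c("trial", "day", "cfu_per_ml"))
  dat$day <- check_numeric_col(dat, "day", path)
  dat$cfu_per_ml <- check_numeric_col(dat, "cfu_per_ml", path)
  bad <- which(dat$cfu_per_ml <= 0)
  if (length(bad)) {
    stop("line ", bad[1] + 1L, ", column 'cfu_per_ml' of '", basename(path),
         "': viable counts must be positive", call. = FALSE)
  }
  trials <- unique(as.character(dat$trial))
  series <- lapply(trials, function(id) {
    rows <- dat[as.character(dat$trial) == id, ]
    rows <- rows[order(rows$day), ]
    viability_series(id, rows$day, rows$cfu_per_ml)
  })
  stats::setNames(series, trials)
}

#' Write viability series to CSV
#'
#' @param series_list list of [viability_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_viability_csv <- function(series_list, path) {
  rows <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(trial = s$trial, day = s$days, cfu_per_ml = s$cfu)
  }))
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}

#' Read syneresis weight pairs from CSV
#'
#' Expects columns `trial,day,whey_g,cheese_g`.
#'
#' @param path CSV file path.
#' @return `data.frame` with a computed `syneresis_percent` column.
#' @export
read_syneresis_csv <- function(path) {
  dat <- read_csv_strict(path, c("trial", "day", "whey_g", "cheese_g"))
  for (col in c("day", "whey_g", "cheese_g")) {
    dat[[col]] <- check_numeric_col(dat, col, path)
  }
  dat$syneresis_percent <- syneresis_percent(dat$whey_g, dat$cheese_g)
  dat
}

#' Read storage pH / titratable acidity series from CSV
#'
#' Expects columns `trial,day,ph,tta_percent`.
#'
#' @param path CSV file path.
#' @return Named list per trial, each with `ph` and `tta`
#'   [storage_series()] elements.
#' @export
read_storage_csv <- function(path) {
  dat <- read_csv_strict(path, c("trial", "day", "ph", "tta_percent"))
  for (col in c("day", "ph", "tta_percent")) {
    dat[[col]] <- check_numeric_col(dat, col, path)
  }
  trials <- unique(as.character(dat$trial))
  out <- lapply(trials, function(id) {
    rows <- dat[as.character(dat$trial) == id, ]
    rows <- rows[order(rows$day), ]
    list(ph = storage_series(id, rows$day, rows$ph, "pH"),
         tta = storage_series(id, rows$day, rows$tta_percent, "tta_percent"))
  })
  stats::setNames(out, trials)
}
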