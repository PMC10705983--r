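#' Fit the first-order model with interaction to a design response
#'
#' Fits `y = b0 + b1*z1 + b2*z2 + b12*z1*z2` by least squares on the coded
#' factor levels `z_i` of a two-factor design, then expands the coefficients
#' algebraically to physical units (see [coded_to_physical()]).  Fitting in
#' coded space keeps the normal equations orthogonal for balanced designs --
#' there `b0` is the grand mean and `b1`, `b2`, `b12` are the factorial
#' contrasts divided by 4 -- and the physical-unit form then reproduces
#' exactly the coefficients a direct physical-unit fit would give.
#'
#' The regression ANOVA decomposition (SSR, SSE, SST with
#' `SST = SSR + SSE`), `R^2 = 1 - SSE/SST`, and the overall regression F test
#' (`F = (SSR/df_reg) / (SSE/df_res)` against the F distribution) are
#' populated on the returned object.  A response that is identical in every
#' run has `SST = 0`; its `R^2` is reported as 0 with `constant_response =
#' TRUE`.  A model that interpolates the data exactly (`SSE = 0`) is flagged
#' `saturated = TRUE` and its p-value reported as `NA`.
#'
#' @param design a `design_table` with exactly two factors, at least 5 runs
#'   including at least one center replicate.
#' @param response name of the response column to fit.
#' @return An object of class `"first_order_fit"`: a list with
#'   `coef_coded` (`b0`, `b1`, `b2`, `b12`), `coef_physical` (intercept,
#'   per-factor slopes, interaction), `sse`, `ssr`, `sst`, `r_squared`,
#'   `f_statistic`, `p_value`, `df_regression`, `df_residual`, `fitted`,
#'   `residuals`, the factor specs and flags.
#' @seealso [regression_anova()], [predict.first_order_fit()],
#'   [surface_grid()]
#' @examples
#' fit <- fit_first_order(petit_suisse_design(), "firmness")
#' coef(fit)                    # physical-unit coefficients
#' regression_anova(fit)$p_value
#' @export
fit_first_order <- function(design, response) {
  factors <- design_factors(design)
  if (length(factors) != 2L) {
    stop("fit_first_order() requires a two-factor design", call. = FALSE)
  }
  if (!response %in% design_responses(design)) {
    stop("response '", response, "' not found in design", call. = FALSE)
  }
  y <- design[[response]]
  if (anyNA(y)) stop("response '", response, "' has missing cells", call. = FALSE)
  z <- coded_matrix(design)
  n <- nrow(z)
  if (n < 5L) stop("need at least 5 runs to fit the 4-parameter model",
                   call. = FALSE)
  if (!any(z[, 1] == 0 & z[, 2] == 0)) {
    stop("design must contain at least one center replicate", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, z, interaction = z[, 1] * z[, 2])
  if (qr(X)$rank < 4L) {
    stop("singular design: coded model matrix is rank-deficient",
         call. = FALSE)
  }
  ls <- stats::lm.fit(X, y)
  b <- ls$coefficients
  names(b) <- c("b0", "b1", "b2", "b12")
  fitted <- drop(X %*% b)
  res <- y - fitted
  sst <- sum((y - mean(y))^2)
  sse <- sum(res^2)
  ssr <- sst - sse
  df_reg <- 3L
  df_res <- n - 4L
  constant <- sst < .Machine$double.eps * max(1, mean(y)^2) * n
  saturated <- !constant && sse <= 1e-12 * sst
  r2 <- if (constant) 0 else 1 - sse / sst
  f_stat <- if (constant || saturated) NA_real_ else (ssr / df_reg) / (sse / df_res)
  p_val <- if (is.na(f_stat)) NA_real_ else
    stats::pf(f_stat, df_reg, df_res, lower.tail = FALSE)
  structure(
    list(response = response,
         factors = factors,
         coef_coded = b,
         coef_physical = coded_to_physical(b, factors),
         fitted = fitted, residuals = res,
         sse = sse, ssr = ssr, sst = sst,
         r_squared = r2,
         f_statistic = f_stat, p_value = p_val,
         df_regression = df_reg, df_residual = df_res,
         constant_response = constant, saturated = saturated,
         n_runs = n),
    class = "first_order_fit"
  )
}

#' Expand coded-unit coefficients to physical units
#'
#' Substitutes the affine coding maps `z_i = (u_i - center_i) / half_range_i`
#' into the coded model and collects terms, giving the model in the form
#' `y = B0 + B1*u1 + B2*u2 + B3*u1*u2` with `u_i` in physical units.
#' Predictions are identical under both forms.
#'
#' @param coef_coded named numeric vector `(b0, b1, b2, b12)`.
#' @param factors list of the two [factor_spec()] objects the coded units
#'   refer to, in model order.
#' @return Named numeric vector: `intercept`, one slope per factor name, and
#'   `<f1>:<f2>` for the interaction.
#' @export
coded_to_physical <- function(coef_coded, factors) {
  factors <- check_factor_list(factors)
  if (length(factors) != 2L) {
    stop("coded_to_physical() expects exactly two factors", call. = FALSE)
  }
  stopifnot(is.numeric(coef_coded), length(coef_coded) == 4L)
  b <- unname(coef_coded)
  c1 <- factors[[1]]$center; h1 <- factors[[1]]$half_range
  c2 <- factors[[2]]$center; h2 <- factors[[2]]$half_range
  B3 <- b[4] / (h1 * h2)
  B1 <- b[2] / h1 - B3 * c2
  B2 <- b[3] / h2 - B3 * c1
  B0 <- b[1] - b[2] * c1 / h1 - b[3] * c2 / h2 + B3 * c1 * c2
  stats::setNames(c(B0, B1, B2, B3),
                  c("intercept", names(factors),
                    paste(names(factors), collapse = ":")))
}

#' @export
coef.first_order_fit <- function(object, space = c("physical", "coded"), ...) {
  switch(match.arg(space),
         physical = object$coef_physical,
         coded = object$coef_coded)
}

#' Regression ANOVA of a first-order fit
#'
#' @param fit a [fit_first_order()] object.
#' @return List with `ss_regression`, `ss_residual`, `ss_total`,
#'   `df_regression`, `df_residual`, `f_statistic`, `p_value`, and logical
#'   flags `constant_response` / `saturated` (when either is `TRUE` the F
#'   statistic is not a number and `p_value` is `NA`).
#' @export
regression_anova <- function(fit) {
  stopifnot(inherits(fit, "first_order_fit"))
  list(ss_regression = fit$ssr, ss_residual = fit$sse, ss_total = fit$sst,
       df_regression = fit$df_regression, df_residual = fit$df_residual,
       f_statistic = fit$f_statistic, p_value = fit$p_value,
       constant_response = fit$constant_response, saturated = fit$saturated)
}

#' Predict a fitted response at physical factor levels
#'
#' Evaluates `B0 + B1*u1 + B2*u2 + B3*u1*u2` at the given physical point(s).
#' Extrapolation beyond the design box is permitted; the result carries an
#' `"extrapolated"` attribute flagging points outside it.
#'
#' @param object a `first_order_fit`.
#' @param newdata `data.frame` (or named list) with one column per factor, in
#'   physical units.  Defaults to the fitted design points.
#' @param ... unused.
#' @return Numeric vector of predictions with attribute `"extrapolated"`.
#' @export
predict.first_order_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    out <- object$fitted
    attr(out, "extrapolated") <- rep(FALSE, length(out))
    return(out)
  }
  nms <- names(object$factors)
  newdata <- as.data.frame(newdata)
  if (!all(nms %in% names(newdata))) {
    stop("newdata must contain columns: ", paste(nms, collapse = ", "),
         call. = FALSE)
  }
  u1 <- newdata[[nms[1]]]; u2 <- newdata[[nms[2]]]
  B <- unname(object$coef_physical)
  out <- B[1] + B[2] * u1 + B[3] * u2 + B[4] * u1 * u2
  f1 <- object$factors[[1]]; f2 <- object$factors[[2]]
  attr(out, "extrapolated") <-
    u1 < f1$low | u1 > f1$high | u2 < f2$low | u2 > f2$high
  out
}

#' @export
print.first_order_fit <- function(x, ...) {
  cat(sprintf("First-order model with interaction for '%s' (%d runs)\n",
              x$response, x$n_runs))
  cat("Physical-unit coefficients:\n")
  print(signif(x$coef_physical, 6))
  if (x$constant_response) {
    cat("Constant response: R^2 reported as 0 by convention\n")
  } else if (x$saturated) {
    cat(sprintf("R^2 = %.4f; exact fit (SSE = 0), no F test\n", x$r_squared))
  } else {
    cat(sprintf("R^2 = %.4f, F(%d,%d) = %.4f, p = %.6f\n", x$r_squared,
                x$df_regression, x$df_residual, x$f_statistic, x$p_value))
  }
  invisible(x)
}

#' Rectangular prediction grid over the factor space
#'
#' @param fit a `first_order_fit`.
#' @param ranges named list of length-2 physical intervals per factor;
#'   defaults to the design box (low to high of each factor).
#' @param resolution integer number of grid points per axis (length 1 or 2,
#'   each >= 2).
#' @return `data.frame` in row-major order (first factor varying fastest)
#'   with one column per factor and a `predicted` column; the axis vectors
#'   are attached as attribute `"axes"`.
#' @export
surface_grid <- function(fit, ranges = NULL, resolution = 21L) {
  stopifnot(inherits(fit, "first_order_fit"))
  nms <- names(fit$factors)
  if (is.null(ranges)) {
    ranges <- lapply(fit$factors, function(f) c(f$low, f$high))
  }
  if (!all(nms %in% names(ranges))) {
    stop("ranges must be named after the factors", call. = FALSE)
  }
  resolution <- rep_len(as.integer(resolution), 2L)
  if (any(resolution < 2L)) stop("resolution must be >= 2 per axis", call. = FALSE)
  axes <- lapply(seq_along(nms), function(j) {
    r <- ranges[[nms[j]]]
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2]) {
      stop("range for '", nms[j], "' must be a finite interval", call. = FALSE)
    }
    seq(r[1], r[2], length.out = resolution[j])
  })
  names(axes) <- nms
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  grid$predicted <- as.numeric(predict(fit, grid))
  attr(grid, "axes") <- axes
  grid
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Standard one-way analysis of variance across replicate groups followed by
#' Tukey's honestly-significant-difference test (studentized range; the
#' Tukey-Kramer adjustment applies automatically for unequal group sizes), as
#' used to compare formulation treatments at a 5% significance level.
#'
#' @param groups named list of numeric replicate vectors, each of length
#'   >= 2.
#' @param alpha significance level for the pairwise decisions (default 0.05).
#' @return Object of class `"group_comparison"`: list with `means`,
#'   `f_statistic`, `p_value`, `pairs` (a `data.frame` of pairwise
#'   differences, adjusted p-values and significance flags) and a
#'   `zero_variance` flag.  When every observation is identical the F test is
#'   undefined: `f_statistic` is `NA` and no pair is significant.
#' @examples
#' one_way_anova_tukey(list(a = c(1, 1.1, 0.9), b = c(5, 5.2, 4.9)))
#' @export
one_way_anova_tukey <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 replicates", call. = FALSE)
  }
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes), levels = names(groups))
  )
  means <- tapply(dat$value, dat$group, mean)
  labels <- names(groups)
  combos <- utils::combn(labels, 2L)
  if (stats::var(dat$value) == 0) {
    pairs <- data.frame(group1 = combos[1, ], group2 = combos[2, ],
                        diff = 0, p_adj = NA_real_, significant = FALSE)
    return(structure(list(means = means, f_statistic = NA_real_,
                          p_value = NA_real_, alpha = alpha, pairs = pairs,
                          zero_variance = TRUE),
                     class = "group_comparison"))
  }
  fit <- stats::aov(value ~ group, data = dat)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  pairs <- data.frame(
    group1 = sub("-.*$", "", rownames(tk)),
    group2 = sub("^[^-]*-", "", rownames(tk)),
    diff = tk[, "diff"],
    p_adj = tk[, "p adj"],
    significant = is.finite(tk[, "p adj"]) & tk[, "p adj"] < alpha,
    row.names = NULL
  )
  # TukeyHSD labels pairs "b-a"; report as (a, b) with the same difference
  pairs[, c("group1", "group2")] <- pairs[, c("group2", "group1")]
  structure(list(means = means,
                 f_statistic = an[["F value"]][1],
                 p_value = an[["Pr(>F)"]][1],
                 alpha = alpha, pairs = pairs, zero_variance = FALSE),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA across %d groups", length(x$means)))
  if (x$zero_variance) {
    cat(": all observations identical, F undefined\n")
  } else {
    cat(sprintf(": F = %.4f, p = %.6g (Tukey HSD at alpha = %g)\n",
                x$f_statistic, x$p_value, x$alpha))
  }
  print(x$pairs)
  invisible(x)
}
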