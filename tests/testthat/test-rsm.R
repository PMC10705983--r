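test_that("firmness fit reproduces the orthogonal-contrast coefficients", {
  fit <- fit_first_order(petit_suisse_design(), "firmness")
  # frozen from the contrast formulas b0 = grand mean, b1 = (-y1+y2-y3+y4)/4,
  # b2 = (-y1-y2+y3+y4)/4, b12 = (y1-y2-y3+y4)/4 on the Table values
  expect_equal(unname(fit$coef_coded),
               c(1.2042857142857144, 0.41, 0.345, 0.095),
               tolerance = 1e-12)
})

test_that("fits match the generic least-squares solution (oracle)", {
  set.seed(11)
  for (i in 1:25) {
    des <- random_balanced_design()
    fit <- fit_first_order(des, "y")
    expect_equal(unname(fit$coef_coded), unname(contrast_fit_oracle(des, "y")),
                 tolerance = 1e-10)
    # independent route: lm() on the coded columns
    z <- coded_matrix(des)
    ref <- lm(des$y ~ z[, 1] * z[, 2])
    expect_equal(unname(fit$coef_coded), unname(coef(ref)), tolerance = 1e-10)
  }
})

test_that("physical-unit expansion is exact and prediction-equivalent", {
  des <- petit_suisse_design()
  firm <- fit_first_order(des, "firmness")
  coh <- fit_first_order(des, "cohesivity")
  expect_equal(unname(coef(firm)),
               c(-0.287, -0.0003, 0.9067, 0.1267), tolerance = 5e-4)
  expect_equal(unname(coef(coh)),
               c(0.4285, -0.096, -0.78, 0.23), tolerance = 1e-10)

  # identity coding leaves coefficients unchanged
  id <- list(factor_spec("a", -1, 1), factor_spec("b", -1, 1))
  b <- c(1.3, -0.4, 2.2, 0.7)
  expect_equal(unname(coded_to_physical(b, id)), b, tolerance = 1e-12)

  # coded and physical forms predict identically at random points
  set.seed(3)
  for (i in 1:10) {
    des <- random_balanced_design()
    fit <- fit_first_order(des, "y")
    pts <- data.frame(a = runif(8, -5, 30), b = runif(8, 0, 3))
    B <- unname(fit$coef_physical)
    phys <- B[1] + B[2] * pts$a + B[3] * pts$b + B[4] * pts$a * pts$b
    f <- design_factors(des)
    z1 <- encode_level(f$a, pts$a); z2 <- encode_level(f$b, pts$b)
    bb <- unname(fit$coef_coded)
    coded <- bb[1] + bb[2] * z1 + bb[3] * z2 + bb[4] * z1 * z2
    expect_equal(phys, coded, tolerance = 1e-9)
    expect_equal(as.numeric(predict(fit, pts)), phys, tolerance = 1e-9)
  }
})

test_that("ANOVA decomposition is consistent and recoding-invariant", {
  set.seed(19)
  for (i in 1:15) {
    des <- random_balanced_design()
    fit <- fit_first_order(des, "y")
    expect_equal(fit$ssr + fit$sse, fit$sst, tolerance = 1e-9 * fit$sst)
    expect_gte(fit$r_squared, 0)
    expect_lte(fit$r_squared, 1)
    expect_equal(fit$df_regression + fit$df_residual, fit$n_runs - 1)

    # affine recoding of the factor units leaves R^2 unchanged
    f <- design_factors(des)
    f2 <- list(factor_spec("a", f$a$low * 10 + 3, f$a$high * 10 + 3,
                           f$a$center * 10 + 3),
               factor_spec("b", f$b$low, f$b$high, f$b$center))
    des2 <- des
    des2$a <- des$a * 10 + 3
    des2 <- design_table(as.data.frame(des2), f2)
    fit2 <- fit_first_order(des2, "y")
    expect_equal(fit2$r_squared, fit$r_squared, tolerance = 1e-9)
    expect_equal(as.numeric(predict(fit2, data.frame(a = des2$a, b = des2$b))),
                 as.numeric(predict(fit, data.frame(a = des$a, b = des$b))),
                 tolerance = 1e-9)
  }
})

test_that("regression F test matches the F distribution", {
  fit <- fit_first_order(petit_suisse_design(), "firmness")
  an <- regression_anova(fit)
  expect_equal(an$f_statistic, (an$ss_regression / 3) / (an$ss_residual / 3))
  expect_equal(an$p_value,
               pf(an$f_statistic, 3, 3, lower.tail = FALSE))
  # F = 1 on (3, 3) df sits at the median by symmetry
  expect_equal(pf(1, 3, 3, lower.tail = FALSE), 0.5, tolerance = 1e-12)
})

test_that("degenerate responses are flagged, not mangled", {
  des <- full_factorial(list(inulin_spec(), xanthan_spec()), 3)
  des$flat <- rep(5, 7)
  fit <- fit_first_order(des, "flat")
  expect_true(fit$constant_response)
  expect_equal(fit$r_squared, 0)
  expect_equal(unname(fit$coef_coded[2:4]), c(0, 0, 0), tolerance = 1e-12)
  expect_true(is.na(fit$p_value))

  # exact interpolation: center replicates identical, corners on the model
  des$exact <- c(1, 2, 3, 4, 2.5, 2.5, 2.5)
  fit2 <- fit_first_order(des, "exact")
  expect_true(fit2$saturated)
  expect_true(is.na(fit2$p_value))
})

test_that("fit validates its inputs", {
  des <- full_factorial(list(inulin_spec(), xanthan_spec()), 3)
  des$y <- c(1:6, NA)
  expect_error(fit_first_order(des, "y"), "missing")
  expect_error(fit_first_order(des, "nope"), "not found")
  corners_only <- full_factorial(list(inulin_spec(), xanthan_spec()), 0)
  corners_only$y <- 1:4
  expect_error(fit_first_order(corners_only, "y"), "5 runs")
})

test_that("pure center replicate noise cannot push R^2 above the noiseless fit", {
  set.seed(23)
  for (i in 1:10) {
    truth <- rnorm(4)
    des <- simulate_design_responses(coef_physical = truth, sigma = 0,
                                     n_center = 3, seed = i)
    base <- fit_first_order(des, "response")$r_squared
    noisy <- des
    center <- coded_matrix(des)[, 1] == 0 & coded_matrix(des)[, 2] == 0
    noisy$response[center] <- noisy$response[center] + rnorm(sum(center), 0, 0.3)
    expect_lte(fit_first_order(noisy, "response")$r_squared, base + 1e-12)
  }
})

test_that("surface grids evaluate the model on a deterministic lattice", {
  fit <- fit_first_order(petit_suisse_design(), "firmness")
  g <- surface_grid(fit, resolution = 2)
  expect_equal(nrow(g), 4)
  # the 2x2 grid over the design box is exactly the four corner predictions
  expect_equal(g$predicted,
               as.numeric(predict(fit, g[, c("inulin", "xanthan")])))
  expect_equal(sort(g$predicted), sort(fit$fitted[1:4]), tolerance = 1e-9)

  g3 <- surface_grid(fit, resolution = 3)
  expect_equal(nrow(g3), 9)
  center_row <- g3[g3$inulin == 11 & g3$xanthan == 0.65, ]
  expect_equal(center_row$predicted, unname(fit$coef_coded["b0"]),
               tolerance = 1e-9)
  expect_error(surface_grid(fit, ranges = list(inulin = c(1, 1),
                                               xanthan = c(0, 1))),
               "interval")
})

test_that("Tukey comparisons separate distinct groups and respect degeneracy", {
  flat <- one_way_anova_tukey(list(a = c(3, 3, 3), b = c(3, 3, 3)))
  expect_true(flat$zero_variance)
  expect_false(any(flat$pairs$significant))
  expect_true(is.na(flat$f_statistic))

  set.seed(5)
  groups <- list(a = rnorm(3, 0, 0.01), b = rnorm(3, 10, 0.01))
  sep <- one_way_anova_tukey(groups)
  expect_true(all(sep$pairs$significant))
  expect_lt(sep$p_value, 1e-6)
  # cross-check the overall F against aov on the same data
  dat <- data.frame(v = unlist(groups), g = rep(c("a", "b"), each = 3))
  expect_equal(sep$f_statistic,
               summary(aov(v ~ g, dat))[[1]][["F value"]][1])

  expect_error(one_way_anova_tukey(list(a = 1, b = c(1, 2))), "2 replicates")
})

test_that("Tukey type-I error under the null is near the nominal level", {
  set.seed(31)
  n_sim <- 1000
  any_sig <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    g <- list(a = rnorm(4), b = rnorm(4), c = rnorm(4))
    any_sig[i] <- any(one_way_anova_tukey(g)$pairs$significant)
  }
  rate <- mean(any_sig)
  # familywise rate should be ~5%; 1000 reps give SE ~ 0.7%
  expect_gt(rate, 0.025)
  expect_lt(rate, 0.075)
})
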