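test_that("desirability ramps hit their documented boundary values", {
  mn <- desirability_spec("y", "minimize", high = 10, target = 2)
  expect_equal(desirability_value(mn, 2), 1)    # at the goal
  expect_equal(desirability_value(mn, 10), 0)   # at the worst bound
  expect_equal(desirability_value(mn, 6), 0.5)  # linear ramp midpoint

  mx <- desirability_spec("y", "maximize", low = 0, target = 4)
  expect_equal(desirability_value(mx, c(-1, 0, 2, 4, 9)),
               c(0, 0, 0.5, 1, 1))

  tg <- desirability_spec("y", "target", low = 0, high = 10, target = 5)
  expect_equal(desirability_value(tg, c(0, 2.5, 5, 7.5, 10)),
               c(0, 0.5, 1, 0.5, 0))

  rg <- desirability_spec("y", "range", low = 0, high = 10, target = c(4, 6))
  expect_equal(desirability_value(rg, c(2, 4, 5, 6, 8)),
               c(0.5, 1, 1, 1, 0.5))

  # shape exponents bend the ramp
  sq <- desirability_spec("y", "maximize", low = 0, target = 4, s = 2)
  expect_equal(desirability_value(sq, 2), 0.25)
})

test_that("ramps are monotone or unimodal as their kind requires", {
  y <- seq(-2, 12, length.out = 200)
  mx <- desirability_value(
    desirability_spec("y", "maximize", low = 0, target = 10, s = 2), y)
  expect_true(all(diff(mx) >= -1e-12))
  mn <- desirability_value(
    desirability_spec("y", "minimize", high = 10, target = 0, s = 0.5), y)
  expect_true(all(diff(mn) <= 1e-12))
  for (sp in list(
    desirability_spec("y", "target", low = 0, high = 10, target = 3, s = 2, t = 0.5),
    desirability_spec("y", "range", low = 0, high = 10, target = c(3, 7)))) {
    d <- desirability_value(sp, y)
    s <- sign(diff(d))
    runs <- rle(s[s != 0])$values
    expect_lte(length(runs), 2)          # rises then falls, once
    if (length(runs) == 2) expect_equal(runs, c(1, -1))
  }
})

test_that("composite desirability is a weighted geometric mean", {
  expect_equal(composite_desirability(c(1, 1, 1, 1)), 1)
  expect_equal(composite_desirability(c(0.8, 0, 0.9)), 0)
  expect_equal(composite_desirability(c(0.25, 1)), 0.5)
  d <- c(0.3, 0.6, 0.9)
  expect_equal(composite_desirability(d, c(1, 2, 3)),
               prod(d^c(1, 2, 3))^(1 / 6))
  # scale-free in the weights
  expect_equal(composite_desirability(d, c(1, 2, 3)),
               composite_desirability(d, c(10, 20, 30)))
  # bounded by the extremes; raising one d never lowers D
  expect_gte(composite_desirability(d), min(d))
  expect_lte(composite_desirability(d), max(d))
  expect_gte(composite_desirability(c(0.5, 0.6, 0.9)),
             composite_desirability(c(0.3, 0.6, 0.9)))
  expect_error(composite_desirability(numeric(0)), "at least one")
  expect_error(composite_desirability(c(0.5, 1.2)), "0, 1")
})

test_that("grid optimization equals brute-force evaluation (oracle)", {
  des <- petit_suisse_design()
  responses <- c("total_sugars", "firmness", "viscosity_index", "cohesivity")
  fits <- lapply(responses, fit_first_order, design = des)
  domain <- list(inulin = c(0, 20), xanthan = c(0.3, 1.5))
  specs <- petit_suisse_desirability_specs()
  opt <- optimize_desirability(fits, specs, domain = domain,
                               resolution = 21, refine = FALSE)

  # independent brute force with plain arithmetic over the same 21x21 grid
  grid <- expand.grid(inulin = seq(0, 20, length.out = 21),
                      xanthan = seq(0.3, 1.5, length.out = 21))
  preds <- sapply(fits, function(f) as.numeric(predict(f, grid)))
  corners <- expand.grid(inulin = c(0, 20), xanthan = c(0.3, 1.5))
  rng <- sapply(fits, function(f) range(predict(f, corners)))
  ramp <- function(x) pmin(1, pmax(0, x))
  d <- cbind(
    ramp((rng[2, 1] - preds[, 1]) / (rng[2, 1] - 10)),              # sugars <= 10
    ifelse(preds[, 2] < 3, ramp((preds[, 2] - rng[1, 2]) / (3 - rng[1, 2])),
           ifelse(preds[, 2] > 6,
                  ramp((rng[2, 2] - preds[, 2]) / (rng[2, 2] - 6)), 1)),
    ifelse(preds[, 3] <= 13,
           ramp((preds[, 3] - rng[1, 3]) / (13 - rng[1, 3])),
           ramp((rng[2, 3] - preds[, 3]) / (rng[2, 3] - 13))),
    ramp((preds[, 4] - rng[1, 4]) / (1.29 - rng[1, 4]))
  )
  D <- apply(d, 1, function(r) if (any(r == 0)) 0 else exp(mean(log(r))))
  i <- which.max(D)
  expect_equal(opt$D, D[i], tolerance = 1e-12)
  expect_equal(unname(opt$optimum), as.numeric(grid[i, ]), tolerance = 1e-12)

  # refinement can only improve on the grid maximum
  ref <- optimize_desirability(fits, specs, domain = domain,
                               resolution = 21, refine = TRUE)
  expect_gte(ref$D, opt$D)

  # contour grid max equals the unrefined optimizer result
  ct <- desirability_contour(fits, specs, domain = domain, resolution = 21)
  expect_equal(max(ct$D), opt$D, tolerance = 1e-12)
  expect_equal(as.numeric(ct[attr(ct, "optimum_index"), c("inulin", "xanthan")]),
               unname(opt$optimum), tolerance = 1e-12)
})

test_that("monotone single-response objectives optimize to the boundary", {
  des <- full_factorial(list(factor_spec("a", -1, 1), factor_spec("b", -1, 1)),
                        n_center = 3)
  des$y <- coded_matrix(des)[, 1]   # y = a in coded units, sigma = 0
  fit <- fit_first_order(des, "y")
  spec <- desirability_spec("y", "maximize", low = -1, target = 1)
  opt <- optimize_desirability(list(fit), list(spec), resolution = 41,
                               refine = FALSE)
  expect_equal(unname(opt$optimum["a"]), 1)
  expect_equal(opt$D, 1)

  # symmetric target on an invertible linear model lands on its preimage
  tspec <- desirability_spec("y", "target", low = -1, high = 1, target = 0.5)
  topt <- optimize_desirability(list(fit), list(tspec), resolution = 41,
                                refine = TRUE)
  expect_equal(unname(opt_pred <- topt$predicted[[1]]), 0.5, tolerance = 1e-6)
  expect_equal(topt$D, 1, tolerance = 1e-9)
})

test_that("flat and all-zero desirability surfaces are flagged", {
  des <- full_factorial(list(factor_spec("a", -1, 1), factor_spec("b", -1, 1)),
                        n_center = 3)
  des$y <- rep(2, 7)
  fit <- fit_first_order(des, "y")
  # constant model far below the maximize ramp: d = 0 everywhere
  spec <- desirability_spec("y", "maximize", low = 5, target = 9)
  opt <- optimize_desirability(list(fit), list(spec), resolution = 11)
  expect_true(opt$degenerate)
  expect_equal(opt$D, 0)

  ct <- desirability_contour(list(fit), list(spec), resolution = 11)
  expect_true(all(ct$D == 0))
})

test_that("spec validation rejects inconsistent configurations", {
  expect_error(desirability_spec("y", "range", target = c(6, 3)), "increasing")
  expect_error(desirability_spec("y", "maximize", target = 1, s = 0),
               "positive")
  expect_error(desirability_spec("y", "target", low = 5, high = 10, target = 2),
               "below lower bound")
  expect_error(desirability_spec("y", "maximize", target = 1, weight = -1),
               "positive")
})
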