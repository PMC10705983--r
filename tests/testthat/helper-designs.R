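# reference factor specs used throughout
inulin_spec <- function() factor_spec("inulin", low = 6, high = 16)
xanthan_spec <- function() factor_spec("xanthan", low = 0.5, high = 0.8)

# random balanced 2^2 + center design with a random response
random_balanced_design <- function(n_center = sample(1:4, 1)) {
  f1 <- factor_spec("a", low = stats::runif(1, 0, 5),
                    high = stats::runif(1, 6, 20))
  f2 <- factor_spec("b", low = stats::runif(1, 0.1, 0.5),
                    high = stats::runif(1, 0.6, 2))
  des <- full_factorial(list(f1, f2), n_center = n_center)
  des$y <- stats::rnorm(nrow(des), mean = 5, sd = 2)
  des
}

# independent closed-form oracle for the coded fit on a balanced design:
# b0 = grand mean shifted by nothing (orthogonal columns), slopes are the
# factorial contrasts divided by the coded sum of squares (4 for 2^2 corners)
contrast_fit_oracle <- function(design, response) {
  z <- coded_matrix(design)
  y <- design[[response]]
  z12 <- z[, 1] * z[, 2]
  c(b0 = mean(y),
    b1 = sum(z[, 1] * y) / sum(z[, 1]^2),
    b2 = sum(z[, 2] * y) / sum(z[, 2]^2),
    b12 = sum(z12 * y) / sum(z12^2))
}
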