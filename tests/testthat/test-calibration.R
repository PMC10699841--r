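# Prior-effect rescaling, the cumulative-sum reformulation, exponential and
# isotonic calibration, and the Wilcoxon co-data filter.

test_that("rescaling divides each source by its max absolute value", {
  z <- cbind(a = c(2, -4, 0), b = c(0, 0, 0))
  pr <- rescale_priors(z)
  expect_equal(unname(pr$effects[, 1]), c(0.5, -1, 0))
  expect_equal(unname(pr$effects[, 2]), c(0, 0, 0))  # passed through
  expect_equal(unname(pr$degenerate), c(FALSE, TRUE))
  expect_true(all(abs(pr$effects) <= 1))
  expect_error(rescale_priors(cbind(c(1, NaN, 0))), "non-finite")
})

test_that("the cumulative design reproduces the worked four-feature example", {
  set.seed(1)
  x <- matrix(rnorm(6 * 4), 6, 4)
  z <- c(-0.5, -0.2, 0.3, 0.9)
  d <- build_cumulative_design(x, z)
  expect_equal(d$q, 2L)
  expect_equal(d$signs, c(-1L, -1L, 1L, 1L))
  expect_equal(d$W[, 1], x[, 1])            # most negative alone
  expect_equal(d$W[, 2], x[, 1] + x[, 2])   # cumulative from the left
  expect_equal(d$W[, 3], x[, 3] + x[, 4])   # cumulative from the right
  expect_equal(d$W[, 4], x[, 4])
})

test_that("with all-positive priors the lower block is empty", {
  set.seed(2)
  x <- matrix(rnorm(5 * 3), 5, 3)
  d <- build_cumulative_design(x, c(0.2, 0.5, 0.9))
  expect_equal(d$q, 0L)
  expect_equal(d$W[, 1], rowSums(x))
  expect_equal(d$W[, 3], x[, 3])
})

test_that("zero-prior features are excluded and tied priors merged", {
  set.seed(3)
  x <- matrix(rnorm(8 * 5), 8, 5)
  z <- c(0.4, 0, 0.4, -0.1, 0)
  d <- build_cumulative_design(x, z)
  expect_equal(d$zero_features, c(2L, 5L))
  expect_equal(length(d$groups), 2L)           # {-0.1} and the 0.4 tie group
  expect_equal(d$groups[[2]], c(1L, 3L))
  gamma <- recover_gamma(c(-0.3, 0.7), d)
  expect_equal(gamma, c(0.7, 0, 0.7, -0.3, 0))  # equal priors, equal effects
})

test_that("recover_gamma computes the stated cumulative sums", {
  set.seed(4)
  x <- matrix(rnorm(6 * 4), 6, 4)
  d <- build_cumulative_design(x, c(-0.5, -0.2, 0.3, 0.9))
  expect_equal(recover_gamma(c(-1, -0.5, 0.3, 0.2), d),
               c(-1.5, -0.5, 0.3, 0.5))
  expect_equal(recover_gamma(rep(0, 4), d), rep(0, 4))
  expect_error(recover_gamma(c(0.5, -0.5, 0.3, 0.2), d), "constraint")
})

test_that("the combined and original linear predictors are identical", {
  # delta' W == gamma' X for any admissible delta, and the recovered gamma
  # is nondecreasing in the prior order
  set.seed(5)
  for (r in 1:20) {
    n <- 10; p <- 6
    x <- matrix(rnorm(n * p), n, p)
    z <- rnorm(p)
    d <- build_cumulative_design(x, z)
    delta <- ifelse(d$signs < 0, -rexp(length(d$signs)),
                    rexp(length(d$signs)))
    gamma <- recover_gamma(delta, d)
    expect_equal(as.numeric(d$W %*% delta), as.numeric(x %*% gamma),
                 tolerance = 1e-12)
    expect_true(all(diff(gamma[order(z)]) >= -1e-12))
  }
})

test_that("exponential calibration recovers an exact power-law relation", {
  set.seed(6)
  n <- 100; p <- 40
  x <- matrix(rnorm(n * p), n, p)
  z <- runif(p, -1, 1)
  y <- as.numeric(x %*% z)               # noiseless, tau = 1, theta = 1
  cal <- exponential_calibrate(x, y, z, "gaussian")
  expect_equal(cal$tau, 1)
  expect_equal(cal$theta, 1, tolerance = 1e-3)
  expect_equal(cal$gamma, z, tolerance = 1e-3)
  # gamma factorizes exactly as theta * sign(z) * |z|^tau
  expect_identical(cal$gamma, cal$theta * sign(z) * abs(z)^cal$tau)
})

test_that("a zero factor estimate sets every calibrated effect to zero", {
  set.seed(7)
  n <- 60; p <- 20
  x <- matrix(rnorm(n * p), n, p)
  z <- runif(p, 0.1, 1)
  y <- -as.numeric(x %*% z)     # anti-correlated: constrained theta hits 0
  cal <- exponential_calibrate(x, y, z, "gaussian")
  expect_equal(cal$theta, 0)
  expect_equal(cal$gamma, rep(0, p))
  # with the constraint dropped, the source is inverted instead
  cal2 <- exponential_calibrate(x, y, z, "gaussian", allow_negative = TRUE)
  expect_true(cal2$inverted)
  expect_lt(cal2$deviance, cal$deviance)
})

test_that("both calibrations are invariant under positive rescaling of z", {
  set.seed(8)
  n <- 80; p <- 30
  x <- matrix(rnorm(n * p), n, p)
  z <- rnorm(p)
  b <- sign(z) * z^2
  y <- as.numeric(x %*% b + rnorm(n))
  for (c_scale in c(3, 0.02)) {
    e1 <- exponential_calibrate(x, y, z, "gaussian")
    e2 <- exponential_calibrate(x, y, c_scale * z, "gaussian")
    expect_equal(e1$gamma, e2$gamma, tolerance = 1e-8)
    i1 <- isotonic_calibrate(x, y, z, "gaussian")
    i2 <- isotonic_calibrate(x, y, c_scale * z, "gaussian")
    expect_equal(i1$gamma, i2$gamma, tolerance = 1e-8)
  }
})

test_that("isotonic calibration honours its defining constraints", {
  set.seed(9)
  n <- 80; p <- 25
  x <- matrix(rnorm(n * p), n, p)
  z <- rnorm(p); z[c(3, 17)] <- 0
  y <- as.numeric(x %*% (0.5 * z) + rnorm(n))
  cal <- isotonic_calibrate(x, y, z, "gaussian")
  expect_true(all(cal$gamma[z == 0] == 0))
  expect_true(all(cal$gamma[z > 0] >= 0))
  expect_true(all(cal$gamma[z < 0] <= 0))
  expect_true(all(diff(cal$gamma[order(z)]) >= -1e-8))
  # the feasible set contains gamma = 0, so the fit cannot be worse than null
  expect_lte(cal$deviance, cal$null_deviance + 1e-10)
})

test_that("isotonic calibration matches a projected-gradient oracle", {
  set.seed(10)
  for (fam in c("gaussian", "binomial")) {
    for (r in 1:3) {
      p <- 5; n <- 60
      x <- matrix(rnorm(n * p), n, p)
      z <- rnorm(p)
      eta <- as.numeric(x %*% (sign(z) * abs(z)))
      y <- if (fam == "gaussian") eta + rnorm(n)
           else rbinom(n, 1, plogis(eta))
      imp <- isotonic_calibrate(x, y, z, fam)
      ora <- oracle_isotonic(x, y, z, fam)
      expect_equal(imp$gamma, ora$gamma, tolerance = 1e-4)
      expect_equal(imp$alpha, ora$intercept, tolerance = 1e-4)
    }
  }
})

test_that("equal priors collapse to a single non-negative regression", {
  set.seed(11)
  n <- 70; p <- 6
  x <- matrix(rnorm(n * p), n, p)
  z <- rep(0.4, p)
  y <- as.numeric(0.3 * rowSums(x) + rnorm(n))
  cal <- isotonic_calibrate(x, y, z, "gaussian")
  expect_equal(length(unique(round(cal$gamma, 10))), 1L)
  scalar <- priorstack:::fit_simple_nonneg(rowSums(x), y, "gaussian")
  expect_equal(cal$gamma, rep(scalar$theta, p), tolerance = 1e-4)
})

test_that("a calibration equal to the null model is never retained", {
  set.seed(12)
  n <- 50; p <- 10
  x <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  cal <- exponential_calibrate(x, y, rep(0, p), "gaussian")  # degenerate
  cal <- filter_codata(x, y, cal, "gaussian")
  expect_false(cal$retained)
  expect_equal(cal$filter_pvalue, 1)
})

test_that("the filter retains an informative source at high signal", {
  # internal-design recipe at signal weight 0.8, prior = true coefficients
  sc <- internal_scenario(family = "gaussian", n_test = 10)
  kept <- vapply(1:100, function(s) {
    study <- simulate_internal(sc, 5000 + s)
    cal <- exponential_calibrate(study$x, study$y, study$beta_target,
                                 "gaussian")
    isTRUE(filter_codata(study$x, study$y, cal, "gaussian")$retained)
  }, logical(1))
  expect_gte(sum(kept), 95)
})
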