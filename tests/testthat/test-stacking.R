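# Cross-validated predictor matrix, meta-learners, combined coefficients,
# and prediction.

fit_both_modes <- function(family = "gaussian", seed = 1, n = 80, p = 40) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  beta <- c(rep(0.6, 6), rep(0, p - 6))
  eta <- as.numeric(x %*% beta)
  y <- if (family == "gaussian") eta + rnorm(n) else rbinom(n, 1, plogis(eta))
  z <- cbind(informative = beta + rnorm(p, sd = 0.15), noise = rnorm(p))
  list(x = x, y = y, z = z,
       sta = priorstack(x, y, z, family = family, stacking = "standard",
                        calibration = "exponential", seed = seed),
       sim = priorstack(x, y, z, family = family, stacking = "simultaneous",
                        calibration = "exponential", seed = seed))
}

test_that("the stacked predictor matrix has shape n x (m + 2)", {
  set.seed(61)
  n <- 50; p <- 20; m <- 3
  x <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  z <- matrix(rnorm(p * m), p, m)
  foldid <- make_folds(y, 5, "gaussian", seed = 7)
  base <- fit_codata_free(x, y, "gaussian", alpha = 0, foldid = foldid)
  cvp <- build_cv_predictors(x, y, rescale_priors(z), "gaussian", foldid,
                             base, calibration = "exponential")
  expect_equal(dim(cvp$Hcv), c(n, m + 2))
  expect_equal(cvp$column_meta,
               c("source1", "source2", "source3", "lambda_min", "lambda_1se"))
})

test_that("a degenerate source contributes an all-zero column", {
  set.seed(62)
  n <- 40; p <- 15
  x <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  z <- cbind(dead = rep(0, p), live = rnorm(p))
  foldid <- make_folds(y, 4, "gaussian", seed = 8)
  base <- fit_codata_free(x, y, "gaussian", alpha = 0, foldid = foldid)
  cvp <- build_cv_predictors(x, y, rescale_priors(z), "gaussian", foldid,
                             base, calibration = "exponential")
  expect_equal(cvp$H0cv[, 1], rep(0, n))
})

test_that("each stacked row comes from fits excluding its own fold", {
  set.seed(63)
  n <- 30; p <- 10
  x <- matrix(rnorm(n * p), n, p)
  beta <- c(rep(0.8, 3), rep(0, p - 3))
  y <- as.numeric(x %*% beta + rnorm(n))
  z <- matrix(beta + rnorm(p, sd = 0.1), ncol = 1)
  pr <- rescale_priors(z)
  foldid <- make_folds(y, 3, "gaussian", seed = 9)
  base <- fit_codata_free(x, y, "gaussian", alpha = 0, foldid = foldid)
  cvp <- build_cv_predictors(x, y, pr, "gaussian", foldid, base,
                             calibration = "exponential")
  k <- 1; hold <- foldid == k
  manual_cal <- exponential_calibrate(x[!hold, ], y[!hold],
                                      pr$effects[, 1], "gaussian")
  manual <- as.numeric(x[hold, ] %*% manual_cal$gamma)  # intercept ignored
  expect_equal(cvp$H0cv[hold, 1], manual, tolerance = 1e-10)
})

test_that("the standard meta-learner gives the true predictor nearly all weight", {
  picks <- vapply(1:20, function(s) {
    set.seed(700 + s)
    n <- 120
    eta <- rnorm(n)
    y <- eta + rnorm(n, sd = 0.5)
    H <- cbind(truth = eta + rnorm(n, sd = 0.02),
               junk1 = rnorm(n), junk2 = rnorm(n), junk3 = rnorm(n))
    foldid <- make_folds(y, 5, "gaussian", seed = s)
    meta <- fit_meta_standard(y, H, "gaussian", foldid)
    meta$omega
  }, numeric(4))
  expect_true(all(picks >= 0))
  avg <- rowMeans(picks)
  expect_gte(avg[1], 0.9)
  expect_true(all(avg[2:4] <= 0.05))
})

test_that("combined standard coefficients reproduce the trivial weightings", {
  set.seed(64)
  p <- 12
  base <- list(a0_min = 0.3, beta_min = rnorm(p),
               a0_1se = -0.1, beta_1se = rnorm(p))
  gammas <- matrix(rnorm(2 * p), p, 2)
  # only the meta intercept active
  comb0 <- combine_standard(list(omega0 = 1.7, omega = rep(0, 4)),
                            gammas, base)
  expect_equal(comb0$beta_star, rep(0, p))
  expect_equal(comb0$beta0_star, 1.7)
  # pure pass-through of the lambda.min fit
  comb1 <- combine_standard(list(omega0 = 0, omega = c(0, 0, 1, 0)),
                            gammas, base)
  expect_identical(comb1$beta_star, base$beta_min)
  expect_identical(comb1$beta0_star, base$a0_min)
})

test_that("predictions via combined coefficients equal stacked component predictions", {
  for (fam in c("gaussian", "binomial")) {
    d <- fit_both_modes(fam, seed = 65)
    xt <- matrix(rnorm(50 * ncol(d$x)), 50, ncol(d$x))
    # standard stacking
    fit <- d$sta
    m <- length(fit$source_names)
    eta_comb <- predict(fit, xt, type = "link")
    eta_parts <- fit$omega0 +
      as.numeric((xt %*% fit$gammas) %*% fit$omega[seq_len(m)]) +
      fit$omega[m + 1] * (fit$base$a0_min + as.numeric(xt %*% fit$base$beta_min)) +
      fit$omega[m + 2] * (fit$base$a0_1se + as.numeric(xt %*% fit$base$beta_1se))
    expect_equal(eta_comb, eta_parts, tolerance = 1e-10)
    # simultaneous stacking
    fit <- d$sim
    eta_comb <- predict(fit, xt, type = "link")
    eta_parts <- fit$meta$beta0 +
      as.numeric((xt %*% fit$gammas) %*% fit$omega) +
      as.numeric(xt %*% fit$meta$beta)
    expect_equal(eta_comb, eta_parts, tolerance = 1e-10)
  }
})

test_that("meta-weights are non-negative and excluded sources get exactly zero", {
  d <- fit_both_modes("gaussian", seed = 66)
  expect_true(all(d$sta$omega >= 0))
  expect_true(all(d$sim$omega >= 0))
  # force exclusion via degenerate priors
  set.seed(67)
  n <- 60; p <- 20
  x <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(x[, 1] + rnorm(n))
  z <- cbind(dead1 = rep(0, p), dead2 = rep(0, p))
  fit <- priorstack(x, y, z, stacking = "standard", seed = 1)
  expect_identical(fit$omega[1:2], c(0, 0))
  expect_false(any(fit$retained))
})

test_that("simultaneous stacking refuses too many sources", {
  set.seed(68)
  n <- 20; p <- 10; m <- 11
  x <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  H0 <- matrix(rnorm(n * m), n, m)
  expect_error(fit_meta_simultaneous(x, y, H0, "gaussian",
                                     foldid = rep(1:4, 5)),
               "few sources")
})

test_that("huge regularization drives deviations to zero and beta-star to gamma omega", {
  set.seed(69)
  n <- 80; p <- 30
  x <- matrix(rnorm(n * p), n, p)
  beta <- c(rep(0.7, 5), rep(0, p - 5))
  y <- as.numeric(x %*% beta + rnorm(n))
  gammas <- matrix(beta + rnorm(p, sd = 0.05), ncol = 1)
  H0cv <- x %*% gammas
  foldid <- make_folds(y, 5, "gaussian", seed = 10)
  meta <- fit_meta_simultaneous(x, y, H0cv, "gaussian", foldid, alpha = 0,
                                lambda = c(1e7, 1e6))
  expect_lt(max(abs(meta$beta)), 1e-4)
  comb <- combine_simultaneous(meta, gammas)
  expect_equal(comb$beta_star, as.numeric(gammas %*% meta$omega),
               tolerance = 1e-4)
})

test_that("lasso deviations are sparse while combined coefficients stay dense", {
  set.seed(70)
  n <- 100; p <- 120
  x <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p, sd = 0.25)            # dense truth
  y <- as.numeric(x %*% beta + rnorm(n))
  z <- matrix(beta + rnorm(p, sd = 0.05), ncol = 1)
  fit <- priorstack(x, y, z, stacking = "simultaneous", alpha = 1,
                    calibration = "exponential", seed = 2)
  expect_lt(sum(fit$meta$beta != 0), p / 2)       # few deviations
  expect_gt(sum(fit$beta_star != 0), p * 0.9)     # dense combination
})

test_that("trivial combined models predict as stated", {
  model <- structure(
    list(family = "binomial", beta0_star = 0, beta_star = rep(0, 3),
         feature_names = c("a", "b", "c")),
    class = "priorstack")
  xt <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(predict(model, xt), rep(0.5, 5))    # logit inverse of 0

  model$family <- "gaussian"
  model$beta0_star <- 2.5
  expect_equal(predict(model, xt), rep(2.5, 5))

  # manual arithmetic on a 5 x 3 example
  model$beta_star <- c(1, -2, 0.5)
  expect_equal(predict(model, xt, type = "link"),
               2.5 + as.numeric(xt %*% c(1, -2, 0.5)))

  expect_error(predict(model, xt[, 1:2]), "missing feature|columns")
})

test_that("uninformative co-data does not cause material negative transfer", {
  ratios <- vapply(1:50, function(s) {
    set.seed(1200 + s)
    n <- 60; p <- 80
    x <- matrix(rnorm(n * p), n, p)
    beta <- c(rep(0.5, 5), rep(0, p - 5))
    y <- as.numeric(x %*% beta + rnorm(n))
    xt <- matrix(rnorm(200 * p), 200, p)
    yt <- as.numeric(xt %*% beta + rnorm(200))
    z <- matrix(rnorm(p), ncol = 1)     # independent of beta
    foldid <- make_folds(y, 5, "gaussian", seed = s)
    stacked <- priorstack(x, y, z, calibration = "exponential",
                          stacking = "standard", alpha = 0, foldid = foldid)
    base <- fit_codata_free(x, y, "gaussian", alpha = 0, foldid = foldid)
    mse_stack <- mean((yt - predict(stacked, xt))^2)
    mse_base <- mean((yt - predict(base, xt))^2)
    mse_stack / mse_base
  }, numeric(1))
  expect_lte(mean(ratios), 1.05)
})
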