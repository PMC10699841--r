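# Simulation benchmarking designs.
#
# Two generators are provided. The "external" design follows the construction
# popularized by the glmtrans package: AR(0.5)-correlated features, a fixed
# effect size for causal features, and source coefficient vectors that differ
# from the target by +-h/p perturbations (transferable) or by relocated
# causal blocks (non-transferable). The "internal" design draws correlated
# continuous coefficients across datasets, thins them with Bernoulli
# indicators, applies non-linear transforms to the transferable sources, and
# standardizes the latent signal so the signal weight w fixes the
# signal-to-noise ratio exactly. Both simulate a target train/test split and
# source datasets from which prior effects are derived by penalized
# regression.

#' External simulation scenario
#'
#' @param family `"gaussian"` or `"binomial"`.
#' @param h difference between source and target coefficients (the
#'   per-feature perturbation is `h/p`).
#' @param K number of source datasets.
#' @param Ka number of transferable sources (`Ka <= K`; the first `Ka`
#'   sources are transferable).
#' @param n_target,n_source,n_test sample sizes (defaults 100/150/10000).
#' @param s number of non-zero target coefficients (50 dense, 15 sparse).
#' @param p number of features.
#' @param alpha target-model elastic-net mixing (0 dense/ridge, 1
#'   sparse/lasso); `alpha_source` is the mixing used to derive prior
#'   effects from the sources (0 when `alpha = 0`, else 0.95, which keeps
#'   the prior information stable in sparse settings).
#' @return An `"external_scenario"` list.
#' @export
external_scenario <- function(family = c("gaussian", "binomial"),
                              h = 5, K = 5, Ka = K, n_target = 100,
                              n_source = 150, s = 50, p = 1000,
                              n_test = 10000, alpha = 0) {
  family <- match.arg(family)
  if (Ka > K) stop_input("Ka must be <= K")
  if (3 * s > p) stop_input("non-transferable construction needs 3*s <= p")
  structure(list(design = "external", family = family, h = h, K = K,
                 Ka = Ka, n_target = n_target, n_source = n_source,
                 s = s, p = p, n_test = n_test, alpha = alpha,
                 alpha_source = if (alpha == 0) 0 else 0.95),
            class = c("external_scenario", "ps_scenario"))
}

#' Internal simulation scenario
#'
#' @param family `"gaussian"` or `"binomial"`.
#' @param rho_x base of the AR feature correlation `rho_x^|i-j|`.
#' @param rho_beta correlation of the underlying coefficient draws between
#'   the target and the two transferable sources (the first source is
#'   uncorrelated with everything).
#' @param pi probability that a coefficient is non-zero (0.2 dense, 0.05
#'   sparse).
#' @param w signal weight: the latent linear predictor is standardized and
#'   mixed as `sqrt(w) z* + sqrt(1-w) eps`, so `w = 0.8` is a 4:1
#'   signal-to-noise ratio.
#' @param n_target,n_source,n_test sample sizes (defaults 100/150/10000).
#' @param p number of features.
#' @param alpha target-model elastic-net mixing; sources are fitted with 0
#'   (dense) or 0.95 (sparse) accordingly.
#' @return An `"internal_scenario"` list.
#' @export
internal_scenario <- function(family = c("gaussian", "binomial"),
                              rho_x = 0.95, rho_beta = 0.99, pi = 0.2,
                              w = 0.8, n_target = 100, n_source = 150,
                              p = 500, n_test = 10000, alpha = 0) {
  family <- match.arg(family)
  if (w < 0 || w > 1) stop_input("w must be in [0, 1]")
  if (rho_x <= 0 || rho_x >= 1) stop_input("rho_x must be in (0, 1)")
  structure(list(design = "internal", family = family, rho_x = rho_x,
                 rho_beta = rho_beta, pi = pi, w = w, n_target = n_target,
                 n_source = n_source, p = p, n_test = n_test, alpha = alpha,
                 alpha_source = if (alpha == 0) 0 else 0.95),
            class = c("internal_scenario", "ps_scenario"))
}

# n x p draw with AR(rho) column correlation: distributionally identical to
# E %*% chol(Sigma) because Sigma_ij = rho^|i-j| admits the recursion
# x_j = rho x_{j-1} + sqrt(1 - rho^2) e_j.
draw_ar_features <- function(n, p, rho) {
  e <- matrix(stats::rnorm(n * p), n, p)
  x <- e
  if (p > 1) for (j in 2:p) x[, j] <- rho * x[, j - 1] + sqrt(1 - rho^2) * e[, j]
  x
}

#' Generate one replicate of the external design
#'
#' @param scenario an [external_scenario()].
#' @param seed integer seed; identical (scenario, seed) pairs yield
#'   bit-identical studies.
#' @return A `"simulated_study"` list: `x`, `y` (target training data),
#'   `x_test`, `y_test`, `sources` (list of `x`, `y` per source),
#'   `beta_target`, `beta_sources` (p x K), `scenario`, `seed`; prior
#'   effects are added later by [derive_priors()].
#' @export
simulate_external <- function(scenario, seed) {
  stopifnot(inherits(scenario, "external_scenario"))
  sc <- scenario
  with_seed(seed, {
    p <- sc$p; s <- sc$s; shift <- sc$h / p
    beta0 <- c(rep(0.5, s), rep(0, p - s))
    beta_sources <- matrix(0, p, sc$K)
    for (k in seq_len(sc$K)) {
      if (k <= sc$Ka) {
        d <- stats::rbinom(p, 1, 0.5)
        beta_sources[, k] <- beta0 + (-1)^d * shift
      } else {
        d <- stats::rbinom(p, 1, 0.5)
        base <- numeric(p)
        base[(s + 1):(2 * s)] <- 0.5                       # relocated causal
        tail_idx <- (2 * s + 1):p
        base[sample(tail_idx, s)] <- 0.5                   # random causal tail
        beta_sources[, k] <- base + (-1)^d * 2 * shift
      }
    }
    draw_target <- function(n) {
      x <- draw_ar_features(n, p, 0.5)
      eta <- as.numeric(x %*% beta0)
      y <- if (sc$family == "gaussian") eta + stats::rnorm(n)
           else stats::rbinom(n, 1, stats::plogis(eta))
      list(x = x, y = y)
    }
    train <- draw_target(sc$n_target)
    test <- draw_target(sc$n_test)
    sources <- lapply(seq_len(sc$K), function(k) {
      x <- draw_ar_features(sc$n_source, p, 0.5)
      eta <- 0.5 + as.numeric(x %*% beta_sources[, k])    # source intercept
      y <- if (sc$family == "gaussian") eta + stats::rnorm(sc$n_source)
           else stats::rbinom(sc$n_source, 1, stats::plogis(eta))
      list(x = x, y = y)
    })
    structure(list(x = train$x, y = train$y,
                   x_test = test$x, y_test = test$y,
                   sources = sources, beta_target = beta0,
                   beta_sources = beta_sources,
                   derived_priors = NULL, scenario = sc, seed = seed),
              class = "simulated_study")
  })
}

# Correlated coefficient draws for the internal design: datasets
# (target, source1, source2, source3); entries involving source1 are
# uncorrelated, pairs within {target, source2, source3} share rho_beta.
internal_coefficients <- function(p, rho_beta, pi) {
  S <- diag(4)
  for (k in 1:4) for (l in 1:4)
    if (k != l && k != 2 && l != 2) S[k, l] <- rho_beta
  R <- chol(S)
  B1 <- matrix(stats::rnorm(p * 4), p, 4) %*% R
  B2 <- matrix(stats::rnorm(p * 4), p, 4) %*% R
  B <- B1 * (B2 > stats::qnorm(1 - pi))
  # transferable transforms: square for source2, square root for source3
  B[, 3] <- sign(B[, 3]) * abs(B[, 3])^2
  B[, 4] <- sign(B[, 4]) * sqrt(abs(B[, 4]))
  B
}

#' Generate one replicate of the internal design
#'
#' The target training and test samples are generated jointly (one
#' standardization of the latent signal), then split; each source dataset is
#' standardized on its own.
#'
#' @param scenario an [internal_scenario()].
#' @param seed integer seed.
#' @return A `"simulated_study"`, as for [simulate_external()] but with 3
#'   sources and `beta_sources` a p x 3 matrix.
#' @export
simulate_internal <- function(scenario, seed) {
  stopifnot(inherits(scenario, "internal_scenario"))
  sc <- scenario
  with_seed(seed, {
    p <- sc$p
    B <- internal_coefficients(p, sc$rho_beta, sc$pi)
    beta0 <- B[, 1]
    beta_sources <- B[, 2:4, drop = FALSE]
    make_y <- function(x, beta) {
      zz <- as.numeric(x %*% beta)
      zs <- if (stats::sd(zz) > 0) (zz - mean(zz)) / stats::sd(zz) else zz
      lat <- sqrt(sc$w) * zs + sqrt(1 - sc$w) * stats::rnorm(length(zz))
      if (sc$family == "gaussian") lat
      else as.numeric(stats::plogis(lat) >= 0.5)  # probabilities rounded
    }
    n_all <- sc$n_target + sc$n_test
    x_all <- draw_ar_features(n_all, p, sc$rho_x)
    y_all <- make_y(x_all, beta0)
    idx <- seq_len(sc$n_target)
    sources <- lapply(1:3, function(k) {
      x <- draw_ar_features(sc$n_source, p, sc$rho_x)
      list(x = x, y = make_y(x, beta_sources[, k]))
    })
    structure(list(x = x_all[idx, , drop = FALSE], y = y_all[idx],
                   x_test = x_all[-idx, , drop = FALSE], y_test = y_all[-idx],
                   sources = sources, beta_target = beta0,
                   beta_sources = beta_sources,
                   derived_priors = NULL, scenario = sc, seed = seed),
              class = "simulated_study")
  })
}

#' Derive prior effects from the simulated source datasets
#'
#' Fits cross-validated penalized regression to each source dataset (ridge
#' in dense settings, lasso-like elastic net `alpha = 0.95` in sparse
#' settings) and uses the lambda.min coefficients as that source's prior
#' effects, rescaled column by column.
#'
#' @param study a `"simulated_study"`.
#' @param alpha_source elastic-net mixing for the source fits (defaults to
#'   the scenario's `alpha_source`).
#' @param seed integer seed for the source-fit fold draws.
#' @return The study with `derived_priors` set to a `"prior_effects"`
#'   object (one column per source).
#' @export
derive_priors <- function(study, alpha_source = NULL, seed = NULL) {
  stopifnot(inherits(study, "simulated_study"))
  alpha_source <- alpha_source %||% study$scenario$alpha_source
  family <- study$scenario$family
  seeds <- make_subseeds(seed %||% study$seed + 1L, length(study$sources))
  z <- vapply(seq_along(study$sources), function(k) {
    src <- study$sources[[k]]
    foldid <- make_folds(src$y, K = 10, family = family, seed = seeds[k])
    cv <- fit_codata_free(src$x, src$y, family, alpha = alpha_source,
                          foldid = foldid)
    cv$beta_min
  }, numeric(ncol(study$x)))
  colnames(z) <- paste0("source", seq_along(study$sources))
  study$derived_priors <- rescale_priors(z)
  study
}

#' Percent-of-null predictive metric
#'
#' Test-set mean squared error (gaussian) or mean logistic deviance
#' (binomial) expressed as a percentage of the same metric for predicting
#' every test sample by the training mean (gaussian) or training prevalence
#' (binomial). 100 means no better than the null model; 0 means perfect.
#'
#' @param pred predictions on the response scale (probabilities for
#'   binomial).
#' @param y_test test responses.
#' @param y_train training responses defining the null prediction.
#' @param family `"gaussian"` or `"binomial"`.
#' @return A single percentage.
#' @export
percent_of_null <- function(pred, y_test, y_train,
                            family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  y_test <- check_response(y_test, family)
  y_train <- check_response(y_train, family)
  clamp <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  if (family == "gaussian") {
    num <- mean((y_test - pred)^2)
    den <- mean((y_test - mean(y_train))^2)
  } else {
    pr <- clamp(pred)
    p0 <- clamp(mean(y_train))
    num <- mean(-2 * (y_test * log(pr) + (1 - y_test) * log(1 - pr)))
    den <- mean(-2 * (y_test * log(p0) + (1 - y_test) * log(1 - p0)))
  }
  if (!is.finite(den) || den <= 0)
    stop_input("degenerate null model: null metric is zero")
  100 * num / den
}

PS_METHODS <- c("glmnet", "exp.sta", "exp.sim", "iso.sta", "iso.sim",
                "naive")

# Fit one method on one simulated study and return test predictions on the
# response scale.
fit_method <- function(method, study, seed) {
  sc <- study$scenario
  family <- sc$family
  if (method == "glmnet") {
    foldid <- make_folds(study$y, 10, family, seed = seed)
    cv <- fit_codata_free(study$x, study$y, family, alpha = sc$alpha,
                          foldid = foldid)
    return(predict(cv, study$x_test, s = "lambda_min", type = "response"))
  }
  if (method == "naive") {
    v <- as.numeric(study$x %*% rowSums(study$derived_priors$effects))
    fit <- fit_simple_nonneg(v, study$y, family, nonnegative = FALSE)
    vt <- as.numeric(study$x_test %*% rowSums(study$derived_priors$effects))
    return(linkinv(fit$alpha + fit$theta * vt, family))
  }
  parts <- strsplit(method, ".", fixed = TRUE)[[1]]
  calibration <- switch(parts[1], exp = "exponential", iso = "isotonic",
                        stop_input("unknown method '", method, "'"))
  stacking <- switch(parts[2], sta = "standard", sim = "simultaneous",
                     stop_input("unknown method '", method, "'"))
  fit <- priorstack(study$x, study$y, study$derived_priors, family = family,
                    calibration = calibration, stacking = stacking,
                    alpha = sc$alpha, seed = seed)
  predict(fit, study$x_test, type = "response")
}

#' Run a simulation study
#'
#' Simulates `n_reps` replicate studies from a scenario, derives prior
#' effects from the sources, fits the requested methods, and scores each on
#' the held-out test set with the percent-of-null metric. Data generation
#' uses one sub-stream per replicate and method fitting another, so adding
#' or removing methods never changes the simulated data.
#'
#' @param scenario an [external_scenario()] or [internal_scenario()].
#' @param methods subset of `"glmnet"` (co-data-free baseline at
#'   lambda.min), `"exp.sta"`, `"exp.sim"`, `"iso.sta"`, `"iso.sim"`
#'   (calibration x stacking), `"naive"` (prior-weighted feature sum in a
#'   simple regression).
#' @param n_reps number of replicates (default 10).
#' @param seed root seed.
#' @return A data.frame with columns `scenario`, `method`, `rep`,
#'   `metric_percent` (plus an `"error"` attribute listing failed
#'   method-replicate pairs, if any).
#' @seealso [summarize_study()]
#' @export
run_study <- function(scenario, methods = c("glmnet", "iso.sta"),
                      n_reps = 10, seed = 1) {
  stopifnot(inherits(scenario, "ps_scenario"))
  methods <- match.arg(methods, PS_METHODS, several.ok = TRUE)
  data_seeds <- make_subseeds(seed, n_reps)
  fit_seeds <- make_subseeds(seed + 1L, n_reps)
  rows <- list()
  failures <- character(0)
  label <- paste0(scenario$design, "_", scenario$family)
  for (r in seq_len(n_reps)) {
    study <- if (scenario$design == "external")
      simulate_external(scenario, data_seeds[r])
    else simulate_internal(scenario, data_seeds[r])
    study <- derive_priors(study, seed = data_seeds[r])
    for (mth in methods) {
      val <- tryCatch({
        pred <- fit_method(mth, study, seed = fit_seeds[r])
        percent_of_null(pred, study$y_test, study$y, scenario$family)
      }, error = function(e) {
        failures <<- c(failures, paste0(mth, "/rep", r, ": ",
                                        conditionMessage(e)))
        NA_real_
      })
      rows[[length(rows) + 1]] <- data.frame(
        scenario = label, method = mth, rep = r, metric_percent = val,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "errors") <- failures
  out
}

#' Summarize a simulation study
#'
#' Mean and standard deviation of the percent-of-null metric per method,
#' plus the paired one-sided Wilcoxon signed-rank p-value against the
#' co-data-free baseline (alternative: the method's metric is smaller),
#' when the baseline was run.
#'
#' @param results output of [run_study()].
#' @param baseline method name used as reference (default `"glmnet"`).
#' @return A data.frame with one row per method.
#' @export
summarize_study <- function(results, baseline = "glmnet") {
  methods <- unique(results$method)
  base <- results$metric_percent[results$method == baseline]
  out <- lapply(methods, function(mth) {
    v <- results$metric_percent[results$method == mth]
    pv <- if (mth != baseline && length(base) == length(v) && length(base))
      tryCatch(suppressWarnings(
        stats::wilcox.test(v, base, paired = TRUE,
                           alternative = "less")$p.value),
        error = function(e) NA_real_)
    else NA_real_
    data.frame(method = mth, mean = mean(v, na.rm = TRUE),
               sd = stats::sd(v, na.rm = TRUE),
               n = sum(is.finite(v)), p_vs_baseline = pv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
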