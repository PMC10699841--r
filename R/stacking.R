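# Stacked generalization on the level of linear predictors.
#
# The meta-learner is trained on cross-validated (prevalidated) linear
# predictors: one column per retained co-data source (intercept contribution
# set to zero) and two columns for the co-data-free model at lambda.min and
# lambda.1se (intercepts included). Standard stacking fits a non-negative
# lasso of the target on these m+2 columns; simultaneous stacking jointly
# fits unpenalized non-negative meta-weights on the m co-data columns and a
# penalized per-feature deviation vector on the raw features. Either way the
# fitted ensemble collapses algebraically to a single combined intercept and
# coefficient vector.

calibrate_once <- function(x, y, z, family, calibration, allow_negative,
                           tau_grid) {
  if (calibration == "exponential")
    exponential_calibrate(x, y, z, family, tau_grid = tau_grid,
                          allow_negative = allow_negative)
  else
    isotonic_calibrate(x, y, z, family, allow_negative = allow_negative)
}

#' Build the cross-validated linear-predictor matrix
#'
#' For each fold, recalibrates every retained source on the other folds and
#' fills the held-out rows with `x_out %*% gamma_hat` (the calibration
#' intercept is deliberately ignored, so co-data columns carry only the
#' feature-dependent part of the linear predictor). The two co-data-free
#' columns are taken from the prevalidated path of `base` at lambda.min and
#' lambda.1se (intercepts included). Sources that are not retained, or whose
#' calibration fails within a fold, contribute zero entries.
#'
#' @param x,y target data.
#' @param priors a `"prior_effects"` object (see [rescale_priors()]).
#' @param family `"gaussian"` or `"binomial"`.
#' @param foldid fold identifiers shared across the whole fit.
#' @param base a `"ps_cvpath"` fitted with the same `foldid`.
#' @param calibration `"exponential"` or `"isotonic"`.
#' @param retained logical m-vector from the co-data filter (`NULL` keeps
#'   all sources).
#' @param allow_negative passed to the calibration routines.
#' @param tau_grid exponent grid for exponential calibration.
#' @return List with `H0cv` (n x m), `H1cv_min`, `H1cv_1se` (n-vectors),
#'   `Hcv` (n x (m+2)) and `column_meta` (source labels plus
#'   `"lambda_min"`, `"lambda_1se"`).
#' @export
build_cv_predictors <- function(x, y, priors,
                                family = c("gaussian", "binomial"),
                                foldid, base,
                                calibration = c("isotonic", "exponential"),
                                retained = NULL, allow_negative = FALSE,
                                tau_grid = DEFAULT_TAU_GRID) {
  family <- match.arg(family)
  calibration <- match.arg(calibration)
  stopifnot(inherits(priors, "prior_effects"), inherits(base, "ps_cvpath"))
  x <- check_feature_matrix(x)
  y <- check_response(y, family)
  n <- nrow(x)
  m <- ncol(priors$effects)
  retained <- retained %||% rep(TRUE, m)
  K <- max(foldid)

  H0cv <- matrix(0, n, m)
  for (k in seq_len(K)) {
    hold <- foldid == k
    for (j in seq_len(m)) {
      if (!retained[j]) next
      cal <- tryCatch(
        calibrate_once(x[!hold, , drop = FALSE], y[!hold],
                       priors$effects[, j], family, calibration,
                       allow_negative, tau_grid),
        error = function(e) NULL)
      if (is.null(cal)) {
        warning("calibration of source '", priors$source_names[j],
                "' failed in fold ", k, "; filling zeros", call. = FALSE)
        next
      }
      H0cv[hold, j] <- as.numeric(x[hold, , drop = FALSE] %*% cal$gamma)
    }
  }
  H1cv_min <- base$preval[, base$index_min]
  H1cv_1se <- base$preval[, base$index_1se]
  Hcv <- cbind(H0cv, H1cv_min, H1cv_1se)
  meta <- c(priors$source_names, "lambda_min", "lambda_1se")
  colnames(Hcv) <- meta
  list(H0cv = H0cv, H1cv_min = H1cv_min, H1cv_1se = H1cv_1se,
       Hcv = Hcv, column_meta = meta)
}

#' Standard stacking meta-learner
#'
#' Non-negative lasso of the target on the m+2 cross-validated linear
#' predictors (intercept free), with lambda chosen by cross-validation on
#' the shared fold plan (lambda.min rule). The meta-features are not
#' standardized: they already share the linear-predictor scale, and
#' standardizing would distort the weighted-coefficient algebra downstream.
#'
#' @param y target response.
#' @param Hcv the n x (m+2) matrix from [build_cv_predictors()].
#' @param family `"gaussian"` or `"binomial"`.
#' @param foldid shared fold identifiers.
#' @param lambda optional fixed lambda (skips cross-validation).
#' @return List with `omega0` (meta intercept), `omega` (m+2 non-negative
#'   weights), `all_zero` flag, and the cv fit.
#' @export
fit_meta_standard <- function(y, Hcv, family = c("gaussian", "binomial"),
                              foldid, lambda = NULL) {
  family <- match.arg(family)
  y <- check_response(y, family)
  if (ncol(Hcv) < 1) stop_input("Hcv must have at least one column")
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(Hcv, y, family = family, alpha = 1,
                          lower.limits = 0, standardize = FALSE,
                          lambda = lambda)
    cf <- stats::coef(fit, s = min(lambda))
  } else {
    fit <- glmnet::cv.glmnet(Hcv, y, family = family, alpha = 1,
                             lower.limits = 0, standardize = FALSE,
                             foldid = foldid)
    cf <- stats::coef(fit, s = "lambda.min")
  }
  cf <- as.numeric(cf)
  omega0 <- cf[1]
  omega <- pmax(cf[-1], 0)  # guard against solver dust below the bound
  list(omega0 = omega0, omega = omega,
       all_zero = all(omega == 0), fit = fit)
}

#' Combine standard-stacking components into one coefficient vector
#'
#' Collapses the fitted ensemble: the combined intercept is
#' `omega0 + omega_{m+1} beta0_min + omega_{m+2} beta0_1se` and the combined
#' coefficient of feature j is the omega-weighted sum of the calibrated
#' effects plus the weighted lambda.min/lambda.1se coefficients. Predictions
#' through the combined coefficients equal predictions through the component
#' linear predictors exactly.
#'
#' @param meta result of [fit_meta_standard()].
#' @param gammas p x m matrix of full-data calibrated effects.
#' @param base `"ps_cvpath"` with the full-data lambda.min/lambda.1se fits.
#' @return List with `beta0_star` and `beta_star`.
#' @export
combine_standard <- function(meta, gammas, base) {
  m <- ncol(gammas)
  omega <- meta$omega
  stopifnot(length(omega) == m + 2)
  w_min <- omega[m + 1]
  w_1se <- omega[m + 2]
  beta0 <- meta$omega0 + w_min * base$a0_min + w_1se * base$a0_1se
  beta <- w_min * base$beta_min + w_1se * base$beta_1se
  if (m > 0) beta <- beta + as.numeric(gammas %*% omega[seq_len(m)])
  list(beta0_star = as.numeric(beta0), beta_star = as.numeric(beta))
}

#' Simultaneous stacking meta-learner
#'
#' Regresses the target jointly on the m co-data columns of the
#' cross-validated linear-predictor matrix and on the p raw features: the
#' meta-weights are unpenalized (penalty factor 0) and bounded below by
#' zero, while the per-feature deviations carry the user's ridge or lasso
#' penalty. Lambda is selected by cross-validation on the shared folds
#' (lambda.min rule). As lambda grows, the deviations vanish and the
#' combined coefficients approach the omega-weighted calibrated effects.
#' Only suitable for few sources; refuses `m > n/2`.
#'
#' @param x,y target data.
#' @param H0cv n x m co-data columns from [build_cv_predictors()].
#' @param family `"gaussian"` or `"binomial"`.
#' @param foldid shared fold identifiers.
#' @param alpha elastic-net mixing for the feature deviations.
#' @param lambda optional fixed lambda (skips cross-validation).
#' @return List with `beta0` (intercept), `omega` (m non-negative weights),
#'   `beta` (p deviations), and the cv fit.
#' @export
fit_meta_simultaneous <- function(x, y, H0cv,
                                  family = c("gaussian", "binomial"),
                                  foldid, alpha = 0, lambda = NULL) {
  family <- match.arg(family)
  x <- check_feature_matrix(x)
  y <- check_response(y, family)
  m <- ncol(H0cv)
  p <- ncol(x)
  n <- nrow(x)
  if (m > n / 2)
    stop_input("simultaneous stacking needs few sources (m <= n/2); ",
               "got m = ", m, ", n = ", n, " - use standard stacking")
  XX <- cbind(H0cv, x)
  pf <- c(rep(0, m), rep(1, p))
  ll <- c(rep(0, m), rep(-Inf, p))
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(XX, y, family = family, alpha = alpha,
                          penalty.factor = pf, lower.limits = ll,
                          lambda = lambda)
    cf <- as.numeric(stats::coef(fit, s = min(lambda)))
  } else {
    fit <- glmnet::cv.glmnet(XX, y, family = family, alpha = alpha,
                             penalty.factor = pf, lower.limits = ll,
                             foldid = foldid)
    cf <- as.numeric(stats::coef(fit, s = "lambda.min"))
  }
  omega <- if (m > 0) pmax(cf[1 + seq_len(m)], 0) else numeric(0)
  list(beta0 = cf[1], omega = omega, beta = cf[-seq_len(1 + m)], fit = fit)
}

#' Combine simultaneous-stacking components into one coefficient vector
#'
#' The combined intercept is the joint-fit intercept and the combined
#' coefficient of feature j is the omega-weighted sum of calibrated effects
#' plus the fitted deviation `beta_j`.
#'
#' @param meta result of [fit_meta_simultaneous()].
#' @param gammas p x m matrix of full-data calibrated effects.
#' @return List with `beta0_star` and `beta_star`.
#' @export
combine_simultaneous <- function(meta, gammas) {
  beta <- meta$beta
  if (ncol(gammas) > 0) beta <- beta + as.numeric(gammas %*% meta$omega)
  list(beta0_star = as.numeric(meta$beta0), beta_star = as.numeric(beta))
}
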