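#' Transfer learning for penalized regression with prior effects
#'
#' Fits the full two-step pipeline on a target dataset and a p x m matrix
#' of prior effects (one column per external source): (1) rescale the prior
#' effects and calibrate each source to the target data by exponential or
#' isotonic calibration, optionally pre-filtering sources with the paired
#' Wilcoxon residual test; (2) fit the co-data-free penalized baseline with
#' 10-fold cross-validation, assemble the cross-validated linear-predictor
#' matrix, and combine everything by stacked generalization (standard or
#' simultaneous). The fitted ensemble is collapsed into a single combined
#' intercept and coefficient vector, so prediction and interpretation work
#' exactly as for an ordinary GLM.
#'
#' @param x numeric n x p feature matrix (samples in rows).
#' @param y response vector: finite reals (gaussian) or 0/1 (binomial).
#' @param z p x m matrix (or p-vector) of prior effects, one column per
#'   source; assumed positively correlated with the true target effects
#'   unless `allow_negative = TRUE`.
#' @param family `"gaussian"` or `"binomial"`.
#' @param calibration `"isotonic"` (sign- and order-preserving, flexible) or
#'   `"exponential"` (two-parameter power law, robust).
#' @param stacking `"standard"` (non-negative lasso on m+2 stacked linear
#'   predictors) or `"simultaneous"` (joint fit of unpenalized non-negative
#'   meta-weights and penalized per-feature deviations; requires few
#'   sources).
#' @param alpha elastic-net mixing for the co-data-free model and, in
#'   simultaneous mode, the feature deviations (0 ridge, 1 lasso).
#' @param nfolds number of cross-validation folds (default 10). One fold
#'   plan is drawn and shared by every cross-validated component.
#' @param foldid optional explicit fold identifiers (overrides `nfolds`).
#' @param filter apply the Wilcoxon co-data filter before stacking
#'   (default TRUE); excluded sources get meta-weight exactly 0.
#' @param allow_negative also consider sign-inverted calibrations for
#'   sources that may be negatively correlated with the target effects.
#' @param tau_grid exponent grid for exponential calibration.
#' @param seed integer seed for the fold draw; `NULL` consumes the current
#'   RNG stream.
#' @return An object of class `"priorstack"` with combined coefficients
#'   (`beta0_star`, `beta_star`), meta-weights (`omega0`, `omega`), the
#'   per-source calibrations (`calibrations`), the co-data-free cv path
#'   (`base`), and bookkeeping needed for prediction and serialization.
#' @examples
#' set.seed(1)
#' n <- 60; p <- 30
#' x <- matrix(rnorm(n * p), n, p)
#' beta <- c(rep(0.5, 5), rep(0, p - 5))
#' y <- as.numeric(x %*% beta + rnorm(n))
#' z <- beta + rnorm(p, sd = 0.1)        # one informative source
#' fit <- priorstack(x, y, z, family = "gaussian",
#'                   calibration = "exponential", nfolds = 5, seed = 1)
#' head(coef(fit))
#' cor(predict(fit, x), y)
#' @seealso [predict.priorstack()], [write_model_json()]
#' @export
priorstack <- function(x, y, z, family = c("gaussian", "binomial"),
                       calibration = c("isotonic", "exponential"),
                       stacking = c("standard", "simultaneous"),
                       alpha = 0, nfolds = 10, foldid = NULL,
                       filter = TRUE, allow_negative = FALSE,
                       tau_grid = DEFAULT_TAU_GRID, seed = NULL) {
  family <- match.arg(family)
  calibration <- match.arg(calibration)
  stacking <- match.arg(stacking)
  x <- check_feature_matrix(x)
  y <- check_response(y, family)
  check_conformable(x, y)
  if (family == "gaussian" && stats::sd(y) == 0)
    stop_input("constant response: nothing to model")

  priors <- if (inherits(z, "prior_effects")) z else rescale_priors(z)
  if (nrow(priors$effects) != ncol(x))
    stop_input("prior effects must have one row per feature")
  m <- ncol(priors$effects)

  foldid <- foldid %||% make_folds(y, K = nfolds, family = family,
                                   seed = seed)

  # co-data-free base learner (shared fold plan)
  base <- fit_codata_free(x, y, family, alpha = alpha, foldid = foldid)

  # full-data calibration + filter, one source at a time
  calibrations <- vector("list", m)
  for (j in seq_len(m)) {
    cal <- calibrate_once(x, y, priors$effects[, j], family, calibration,
                          allow_negative, tau_grid)
    cal$source <- priors$source_names[j]
    cal <- if (filter) filter_codata(x, y, cal, family)
           else { cal$retained <- TRUE; cal$filter_pvalue <- NA_real_; cal }
    if (priors$degenerate[j]) cal$retained <- FALSE
    calibrations[[j]] <- cal
  }
  retained <- vapply(calibrations, function(cc) isTRUE(cc$retained),
                     logical(1))

  cvp <- build_cv_predictors(x, y, priors, family, foldid, base,
                             calibration = calibration, retained = retained,
                             allow_negative = allow_negative,
                             tau_grid = tau_grid)
  gammas <- vapply(calibrations, function(cc) cc$gamma,
                   numeric(ncol(x)))
  gammas <- matrix(gammas, nrow = ncol(x))
  gammas[, !retained] <- 0

  if (stacking == "standard") {
    meta <- fit_meta_standard(y, cvp$Hcv, family, foldid)
    meta$omega[seq_len(m)][!retained] <- 0
    comb <- combine_standard(meta, gammas, base)
    omega0 <- meta$omega0
    omega <- meta$omega
  } else {
    meta <- fit_meta_simultaneous(x, y, cvp$H0cv, family, foldid,
                                  alpha = alpha)
    if (m > 0) meta$omega[!retained] <- 0
    comb <- combine_simultaneous(meta, gammas)
    omega0 <- meta$beta0
    omega <- meta$omega
  }

  structure(
    list(family = family, calibration = calibration, stacking = stacking,
         alpha = alpha, foldid = foldid, nfolds = max(foldid),
         priors = priors, calibrations = calibrations, retained = retained,
         gammas = gammas, base = base, meta = meta, cv_predictors = cvp,
         omega0 = omega0, omega = omega,
         beta0_star = comb$beta0_star, beta_star = comb$beta_star,
         feature_names = colnames(x) %||% paste0("V", seq_len(ncol(x))),
         source_names = priors$source_names,
         version = as.character(utils::packageVersion("priorstack"))),
    class = "priorstack")
}

#' Predict from a fitted transfer-learning model
#'
#' @param object a `"priorstack"` fit (or a model restored by
#'   [read_model_json()]).
#' @param newx feature matrix with the p training columns, in training
#'   order. If `newx` has column names and the model stores feature names,
#'   columns are matched by name.
#' @param type `"response"` (default; probabilities for binomial) or
#'   `"link"` for raw linear predictors.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.priorstack <- function(object, newx, type = c("response", "link"),
                               ...) {
  type <- match.arg(type)
  newx <- check_feature_matrix(newx, "newx")
  p <- length(object$beta_star)
  fn <- object$feature_names
  if (!is.null(colnames(newx)) && !is.null(fn) &&
      !identical(colnames(newx), as.character(fn))) {
    missing <- setdiff(fn, colnames(newx))
    if (length(missing))
      stop_input("newx is missing feature column(s): ",
                 paste(utils::head(missing, 5), collapse = ", "))
    newx <- newx[, fn, drop = FALSE]
  }
  if (ncol(newx) != p)
    stop_input("newx has ", ncol(newx), " columns; model expects ", p)
  eta <- object$beta0_star + as.numeric(newx %*% object$beta_star)
  if (type == "link") eta else linkinv(eta, object$family)
}

#' @export
coef.priorstack <- function(object, ...) {
  stats::setNames(c(object$beta0_star, object$beta_star),
                  c("(Intercept)", object$feature_names))
}

#' @export
print.priorstack <- function(x, ...) {
  cat("priorstack fit (", x$family, ", ", x$calibration, " calibration, ",
      x$stacking, " stacking)\n", sep = "")
  cat("  features:", length(x$beta_star),
      " sources:", length(x$source_names),
      " folds:", x$nfolds, "\n")
  m <- length(x$source_names)
  if (m > 0) {
    for (j in seq_len(m)) {
      cc <- x$calibrations[[j]]
      cat(sprintf("  source %-12s retained=%-5s weight=%.4f p=%.3g",
                  x$source_names[j], x$retained[j], x$omega[j],
                  cc$filter_pvalue))
      if (cc$method == "exponential")
        cat(sprintf(" (theta=%.3f, tau=%.2f)", cc$theta, cc$tau))
      cat("\n")
    }
  }
  if (x$stacking == "standard")
    cat(sprintf("  co-data-free weights: lambda_min=%.4f lambda_1se=%.4f\n",
                x$omega[m + 1], x$omega[m + 2]))
  cat(sprintf("  lambda_min=%.4g lambda_1se=%.4g\n",
              x$base$lambda_min, x$base$lambda_1se))
  cat(sprintf("  combined: intercept=%.4f, %d non-zero coefficients\n",
              x$beta0_star, sum(x$beta_star != 0)))
  invisible(x)
}
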