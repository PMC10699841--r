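# Co-data-free penalized base learner: a full-data coefficient path over a
# decreasing lambda sequence, plus K-fold cross-validation delivering the
# lambda.min / lambda.1se fits and the held-out (prevalidated) linear
# predictors reused by the stacking layer.

#' Build a cross-validation fold plan
#'
#' Assigns each sample to one of `K` near-equal folds, reproducibly from
#' `seed`. Binomial responses are stratified by class so every fold carries
#' approximately the training prevalence.
#'
#' @param y response vector.
#' @param K number of folds (default 10).
#' @param family `"gaussian"` or `"binomial"`.
#' @param seed integer seed, or `NULL` to consume the current RNG stream.
#' @return Integer n-vector of fold identifiers in `1..K`.
#' @export
make_folds <- function(y, K = 10, family = c("gaussian", "binomial"),
                       seed = NULL) {
  family <- match.arg(family)
  y <- check_response(y, family)
  n <- length(y)
  if (K < 2 || K > n) stop_input("need n >= K >= 2")
  with_seed(seed, {
    foldid <- integer(n)
    if (family == "binomial") {
      for (cls in c(0, 1)) {
        idx <- which(y == cls)
        if (length(idx) < K)
          stop_input("binomial class ", cls, " has fewer samples (",
                     length(idx), ") than folds (", K, ")")
        foldid[idx[sample.int(length(idx))]] <- rep_len(seq_len(K),
                                                        length(idx))
      }
    } else {
      foldid[sample.int(n)] <- rep_len(seq_len(K), n)
    }
    foldid
  })
}

#' Cross-validated co-data-free penalized regression
#'
#' Fits the full-data coefficient path over a decreasing sequence of
#' `nlambda` values, refits the path on each set of K-1 folds, and scores
#' every lambda by mean held-out deviance (squared error for gaussian,
#' logistic deviance for binomial). `lambda.min` minimizes the
#' cross-validated loss; `lambda.1se` is the largest lambda whose loss is
#' within one standard error of that minimum. The held-out linear
#' predictors at both values are retained for stacked generalization.
#'
#' @param x feature matrix (n x p).
#' @param y response vector.
#' @param family `"gaussian"` or `"binomial"`.
#' @param alpha elastic-net mixing (0 ridge, 1 lasso).
#' @param foldid fold identifiers from [make_folds()] (values in `1..K`).
#' @param nlambda length of the lambda sequence (default 100).
#' @return An object of class `"ps_cvpath"`: the full-data `"ps_path"`,
#'   `lambda`, `cvm` (mean CV loss), `cvsd` (standard errors),
#'   `lambda_min`/`lambda_1se` and their indices, intercepts and
#'   coefficients at both (`a0_min`, `beta_min`, `a0_1se`, `beta_1se`), and
#'   `preval` (n x L held-out linear predictors; row i is computed from
#'   fits that excluded the fold of sample i).
#' @export
fit_codata_free <- function(x, y, family = c("gaussian", "binomial"),
                            alpha = 0, foldid, nlambda = 100) {
  family <- match.arg(family)
  x <- check_feature_matrix(x)
  y <- check_response(y, family)
  check_conformable(x, y)
  foldid <- as.integer(foldid)
  if (length(foldid) != length(y)) stop_input("foldid must have length n")
  K <- max(foldid)
  if (K < 2 || !setequal(unique(foldid), seq_len(K)))
    stop_input("foldid must use every fold in 1..K")

  full <- fit_penalized_path(x, y, family,
                             penalty_spec(alpha = alpha, nlambda = nlambda))
  lam <- full$lambda
  L <- length(lam)
  n <- length(y)

  preval <- matrix(NA_real_, n, L)
  for (k in seq_len(K)) {
    hold <- foldid == k
    fk <- glmnet::glmnet(x[!hold, , drop = FALSE], y[!hold], family = family,
                         alpha = alpha, lambda = lam)
    preval[hold, ] <- stats::predict(fk, x[hold, , drop = FALSE],
                                     type = "link")
  }
  loss <- obs_deviance(matrix(y, n, L), preval, family)
  fold_means <- rowsum(loss, foldid) / as.vector(table(foldid))
  cvm <- colMeans(fold_means)
  cvsd <- apply(fold_means, 2, stats::sd) / sqrt(K)

  imin <- which.min(cvm)
  i1se <- min(which(cvm <= cvm[imin] + cvsd[imin]))  # lambda is decreasing

  structure(
    list(path = full, lambda = lam, cvm = cvm, cvsd = cvsd,
         lambda_min = lam[imin], lambda_1se = lam[i1se],
         index_min = imin, index_1se = i1se,
         a0_min = full$a0[imin], beta_min = full$beta[, imin],
         a0_1se = full$a0[i1se], beta_1se = full$beta[, i1se],
         preval = preval, foldid = foldid, family = family, alpha = alpha),
    class = "ps_cvpath")
}

#' Predict from a cross-validated path
#'
#' @param object a `"ps_cvpath"`.
#' @param newx feature matrix with the training columns.
#' @param s `"lambda_min"` (default) or `"lambda_1se"`.
#' @param type `"link"` for linear predictors, `"response"` for expected
#'   values (probabilities for binomial).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.ps_cvpath <- function(object, newx,
                              s = c("lambda_min", "lambda_1se"),
                              type = c("response", "link"), ...) {
  s <- match.arg(s)
  type <- match.arg(type)
  newx <- check_feature_matrix(newx, "newx")
  eta <- if (s == "lambda_min")
    object$a0_min + as.numeric(newx %*% object$beta_min)
  else
    object$a0_1se + as.numeric(newx %*% object$beta_1se)
  if (type == "link") eta else linkinv(eta, object$family)
}
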