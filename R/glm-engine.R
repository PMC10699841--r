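# Shared numerical core: penalized GLM paths with per-coefficient penalty
# factors and box constraints, and (epsilon-ridge-stabilized) sign-constrained
# maximum likelihood. All penalized optimization is delegated to glmnet;
# this file owns the interface contracts and the stabilized ML construction.

#' Penalty specification for a penalized GLM path
#'
#' Describes the elastic-net penalty, the lambda sequence, per-coefficient
#' penalty factors, and per-coefficient box (sign) constraints used by
#' [fit_penalized_path()]. When `lambda` is `NULL` the solver constructs the
#' usual decreasing sequence of `nlambda` log-spaced values from the data
#' (largest value = smallest lambda with all penalized slopes zero).
#'
#' @param alpha elastic-net mixing parameter in `[0, 1]`; 0 is ridge, 1 lasso.
#' @param lambda optional user lambda sequence (strictly decreasing, >= 0).
#' @param nlambda length of the automatic lambda sequence (default 100).
#' @param penalty_factor optional non-negative per-coefficient multipliers;
#'   0 leaves a coefficient unpenalized.
#' @param lower_limits,upper_limits per-coefficient box limits (recycled);
#'   lower must be <= 0 <= upper, as the null model must be feasible.
#' @param standardize logical; internally standardize columns to unit
#'   variance before fitting (coefficients are always returned on the
#'   original scale). Constant columns receive coefficient 0.
#' @param thresh coordinate-descent convergence threshold (glmnet's
#'   `thresh`); tighten for high-precision comparisons.
#' @details `lambda` follows the solver convention of glmnet: for gaussian
#'   responses the fit is computed on the unit-variance-scaled response, so
#'   at a stated `lambda` the ridge part of the penalty acts on the
#'   raw-scale objective as `lambda / sd_n(y)` while the lasso part is
#'   unscaled (`sd_n` is the population standard deviation). Cross-validated
#'   selection is unaffected by the convention.
#' @return An object of class `"penalty_spec"`.
#' @export
penalty_spec <- function(alpha = 1, lambda = NULL, nlambda = 100,
                         penalty_factor = NULL,
                         lower_limits = -Inf, upper_limits = Inf,
                         standardize = TRUE, thresh = 1e-7) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1)
    stop_input("'alpha' must be a single value in [0, 1]")
  if (!is.null(lambda)) {
    lambda <- as.numeric(lambda)
    if (any(!is.finite(lambda)) || any(lambda < 0))
      stop_input("'lambda' must be non-negative and finite")
    if (length(lambda) > 1 && any(diff(lambda) >= 0))
      stop_input("'lambda' must be strictly decreasing")
  }
  if (!is.null(penalty_factor) && any(penalty_factor < 0))
    stop_input("'penalty_factor' must be non-negative")
  structure(
    list(alpha = alpha, lambda = lambda, nlambda = nlambda,
         penalty_factor = penalty_factor,
         lower_limits = lower_limits, upper_limits = upper_limits,
         standardize = standardize, thresh = thresh),
    class = "penalty_spec")
}

# Expand a penalty_spec into glmnet arguments for a p-column problem.
spec_to_glmnet_args <- function(spec, p) {
  lower <- rep_len(spec$lower_limits, p)
  upper <- rep_len(spec$upper_limits, p)
  if (any(lower > upper)) stop_input("lower_limits must be <= upper_limits")
  if (any(lower > 0) || any(upper < 0))
    stop_input("box limits must satisfy lower <= 0 <= upper")
  args <- list(alpha = spec$alpha, lower.limits = lower, upper.limits = upper,
               standardize = spec$standardize, thresh = spec$thresh)
  if (!is.null(spec$penalty_factor))
    args$penalty.factor <- rep_len(spec$penalty_factor, p)
  if (!is.null(spec$lambda)) args$lambda <- spec$lambda
  else args$nlambda <- spec$nlambda
  args
}

#' Fit a penalized GLM path
#'
#' Fits gaussian or binomial penalized regression along a decreasing lambda
#' sequence, with optional per-coefficient penalty factors and box
#' constraints, warm-started along the path. The intercept is always
#' unpenalized and unconstrained.
#'
#' @param x numeric feature matrix (n x p), samples in rows.
#' @param y response vector: finite reals (gaussian) or 0/1 (binomial).
#' @param family `"gaussian"` or `"binomial"`.
#' @param spec a [penalty_spec()].
#' @return An object of class `"ps_path"` wrapping the fitted path, with
#'   elements `lambda`, `a0` (intercepts), `beta` (p x L coefficient matrix),
#'   `converged`, and the underlying `glmnet` fit.
#' @seealso [fit_sign_constrained_ml()], [fit_codata_free()]
#' @export
fit_penalized_path <- function(x, y, family = c("gaussian", "binomial"),
                               spec = penalty_spec()) {
  family <- match.arg(family)
  x <- check_feature_matrix(x)
  y <- check_response(y, family)
  check_conformable(x, y)
  if (nrow(x) < 2) stop_input("need at least 2 samples")
  args <- spec_to_glmnet_args(spec, ncol(x))
  pf_all_zero <- !is.null(args$penalty.factor) && all(args$penalty.factor == 0)
  if (pf_all_zero) {
    # nothing is penalized: the path is constant in lambda and equals the
    # unpenalized fit (glmnet itself refuses an all-zero penalty factor)
    lam_req <- args$lambda %||% 1
    args$penalty.factor <- NULL
    args$lambda <- c(1e6, 0)
    fit <- do.call(glmnet::glmnet,
                   c(list(x = x, y = y, family = family), args))
    L <- length(lam_req)
    out <- structure(
      list(lambda = lam_req,
           a0 = rep(fit$a0[2], L),
           beta = matrix(fit$beta[, 2], ncol(x), L),
           df = rep(fit$df[2], L),
           converged = fit$jerr == 0,
           family = family, spec = spec, glmnet_fit = fit),
      class = "ps_path")
    return(out)
  }
  fit <- do.call(glmnet::glmnet,
                 c(list(x = x, y = y, family = family), args))
  beta <- as.matrix(fit$beta)
  structure(
    list(lambda = fit$lambda,
         a0 = as.numeric(fit$a0),
         beta = beta,
         df = fit$df,
         converged = fit$jerr == 0,
         family = family,
         spec = spec,
         glmnet_fit = fit),
    class = "ps_path")
}

#' Per-lambda penalized deviance of a fitted path
#'
#' Mean in-sample deviance plus the elastic-net penalty term actually
#' optimized at each lambda (respecting the solver's response-scaling
#' convention for the gaussian ridge part, see [penalty_spec()]), useful
#' for monotonicity diagnostics.
#'
#' @param path a `"ps_path"` object.
#' @param x,y the data the path was fitted on.
#' @return Numeric vector, one value per lambda.
#' @export
path_objective <- function(path, x, y) {
  eta <- sweep(x %*% path$beta, 2, path$a0, "+")
  dev <- colMeans(obs_deviance(y, eta, path$family)) / 2
  pf <- path$spec$penalty_factor %||% rep(1, nrow(path$beta))
  pf <- rep_len(pf, nrow(path$beta))
  a <- path$spec$alpha
  l2_scale <- if (path$family == "gaussian") sqrt(mean((y - mean(y))^2)) else 1
  pen <- vapply(seq_along(path$lambda), function(l) {
    b <- path$beta[, l]
    path$lambda[l] * sum(pf * (a * abs(b) + (1 - a) / 2 * b^2 / l2_scale))
  }, numeric(1))
  dev + pen
}

#' Sign-constrained maximum likelihood
#'
#' Maximizes the (epsilon-ridge-stabilized) likelihood of a gaussian or
#' binomial GLM over the orthant defined by `signs`: coefficient j is forced
#' `<= 0` when `signs[j] == -1`, `>= 0` when `+1`, and exactly 0 when `0`.
#' The intercept is unconstrained. A fixed tiny ridge penalty (`eps`, on the
#' internally standardized scale) guarantees a unique bounded optimum when
#' p >= n or under binomial separation; the solution is obtained as the end
#' of a warm-started constrained ridge path.
#'
#' @param x numeric feature matrix (n x p).
#' @param y response vector.
#' @param family `"gaussian"` or `"binomial"`.
#' @param signs integer p-vector in {-1, 0, +1}.
#' @param eps ridge stabilizer at the end of the path (default 1e-8).
#' @param nsteps number of warm-start steps on the internal path.
#' @return A list with `intercept`, `slopes` (length p, zeros where
#'   `signs == 0`), `deviance` (mean in-sample deviance), `converged`, and
#'   `separated` (binomial fits with huge linear predictors are flagged,
#'   not rejected).
#' @export
fit_sign_constrained_ml <- function(x, y, family = c("gaussian", "binomial"),
                                    signs, eps = 1e-8, nsteps = 30) {
  family <- match.arg(family)
  x <- check_feature_matrix(x)
  y <- check_response(y, family)
  check_conformable(x, y)
  p <- ncol(x)
  signs <- as.integer(rep_len(signs, p))
  if (!all(signs %in% c(-1L, 0L, 1L)))
    stop_input("'signs' must contain only -1, 0, +1")

  out <- list(intercept = null_intercept(y, family),
              slopes = numeric(p), lambda = eps,
              converged = TRUE, separated = FALSE)
  active <- which(signs != 0L)
  if (length(active) == 0L) {
    out$deviance <- mean(obs_deviance(y, rep(out$intercept, length(y)), family))
    return(out)
  }

  xa <- x[, active, drop = FALSE]
  # glmnet needs >= 2 columns; pad single-column problems with a zero column
  pad <- ncol(xa) == 1L
  if (pad) xa <- cbind(xa, 0)
  sg <- signs[active]
  lower <- ifelse(sg < 0, -Inf, 0)
  upper <- ifelse(sg > 0, Inf, 0)
  if (pad) { lower <- c(lower, 0); upper <- c(upper, 0) }

  # Warm-started ridge path from heavy shrinkage down to the stabilizer.
  xs <- scale(xa)
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  r0 <- y - mean(y)
  lamtop <- max(abs(crossprod(xs, r0))) / length(y) / 0.001
  lamtop <- max(lamtop, eps * 10)
  lam <- exp(seq(log(lamtop), log(eps), length.out = nsteps))

  fit <- tryCatch(
    glmnet::glmnet(xa, y, family = family, alpha = 0, lambda = lam,
                   lower.limits = lower, upper.limits = upper,
                   thresh = 1e-10, maxit = 1e6),
    error = function(e) NULL)
  if (is.null(fit)) {
    out$converged <- FALSE
    out$deviance <- mean(obs_deviance(y, rep(out$intercept, length(y)), family))
    return(out)
  }
  l <- length(fit$lambda)
  b <- as.numeric(fit$beta[, l])
  if (pad) b <- b[1]
  out$intercept <- as.numeric(fit$a0[l])
  out$slopes[active] <- b
  # clamp solver dust that crosses the orthant boundary
  out$slopes[signs > 0 & out$slopes < 0] <- 0
  out$slopes[signs < 0 & out$slopes > 0] <- 0
  eta <- as.numeric(out$intercept + x %*% out$slopes)
  out$deviance <- mean(obs_deviance(y, eta, family))
  out$converged <- fit$jerr == 0 && l == length(lam)
  if (family == "binomial" && max(abs(eta)) > 30) out$separated <- TRUE
  out
}
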