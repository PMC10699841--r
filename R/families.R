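# Family abstraction: link functions and deviance for the two supported
# response types. Binomial responses are coded in {0,1}; gaussian responses
# are finite reals.

PS_FAMILIES <- c("gaussian", "binomial")

check_family <- function(family) {
  family <- match.arg(family, PS_FAMILIES)
  family
}

check_response <- function(y, family) {
  y <- as.numeric(y)
  if (anyNA(y) || any(!is.finite(y)))
    stop_input("response contains missing or non-finite values")
  if (family == "binomial" && !all(y %in% c(0, 1)))
    stop_input("binomial responses must be coded 0/1")
  y
}

#' Inverse link function
#'
#' Identity for the gaussian family, inverse logit for the binomial family.
#'
#' @param eta numeric vector of linear predictors.
#' @param family `"gaussian"` or `"binomial"`.
#' @return Numeric vector of expected values (probabilities for binomial).
#' @export
linkinv <- function(eta, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  if (family == "gaussian") as.numeric(eta) else stats::plogis(as.numeric(eta))
}

# Per-observation deviance contribution on the linear-predictor scale.
# gaussian: squared error; binomial: -2 log-likelihood with probabilities
# clamped away from 0/1 so that separated fits stay finite.
obs_deviance <- function(y, eta, family) {
  if (family == "gaussian") {
    (y - eta)^2
  } else {
    p <- stats::plogis(eta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -2 * (y * log(p) + (1 - y) * log(1 - p))
  }
}

# Intercept of the empty (covariate-free) model.
null_intercept <- function(y, family) {
  if (family == "gaussian") mean(y) else {
    prev <- mean(y)
    prev <- pmin(pmax(prev, 1e-12), 1 - 1e-12)
    stats::qlogis(prev)
  }
}
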