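# Independent oracles used to cross-check the package's solvers. These are
# deliberately implemented through different routes than the package code
# (generic optimizers on the original parametrizations, closed forms, PAVA),
# so agreement is evidence of correctness rather than tautology.

# Pool-adjacent-violators: least-squares nondecreasing fit with unit weights.
pava <- function(v) {
  n <- length(v)
  nv <- numeric(n); nw <- numeric(n); sz <- integer(n); top <- 0
  for (i in seq_len(n)) {
    top <- top + 1; nv[top] <- v[i]; nw[top] <- 1; sz[top] <- 1
    while (top > 1 && nv[top - 1] > nv[top]) {
      m <- (nv[top - 1] * nw[top - 1] + nv[top] * nw[top]) /
        (nw[top - 1] + nw[top])
      nw[top - 1] <- nw[top - 1] + nw[top]
      sz[top - 1] <- sz[top - 1] + sz[top]
      nv[top - 1] <- m
      top <- top - 1
    }
  }
  out <- numeric(n); pos <- 1
  for (k in seq_len(top)) {
    out[pos:(pos + sz[k] - 1)] <- nv[k]
    pos <- pos + sz[k]
  }
  out
}

# Euclidean projection onto the sign- and order-constrained cone: isotonic
# regression in the z-order, then clipping to the (order-compatible) sign
# boxes; zero-prior coordinates are pinned at 0.
proj_iso_cone <- function(g, z) {
  ord <- order(z)
  gp <- numeric(length(g))
  gp[ord] <- pava(g[ord])
  gp[z > 0] <- pmax(gp[z > 0], 0)
  gp[z < 0] <- pmin(gp[z < 0], 0)
  gp[z == 0] <- 0
  gp
}

# Projected-gradient maximum likelihood on the ORIGINAL gamma
# parametrization (intercept free), independent of the cumulative-sum
# reformulation used by the package.
oracle_isotonic <- function(x, y, z, family, iters = 20000) {
  n <- nrow(x); p <- ncol(x)
  L <- (if (family == "gaussian") 1 else 0.25) * norm(cbind(1, x), "2")^2 / n
  par <- c(if (family == "gaussian") mean(y) else qlogis(mean(y)), numeric(p))
  for (i in seq_len(iters)) {
    eta <- par[1] + as.numeric(x %*% par[-1])
    g <- if (family == "gaussian") (eta - y) / n else (plogis(eta) - y) / n
    par <- par - c(sum(g), as.numeric(crossprod(x, g))) / L
    par[-1] <- proj_iso_cone(par[-1], z)
  }
  list(intercept = par[1], gamma = par[-1])
}

# Generic box-constrained penalized GLM oracle via L-BFGS-B. The l1 term is
# handled only where the box fixes the coefficient sign (which is all the
# package's constrained-lasso use cases), keeping the objective smooth.
oracle_penalized <- function(x, y, family, alpha = 0, lambda = 0,
                             lower = rep(-Inf, ncol(x)),
                             upper = rep(Inf, ncol(x)),
                             pf = rep(1, ncol(x))) {
  n <- nrow(x); p <- ncol(x)
  sgn <- ifelse(lower >= 0, 1, ifelse(upper <= 0, -1, 0))
  if (alpha > 0 && lambda > 0 && any(sgn == 0 & pf > 0))
    stop("oracle needs sign-fixed boxes for l1 terms")
  obj <- function(par) {
    b0 <- par[1]; b <- par[-1]
    eta <- as.numeric(b0 + x %*% b)
    dev <- if (family == "gaussian") mean((y - eta)^2) / 2
    else {
      pr <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
      -mean(y * log(pr) + (1 - y) * log(1 - pr))
    }
    dev + lambda * sum(pf * (alpha * sgn * b + (1 - alpha) / 2 * b^2))
  }
  gr <- function(par) {
    b0 <- par[1]; b <- par[-1]
    eta <- as.numeric(b0 + x %*% b)
    g <- if (family == "gaussian") (eta - y) / n else (plogis(eta) - y) / n
    c(sum(g),
      as.numeric(crossprod(x, g)) + lambda * pf * (alpha * sgn + (1 - alpha) * b))
  }
  start <- c(if (family == "gaussian") mean(y) else qlogis(mean(pmax(pmin(y, 1), 0))),
             numeric(p))
  fit <- stats::optim(start, obj, gr, method = "L-BFGS-B",
                      lower = c(-Inf, lower), upper = c(Inf, upper),
                      control = list(maxit = 5000, factr = 10))
  list(intercept = fit$par[1], slopes = fit$par[-1], value = fit$value)
}

# Small reproducible regression problems.
make_gaussian <- function(n, p, s = min(5, p), seed = 1, beta_scale = 0.6) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  beta <- c(rep(beta_scale, s), rep(0, p - s))
  list(x = x, beta = beta, y = as.numeric(x %*% beta + rnorm(n)))
}

make_binomial <- function(n, p, s = min(5, p), seed = 1, beta_scale = 0.8) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  beta <- c(rep(beta_scale, s), rep(0, p - s))
  list(x = x, beta = beta,
       y = rbinom(n, 1, plogis(as.numeric(x %*% beta))))
}

# Fig-1-style calibration benchmark: iid gaussian features, trimmed-normal
# prior effects, six truth-vs-prior relationships, noise variance = Var(eta).
calibration_battery <- function(seed, n = 200, p = 500) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  z <- qnorm(runif(p, 0.01, 0.99))
  betas <- list(
    z,
    sign(z) * sqrt(abs(z)),
    sign(z) * z^2,
    ifelse(z > 0, z, 0),
    as.numeric(z > 1),
    ifelse(z <= 0, -abs(z), z^2))
  vapply(betas, function(b) {
    eta <- as.numeric(x %*% b)
    y <- eta + rnorm(n, sd = sd(eta))
    e <- exponential_calibrate(x, y, z, "gaussian")
    i <- isotonic_calibrate(x, y, z, "gaussian")
    c(exp = mean((e$gamma - b)^2), iso = mean((i$gamma - b)^2))
  }, numeric(2))
}
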