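# Independent oracles, kept deliberately naive: direct formulas and plain
# enumeration, no log-space tricks, no reuse of package internals.

# Wakefield ABF evaluated directly (not in log space).
oracle_abf <- function(beta, se, prior_sd) {
  V <- se^2; W <- prior_sd^2
  r <- W / (V + W)
  sqrt(1 - r) * exp(0.5 * r * (beta / se)^2)
}

# Single-causal-variant colocalization posteriors by explicit enumeration
# of every configuration (feasible for small regions).
oracle_coloc <- function(beta1, se1, beta2, se2, priors,
                         sd1 = priors$prior_sd_quant, sd2 = priors$prior_sd_quant) {
  a1 <- oracle_abf(beta1, se1, sd1)
  a2 <- oracle_abf(beta2, se2, sd2)
  n <- length(a1)
  s0 <- 1
  s1 <- priors$p1 * sum(a1)
  s2 <- priors$p2 * sum(a2)
  s3 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) s3 <- s3 + priors$p1 * priors$p2 * a1[i] * a2[j]
  }
  s4 <- priors$p12 * sum(a1 * a2)
  s <- c(s0, s1, s2, s3, s4)
  setNames(s / sum(s), c("pp_h0", "pp_h1", "pp_h2", "pp_h3", "pp_h4"))
}

# Weighted least squares through the origin via the closed-form normal
# equation; returns estimate and fixed-effect SE.
oracle_wls_origin <- function(x, y, w) {
  est <- sum(w * x * y) / sum(w * x^2)
  list(estimate = est, se_fixed = sqrt(1 / sum(w * x^2)),
       q = sum(w * (y - est * x)^2))
}

# Weighted least squares with intercept via explicit 2x2 normal equations.
oracle_wls_intercept <- function(x, y, w) {
  X <- cbind(1, x)
  A <- t(X) %*% (w * X)
  b <- t(X) %*% (w * y)
  coef <- solve(A, b)
  fitted <- drop(X %*% coef)
  list(intercept = coef[1], slope = coef[2],
       v_fixed = solve(A), q = sum(w * (y - fitted)^2))
}

# Multivariable WLS through the origin, K columns.
oracle_mv_wls <- function(X, y, w) {
  A <- t(X) %*% (w * X)
  est <- drop(solve(A, t(X) %*% (w * y)))
  list(estimate = est, v_fixed = solve(A),
       q = sum(w * (y - drop(X %*% est))^2))
}

# Weighted median via the piecewise-linear weighted CDF and stats::approx,
# midpoint convention.
oracle_weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cdf <- cumsum(w) - w / 2
  if (cdf[1] >= 0.5) return(x[1])
  if (cdf[length(cdf)] <= 0.5) return(x[length(x)])
  approx(cdf, x, xout = 0.5, ties = "ordered")$y
}

# Penalised weighted median replayed step by step.
oracle_penalised_wm <- function(ratio, w, penalty = 20) {
  est0 <- oracle_weighted_median(ratio, w)
  qi <- pchisq(w * (ratio - est0)^2, df = 1, lower.tail = FALSE)
  oracle_weighted_median(ratio, w * pmin(1, penalty * qi))
}
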