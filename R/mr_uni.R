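#' @title Univariable two-sample MR estimators
#' @description Inverse-variance weighted, MR-Egger, weighted median and
#'   penalised weighted median estimators, all operating on harmonised
#'   SNP-exposure / SNP-outcome pairs. Estimates are on the outcome scale
#'   per SD (or unit) of exposure; for binary outcomes on the log-odds
#'   scale, `exp(estimate)` is the odds ratio.
#' @name mr_uni
NULL

mr_result <- function(method, n_snp, estimate, se, cochran_q = NA_real_,
                      q_df = NA_real_, egger_intercept = NA_real_,
                      egger_intercept_se = NA_real_, egger_intercept_p = NA_real_,
                      seed = NA_integer_) {
  z <- estimate / se
  structure(data.frame(
    method = method, n_snp = n_snp, estimate = estimate, se = se,
    ci_low = estimate - stats::qnorm(0.975) * se,
    ci_high = estimate + stats::qnorm(0.975) * se,
    pvalue = 2 * stats::pnorm(-abs(z)),
    cochran_q = cochran_q, q_df = q_df,
    egger_intercept = egger_intercept,
    egger_intercept_se = egger_intercept_se,
    egger_intercept_p = egger_intercept_p,
    seed = seed,
    stringsAsFactors = FALSE
  ), class = c("mr_result", "data.frame"))
}

pairs_matrix <- function(pairs) {
  p <- retained(pairs)
  if (any(is.na(p$beta_outcome))) p <- p[!is.na(p$beta_outcome), , drop = FALSE]
  p
}

#' Inverse-variance weighted estimate of the causal effect
#'
#' Weighted least squares of outcome betas on exposure betas through the
#' origin, with weights `1/se_outcome^2`. Under `model = "random"` (the
#' default) the standard error is inflated by the multiplicative
#' random-effects factor `max(1, sqrt(Q/(L-1)))`, so heterogeneity widens
#' but never narrows the interval; `model = "fixed"` reports the
#' fixed-effect SE. With a single SNP the estimate is the Wald ratio with
#' the first-order delta-method SE `se_outcome/|beta_exposure|`.
#'
#' @param pairs A `harmonised_pairs` data.frame (dropped rows are ignored).
#' @param model `"random"` or `"fixed"` effects SE.
#' @return An `mr_result` one-row data.frame with estimate, SE, 95% CI,
#'   p-value, Cochran's Q and its df (`n_snp - 1`).
#' @export
ivw <- function(pairs, model = c("random", "fixed")) {
  model <- match.arg(model)
  p <- pairs_matrix(pairs)
  if (nrow(p) == 0) stop("no retained SNPs", call. = FALSE)
  if (all(p$beta_exposure == 0)) stop("all exposure betas are zero", call. = FALSE)
  if (nrow(p) == 1) {
    est <- p$beta_outcome / p$beta_exposure
    se <- p$se_outcome / abs(p$beta_exposure)
    return(mr_result("Wald ratio", 1L, est, se))
  }
  w <- 1 / p$se_outcome^2
  fit <- stats::lm(beta_outcome ~ beta_exposure - 1, data = p, weights = w)
  est <- unname(stats::coef(fit)[1])
  q <- sum(w * stats::residuals(fit)^2)
  q_df <- nrow(p) - 1L
  se_fixed <- sqrt(1 / sum(w * p$beta_exposure^2))
  phi <- if (model == "random") max(1, sqrt(q / q_df)) else 1
  mr_result(paste0("IVW (", model, ")"), nrow(p), est, phi * se_fixed,
            cochran_q = q, q_df = q_df)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with an
#' intercept, weights `1/se_outcome^2`, after re-orienting every SNP so its
#' exposure beta is positive (the InSIDE convention). The slope is the
#' causal estimate; the intercept estimates directional pleiotropy and is
#' reported with its own SE and p-value. SEs use the multiplicative
#' random-effects factor `max(1, sqrt(Q/(L-2)))`.
#'
#' @inheritParams ivw
#' @return An `mr_result` row with `egger_intercept` fields populated and
#'   `q_df = n_snp - 2`.
#' @export
egger <- function(pairs, model = c("random", "fixed")) {
  model <- match.arg(model)
  p <- pairs_matrix(pairs)
  if (nrow(p) < 3) stop("MR-Egger needs at least 3 SNPs", call. = FALSE)
  flip <- sign(p$beta_exposure)
  flip[flip == 0] <- 1
  bx <- p$beta_exposure * flip
  by <- p$beta_outcome * flip
  w <- 1 / p$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  q <- sum(w * stats::residuals(fit)^2)
  q_df <- nrow(p) - 2L
  phi <- if (model == "random") max(1, sqrt(q / q_df)) else 1
  X <- cbind(1, bx)
  v_fixed <- solve(crossprod(X * sqrt(w)))
  se_slope <- phi * sqrt(v_fixed[2, 2])
  se_int <- phi * sqrt(v_fixed[1, 1])
  int <- unname(stats::coef(fit)[1])
  res <- mr_result(paste0("MR-Egger (", model, ")"), nrow(p),
                   unname(stats::coef(fit)[2]), se_slope,
                   cochran_q = q, q_df = q_df,
                   egger_intercept = int, egger_intercept_se = se_int,
                   egger_intercept_p = 2 * stats::pnorm(-abs(int / se_int)))
  res
}

ratio_estimates <- function(p, second_order = FALSE) {
  keep <- p$beta_exposure != 0
  if (!all(keep)) {
    warning(sum(!keep), " SNP(s) with zero exposure beta dropped (ratio undefined)")
    p <- p[keep, , drop = FALSE]
  }
  ratio <- p$beta_outcome / p$beta_exposure
  se <- p$se_outcome / abs(p$beta_exposure)
  if (second_order) {
    se <- sqrt(se^2 + p$beta_outcome^2 * p$se_exposure^2 / p$beta_exposure^4)
  }
  list(p = p, ratio = ratio, se = se)
}

# Weighted median of `x` with weights `w`: linear interpolation of the
# weighted empirical CDF at 0.5, midpoint convention (mass centred on each
# order statistic).
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w) - 0.5 * w
  if (cw[1] >= 0.5) return(x[1])
  if (cw[length(cw)] <= 0.5) return(x[length(x)])
  below <- max(which(cw < 0.5))
  x[below] + (x[below + 1] - x[below]) * (0.5 - cw[below]) / (cw[below + 1] - cw[below])
}

wm_bootstrap_se <- function(p, n_boot, seed, point_fun) {
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(nrow(p), p$beta_exposure, p$se_exposure)
    by <- stats::rnorm(nrow(p), p$beta_outcome, p$se_outcome)
    point_fun(bx, by, p)
  }, numeric(1))
  stats::sd(reps)
}

#' Weighted median estimator
#'
#' Per-SNP Wald ratios are ordered and the estimate is the median of their
#' weighted empirical distribution (inverse-variance weights from the
#' first-order delta-method ratio SE; linear interpolation at cumulative
#' weight 0.5 with the midpoint convention). Consistent when at least half
#' the weight comes from valid instruments. The SE comes from a parametric
#' bootstrap resampling both betas from their sampling distributions.
#'
#' @inheritParams ivw
#' @param n_boot Bootstrap replicates for the SE.
#' @param seed RNG seed (mandatory; recorded in the result).
#' @param second_order Use the second-order delta-method ratio variance.
#' @return An `mr_result` row.
#' @export
weighted_median <- function(pairs, n_boot = 1000, seed, second_order = FALSE) {
  if (missing(seed)) stop("seed is required for the bootstrap SE", call. = FALSE)
  p <- pairs_matrix(pairs)
  r <- ratio_estimates(p, second_order)
  if (nrow(r$p) < 3) stop("weighted median needs at least 3 usable SNPs", call. = FALSE)
  w <- 1 / r$se^2
  est <- weighted_median_point(r$ratio, w)
  point_fun <- function(bx, by, pp) {
    keep <- bx != 0
    ratio <- by[keep] / bx[keep]
    se <- pp$se_outcome[keep] / abs(bx[keep])
    weighted_median_point(ratio, 1 / se^2)
  }
  se <- wm_bootstrap_se(r$p, n_boot, seed, point_fun)
  mr_result("Weighted median", nrow(r$p), est, se, seed = as.integer(seed))
}

#' Penalised weighted median estimator
#'
#' Starts from the plain weighted median, scores each SNP's heterogeneity
#' contribution `Q_i = w_i (ratio_i - estimate)^2`, converts it to a
#' one-sided chi-square(1) upper-tail probability `q_i`, down-weights
#' outliers with `w_i * min(1, penalty * q_i)` and recomputes the weighted
#' median. Homogeneous data are untouched (all `penalty * q_i >= 1`).
#'
#' @inheritParams weighted_median
#' @param penalty Penalisation constant (default 20, the published
#'   convention).
#' @return An `mr_result` row.
#' @export
penalised_weighted_median <- function(pairs, penalty = 20, n_boot = 1000, seed,
                                      second_order = FALSE) {
  if (missing(seed)) stop("seed is required for the bootstrap SE", call. = FALSE)
  p <- pairs_matrix(pairs)
  r <- ratio_estimates(p, second_order)
  if (nrow(r$p) < 3) stop("penalised weighted median needs at least 3 usable SNPs",
                          call. = FALSE)
  w <- 1 / r$se^2
  pen_w <- function(ratio, w) {
    est0 <- weighted_median_point(ratio, w)
    qi <- stats::pchisq(w * (ratio - est0)^2, df = 1, lower.tail = FALSE)
    w * pmin(1, penalty * qi)
  }
  est <- weighted_median_point(r$ratio, pen_w(r$ratio, w))
  point_fun <- function(bx, by, pp) {
    keep <- bx != 0
    ratio <- by[keep] / bx[keep]
    se <- pp$se_outcome[keep] / abs(bx[keep])
    w <- 1 / se^2
    weighted_median_point(ratio, pen_w(ratio, w))
  }
  se <- wm_bootstrap_se(r$p, n_boot, seed, point_fun)
  mr_result("Penalised weighted median", nrow(r$p), est, se, seed = as.integer(seed))
}

#' Run all univariable estimators on one harmonised pair set
#'
#' @inheritParams weighted_median
#' @param methods Subset of `c("ivw", "egger", "weighted_median",
#'   "penalised_weighted_median")`.
#' @return `mr_result` data.frame, one row per method. Methods whose
#'   preconditions fail (e.g. fewer than 3 SNPs) are omitted with a warning.
#' @export
mr_all <- function(pairs, seed, n_boot = 1000,
                   methods = c("ivw", "egger", "weighted_median",
                               "penalised_weighted_median")) {
  runs <- list(
    ivw = function() ivw(pairs),
    egger = function() egger(pairs),
    weighted_median = function() weighted_median(pairs, n_boot = n_boot, seed = seed),
    penalised_weighted_median = function()
      penalised_weighted_median(pairs, n_boot = n_boot, seed = seed)
  )
  out <- lapply(methods, function(m) {
    tryCatch(runs[[m]](), error = function(e) {
      warning(m, " skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  class(out) <- c("mr_result", "data.frame")
  out
}

#' Odds-ratio view of MR results
#' @param x An `mr_result` data.frame (log-odds scale estimates).
#' @return data.frame with `or`, `or_ci_low`, `or_ci_high` appended.
#' @export
as_odds_ratios <- function(x) {
  x$or <- exp(x$estimate)
  x$or_ci_low <- exp(x$ci_low)
  x$or_ci_high <- exp(x$ci_high)
  x
}
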