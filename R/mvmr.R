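#' Build the PPA4-weighted multivariable MR design
#'
#' Takes one instrument set per tissue, forms the union of their SNPs
#' (deduplicated by rsid), harmonises the union against the outcome, and
#' constructs the weighted exposure matrix `B*` with
#' `B*[i, t] = beta_exposure[i] * PPA4[i, t]`. A SNP's PPA4 in a tissue is
#' its value in that tissue's instrument set if selected there, otherwise
#' looked up in `ppa4_lookup` (the colocalization evidence for the SNP's
#' locus in the other tissue), otherwise 0 — so a variant with no
#' colocalization evidence in a tissue contributes nothing to that tissue's
#' column. Exposure standard errors are carried unmodified: the weighting
#' shrinks the signal a SNP contributes, not its sampling uncertainty.
#'
#' @param sets Named list of `instrument_set` data.frames, one per tissue;
#'   names are the tissue labels (column order of the design).
#' @param exposure `sumstats` for the exposure, used to resolve betas/SEs
#'   uniformly across tissues.
#' @param outcome `sumstats` for the outcome; harmonisation runs through
#'   [harmonise()] and SNPs dropped there are excluded from the design.
#' @param ppa4_lookup Optional data.frame (`rsid`, `tissue`, `ppa4`) giving
#'   cross-tissue posteriors below the selection threshold; the maximum per
#'   (rsid, tissue) is used.
#' @param ... Passed to [harmonise()].
#' @return An `mvmr_input` list: `rsid`, `tissues`, `bstar` (L x K matrix),
#'   `ppa4` (L x K), `beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome`.
#' @export
build_weighted_design <- function(sets, exposure, outcome, ppa4_lookup = NULL, ...) {
  stopifnot(is.list(sets), length(sets) >= 1)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("instrument sets must be a named list (tissue labels)", call. = FALSE)
  }
  tissues <- names(sets)
  union_rsid <- unique(unlist(lapply(sets, function(s) s$rsid)))
  if (length(union_rsid) == 0) stop("empty instrument union", call. = FALSE)
  miss <- setdiff(union_rsid, exposure$rsid)
  if (length(miss) > 0) {
    stop("instrument(s) absent from exposure table: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  exp_sub <- restat(exposure[match(union_rsid, exposure$rsid), , drop = FALSE], exposure)
  pairs <- harmonise(exp_sub, outcome, ...)
  kept <- retained(pairs)
  if (nrow(kept) == 0) stop("no SNPs retained after harmonisation", call. = FALSE)

  L <- nrow(kept); K <- length(tissues)
  ppa4 <- matrix(0, L, K, dimnames = list(kept$rsid, tissues))
  for (t in tissues) {
    s <- sets[[t]]
    hit <- match(kept$rsid, s$rsid)
    ppa4[!is.na(hit), t] <- s$ppa4[hit[!is.na(hit)]]
    if (!is.null(ppa4_lookup)) {
      lk <- ppa4_lookup[ppa4_lookup$tissue == t, , drop = FALSE]
      if (nrow(lk) > 0) {
        agg <- tapply(lk$ppa4, lk$rsid, max)
        fill <- is.na(hit) & kept$rsid %in% names(agg)
        ppa4[fill, t] <- agg[kept$rsid[fill]]
      }
    }
  }
  bstar <- kept$beta_exposure * ppa4
  zero_col <- colSums(abs(bstar)) == 0
  if (any(zero_col)) {
    stop("weighted exposure column entirely zero for tissue(s): ",
         paste(tissues[zero_col], collapse = ", "), call. = FALSE)
  }
  structure(list(
    rsid = kept$rsid, tissues = tissues,
    bstar = bstar, ppa4 = ppa4,
    beta_exposure = kept$beta_exposure, se_exposure = kept$se_exposure,
    beta_outcome = kept$beta_outcome, se_outcome = kept$se_outcome
  ), class = "mvmr_input")
}

#' Assemble an `mvmr_input` directly from matrices
#'
#' Low-level constructor used by the simulation engine and tests, bypassing
#' file harmonisation. All vectors must share length L; `bstar` is formed as
#' `beta_exposure * ppa4` column-wise.
#'
#' @param rsid SNP identifiers.
#' @param beta_exposure,se_exposure Exposure estimates.
#' @param beta_outcome,se_outcome Outcome estimates, already aligned.
#' @param ppa4 L x K matrix of per-tissue posteriors; column names are the
#'   tissue labels.
#' @return An `mvmr_input`.
#' @export
mvmr_input <- function(rsid, beta_exposure, se_exposure,
                       beta_outcome, se_outcome, ppa4) {
  ppa4 <- as.matrix(ppa4)
  stopifnot(length(beta_exposure) == nrow(ppa4),
            length(beta_outcome) == nrow(ppa4),
            all(ppa4 >= 0), all(ppa4 <= 1))
  if (is.null(colnames(ppa4))) colnames(ppa4) <- paste0("tissue", seq_len(ncol(ppa4)))
  rownames(ppa4) <- rsid
  structure(list(
    rsid = rsid, tissues = colnames(ppa4),
    bstar = beta_exposure * ppa4, ppa4 = ppa4,
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    beta_outcome = beta_outcome, se_outcome = se_outcome
  ), class = "mvmr_input")
}

design_condition_number <- function(X, w) {
  s <- svd(X * sqrt(w), nu = 0, nv = 0)$d
  if (min(s) == 0) Inf else max(s) / min(s)
}

#' Multivariable IVW estimation of tissue-level effects
#'
#' Weighted least squares of outcome betas on all weighted exposure columns
#' jointly, no intercept, weights `1/se_outcome^2`. Each coefficient is the
#' direct contribution of one tissue-instrumented exposure conditional on
#' the others. SEs use the multiplicative random-effects factor
#' `max(1, sqrt(Q/(L-K)))` (`model = "fixed"` disables it). A weighted
#' design with condition number above `cond_limit` aborts with a
#' "collinear exposures" error rather than returning unstable estimates.
#'
#' @param input An `mvmr_input`.
#' @param model `"random"` or `"fixed"` effects SE.
#' @param cond_limit Condition-number guard (default 1e8).
#' @return An `mvmr_result` data.frame, one row per tissue: `tissue`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `pvalue`, `n_snp`, `cochran_q`,
#'   `q_df`, `conditional_f`.
#' @export
mvmr_ivw <- function(input, model = c("random", "fixed"), cond_limit = 1e8) {
  model <- match.arg(model)
  X <- input$bstar
  L <- nrow(X); K <- ncol(X)
  if (L < K + 1) stop("need at least K+1 SNPs for K exposures", call. = FALSE)
  w <- 1 / input$se_outcome^2
  if (design_condition_number(X, w) > cond_limit) {
    stop("collinear exposures: weighted design is numerically singular",
         call. = FALSE)
  }
  Xw <- X * sqrt(w)
  yw <- input$beta_outcome * sqrt(w)
  xtx <- crossprod(Xw)
  est <- drop(solve(xtx, crossprod(Xw, yw)))
  resid <- input$beta_outcome - drop(X %*% est)
  q <- sum(w * resid^2)
  q_df <- L - K
  phi <- if (model == "random" && q_df > 0) max(1, sqrt(q / q_df)) else 1
  se <- phi * sqrt(diag(solve(xtx)))
  cf <- tryCatch(conditional_f(input),
                 error = function(e) stats::setNames(rep(NA_real_, K), input$tissues))
  z <- est / se
  structure(data.frame(
    tissue = input$tissues,
    estimate = est, se = se,
    ci_low = est - stats::qnorm(0.975) * se,
    ci_high = est + stats::qnorm(0.975) * se,
    pvalue = 2 * stats::pnorm(-abs(z)),
    n_snp = L, cochran_q = q, q_df = q_df,
    conditional_f = cf[input$tissues],
    row.names = NULL, stringsAsFactors = FALSE
  ), class = c("mvmr_result", "data.frame"), model = model)
}

#' Conditional F-statistics for instrument strength in MVMR
#'
#' For each tissue, regresses its weighted exposure column on all other
#' columns by weighted least squares with weights `1/se_exposure^2`
#' (pairwise exposure covariances taken as zero, the diagonal convention
#' used when no phenotypic covariance is supplied). The weighted residual
#' sum of squares `Q_t` measures the signal unique to that tissue, and
#' `F_t = Q_t / (L - K + 1)` for L SNPs and K exposures. F above 10 is the
#' conventional indication that weak-instrument bias is not a concern.
#'
#' @param input An `mvmr_input` with at least 3 SNPs.
#' @return Named numeric vector of conditional F per tissue (all `>= 0`).
#' @export
conditional_f <- function(input) {
  X <- input$bstar
  L <- nrow(X); K <- ncol(X)
  if (L < 3) stop("conditional F needs at least 3 SNPs", call. = FALSE)
  w <- 1 / input$se_exposure^2
  vapply(seq_len(K), function(t) {
    y <- X[, t]
    others <- X[, -t, drop = FALSE]
    resid <- if (ncol(others) == 0 || all(others == 0)) {
      y
    } else {
      fit <- stats::lm.wfit(x = others, y = y, w = w)
      stats::residuals(fit)
    }
    sum(w * resid^2) / (L - K + 1)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(input$tissues)
}

#' Conditional F across a grid of PPA4 selection thresholds
#'
#' Relaxing the PPA4 inclusion threshold admits variants with weaker
#' colocalization evidence, which enter the design with small weights and
#' dilute instrument strength. This helper rebuilds the weighted design at
#' each threshold and tabulates the conditional F-statistics, the basis for
#' recommending the 0.8 threshold.
#'
#' @param sets_at_thresholds Named list: threshold (as character or coerced
#'   via names) -> named list of per-tissue `instrument_set`s selected at
#'   that threshold.
#' @param exposure,outcome `sumstats` objects, as in
#'   [build_weighted_design()].
#' @param ... Passed to [build_weighted_design()].
#' @return Tidy data.frame: `threshold`, `tissue`, `conditional_f`, `n_snp`.
#' @export
ppa_threshold_sensitivity <- function(sets_at_thresholds, exposure, outcome, ...) {
  rows <- lapply(names(sets_at_thresholds), function(th) {
    input <- build_weighted_design(sets_at_thresholds[[th]], exposure, outcome, ...)
    cf <- conditional_f(input)
    data.frame(threshold = as.numeric(th), tissue = names(cf),
               conditional_f = unname(cf), n_snp = nrow(input$bstar),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
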