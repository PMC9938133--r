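#' Define a simulation study for the tissue-partitioned MVMR design
#'
#' Defaults reproduce the reference study conditions: a pool of 915
#' independent exposure loci from a GWAS of n = 700,000, true outcome
#' effects of 0.1, 0.125 and 0.15, outcome sample sizes from 10,000 to
#' 100,000, and per-tissue variance explained from 0.5% to 3%, with 86
#' adipose-like and 140 brain-like colocalizing instruments.
#'
#' @param n_snps_pool Number of independent exposure loci.
#' @param n_exposure_gwas Exposure GWAS sample size.
#' @param effect_grid True per-tissue causal effects to sweep.
#' @param n_outcome_grid Outcome GWAS sample sizes to sweep.
#' @param varexp_grid Per-tissue variance-explained fractions to sweep
#'   (each in (0, 0.05]).
#' @param n_adipose_like,n_brain_like Tissue-labelled instrument counts.
#' @param ppa4_own_shape Beta shape parameters for own-tissue PPA4,
#'   truncated to at least `ppa4_threshold`.
#' @param ppa4_cross_shape Beta shape parameters for cross-tissue and
#'   unlabelled-SNP PPA4.
#' @param ppa4_threshold Selection threshold applied when instruments are
#'   re-selected each replicate.
#' @param background_varexp Variance explained by the unlabelled remainder
#'   of the pool (loci acting through neither modelled tissue).
#' @param n_reps Replicates per grid cell.
#' @param alpha Rejection level.
#' @param seed Master seed; per-replicate child seeds are
#'   `seed + (cell_index - 1) * 1e4 + rep` with cells in lexicographic
#'   (effect, n_outcome, varexp) order.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_snps_pool = 915,
                            n_exposure_gwas = 7e5,
                            effect_grid = c(0.1, 0.125, 0.15),
                            n_outcome_grid = c(1e4, 2.5e4, 5e4, 7.5e4, 1e5),
                            varexp_grid = c(0.005, 0.01, 0.015, 0.02, 0.025, 0.03),
                            n_adipose_like = 86,
                            n_brain_like = 140,
                            ppa4_own_shape = c(8, 2),
                            ppa4_cross_shape = c(1, 9),
                            ppa4_threshold = 0.8,
                            background_varexp = 0.02,
                            n_reps = 200,
                            alpha = 0.05,
                            seed = 1L) {
  stopifnot(n_snps_pool >= n_adipose_like + n_brain_like,
            all(varexp_grid > 0), all(varexp_grid <= 0.05),
            all(effect_grid > 0), all(n_outcome_grid > 0),
            n_reps >= 1, alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "simulation_spec")
}

rbeta_trunc <- function(n, shape1, shape2, lower) {
  u <- stats::runif(n, stats::pbeta(lower, shape1, shape2), 1)
  stats::qbeta(u, shape1, shape2)
}

# Rescale effects so the realised variance explained, sum 2p(1-p) beta^2,
# hits the target exactly.
scale_to_varexp <- function(beta, maf, target) {
  realised <- sum(2 * maf * (1 - maf) * beta^2)
  if (realised == 0) return(beta)
  beta * sqrt(target / realised)
}

#' Simulate an exposure GWAS over a pool of independent loci
#'
#' Generates summary-level data directly (no individual-level genotypes).
#' Per SNP: MAF ~ Uniform(0.05, 0.5); standard error of the per-allele
#' estimate implied by allele frequency and GWAS sample size,
#' `se = 1/sqrt(2 p (1-p) n)`. The first `n_adipose_like` SNPs act through
#' adipose expression, the next `n_brain_like` through brain expression;
#' each tissue's true effects are zero-mean normal draws rescaled so the
#' variance explained, `sum 2p(1-p) beta^2`, equals that tissue's target
#' exactly. Unlabelled pool SNPs carry background effects (variance
#' `background_varexp`) and sub-threshold PPA4 in both tissues. Estimated
#' betas add Gaussian noise at the analytic SE. Own-tissue PPA4 values are
#' drawn from the truncated Beta in the spec, cross-tissue from the
#' sub-threshold Beta.
#'
#' @param spec A [simulation_spec()].
#' @param varexp Per-tissue variance explained; length 1 (shared) or 2
#'   (adipose, brain).
#' @param seed Optional seed; `NULL` uses the current RNG state (as the
#'   power grid does after seeding each replicate).
#' @return A data.frame, one row per pool SNP: `rsid`, `maf`, `tissue`
#'   (`adipose`/`brain`/`none`), `beta_true_adipose`, `beta_true_brain`,
#'   `beta_true` (total exposure effect incl. background), `beta_hat`,
#'   `se`, `ppa4_adipose`, `ppa4_brain`.
#' @export
simulate_exposure_pool <- function(spec, varexp = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(varexp) == 1) varexp <- c(varexp, varexp)
  n <- spec$n_snps_pool
  na <- spec$n_adipose_like; nb <- spec$n_brain_like
  if (na + nb > n) stop("instrument counts exceed pool size", call. = FALSE)
  maf <- stats::runif(n, 0.05, 0.5)
  tissue <- c(rep("adipose", na), rep("brain", nb), rep("none", n - na - nb))
  se <- 1 / sqrt(2 * maf * (1 - maf) * spec$n_exposure_gwas)

  bta <- numeric(n); btb <- numeric(n); bg <- numeric(n)
  ia <- tissue == "adipose"; ib <- tissue == "brain"; in_ <- tissue == "none"
  bta[ia] <- scale_to_varexp(stats::rnorm(na), maf[ia], varexp[1])
  btb[ib] <- scale_to_varexp(stats::rnorm(nb), maf[ib], varexp[2])
  if (any(in_)) {
    bg[in_] <- scale_to_varexp(stats::rnorm(sum(in_)), maf[in_], spec$background_varexp)
  }
  beta_true <- bta + btb + bg
  beta_hat <- beta_true + stats::rnorm(n, 0, se)

  ppa_a <- stats::rbeta(n, spec$ppa4_cross_shape[1], spec$ppa4_cross_shape[2])
  ppa_b <- stats::rbeta(n, spec$ppa4_cross_shape[1], spec$ppa4_cross_shape[2])
  ppa_a[ia] <- rbeta_trunc(na, spec$ppa4_own_shape[1], spec$ppa4_own_shape[2],
                           spec$ppa4_threshold)
  ppa_b[ib] <- rbeta_trunc(nb, spec$ppa4_own_shape[1], spec$ppa4_own_shape[2],
                           spec$ppa4_threshold)

  data.frame(
    rsid = sprintf("rs%04d", seq_len(n)), maf = maf, tissue = tissue,
    beta_true_adipose = bta, beta_true_brain = btb, beta_true = beta_true,
    beta_hat = beta_hat, se = se,
    ppa4_adipose = ppa_a, ppa4_brain = ppa_b,
    stringsAsFactors = FALSE
  )
}

#' Simulate an outcome GWAS given tissue-level causal effects
#'
#' The true SNP-outcome effect is `gamma_i = theta_adipose *
#' beta_true_adipose_i + theta_brain * beta_true_brain_i` (true,
#' unweighted tissue effects; unlabelled SNPs act through pathways with no
#' modelled outcome effect). Estimates add noise at
#' `se = 1/sqrt(2 p (1-p) n_outcome)`.
#'
#' @param pool Output of [simulate_exposure_pool()].
#' @param theta Length-2 true causal effects `(adipose, brain)`.
#' @param n_outcome Outcome GWAS sample size.
#' @param seed Optional seed (`NULL` = current RNG state).
#' @return data.frame: `rsid`, `gamma_true`, `beta_hat`, `se`.
#' @export
simulate_outcome <- function(pool, theta, n_outcome, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(theta) == 2)
  gamma <- theta[1] * pool$beta_true_adipose + theta[2] * pool$beta_true_brain
  se <- 1 / sqrt(2 * pool$maf * (1 - pool$maf) * n_outcome)
  data.frame(rsid = pool$rsid, gamma_true = gamma,
             beta_hat = gamma + stats::rnorm(nrow(pool), 0, se), se = se,
             stringsAsFactors = FALSE)
}

#' Weighted MVMR design from a simulated pool and outcome
#'
#' Re-selects instruments at `ppa4_threshold` (a SNP enters if either
#' tissue's PPA4 reaches it), then forms the PPA4-weighted design from the
#' estimated exposure betas.
#'
#' @param pool,outcome Outputs of [simulate_exposure_pool()] /
#'   [simulate_outcome()] on matching SNP lists.
#' @param ppa4_threshold Instrument selection threshold.
#' @return An `mvmr_input` with tissues `adipose`, `brain`.
#' @export
sim_mvmr_input <- function(pool, outcome, ppa4_threshold = 0.8) {
  if (!identical(pool$rsid, outcome$rsid)) stop("mismatched SNP lists", call. = FALSE)
  sel <- pool$ppa4_adipose >= ppa4_threshold | pool$ppa4_brain >= ppa4_threshold
  if (sum(sel) < 3) stop("fewer than 3 instruments selected", call. = FALSE)
  p <- pool[sel, , drop = FALSE]; o <- outcome[sel, , drop = FALSE]
  ppa4 <- cbind(adipose = p$ppa4_adipose, brain = p$ppa4_brain)
  # evidence below the selection threshold is retained as a weight, the
  # same convention as the applied cross-tissue lookup
  mvmr_input(p$rsid, p$beta_hat, p$se, o$beta_hat, o$se, ppa4)
}

cell_child_seed <- function(seed, cell_index, rep) {
  as.integer(seed + (cell_index - 1L) * 1e4 + rep)
}

#' Power and calibration of the tissue-partitioned MVMR design
#'
#' Sweeps the full (effect, outcome sample size, variance explained) grid.
#' Each replicate independently simulates the exposure pool, re-selects
#' instruments at the PPA4 threshold, simulates the outcome with both
#' tissue effects set to the cell's effect size, fits the weighted
#' multivariable IVW model and records rejection at `alpha`, the estimate,
#' CI coverage of the true effect and the conditional F-statistics.
#' Fully deterministic given the spec's master seed.
#'
#' @param spec A [simulation_spec()].
#' @param theta_null If `TRUE`, simulate under no causal effect
#'   (type-I-error calibration) while keeping the labelled grid.
#' @return A `power_table` data.frame: one row per
#'   (effect, n_outcome, varexp, tissue) with `rejection_rate`,
#'   `mean_estimate`, `empirical_se`, `coverage`, `mean_conditional_f`,
#'   `n_reps`.
#' @export
power_grid <- function(spec, theta_null = FALSE) {
  grid <- expand.grid(varexp = spec$varexp_grid,
                      n_outcome = spec$n_outcome_grid,
                      effect = spec$effect_grid,
                      KEEP.OUT.ATTRS = FALSE)
  # lexicographic (effect, n_outcome, varexp) cell order
  grid <- grid[order(grid$effect, grid$n_outcome, grid$varexp), , drop = FALSE]
  rows <- vector("list", nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    eff <- grid$effect[ci]; n_out <- grid$n_outcome[ci]; ve <- grid$varexp[ci]
    theta <- if (theta_null) c(0, 0) else c(eff, eff)
    rej <- est <- cov <- cf <- matrix(NA_real_, spec$n_reps, 2)
    for (r in seq_len(spec$n_reps)) {
      set.seed(cell_child_seed(spec$seed, ci, r))
      pool <- simulate_exposure_pool(spec, varexp = ve)
      out <- simulate_outcome(pool, theta, n_out)
      fit <- tryCatch(
        mvmr_ivw(sim_mvmr_input(pool, out, spec$ppa4_threshold)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rej[r, ] <- fit$pvalue < spec$alpha
      est[r, ] <- fit$estimate
      cov[r, ] <- fit$ci_low <= theta & theta <= fit$ci_high
      cf[r, ] <- fit$conditional_f
    }
    rows[[ci]] <- data.frame(
      effect = eff, n_outcome = n_out, varexp = ve,
      tissue = c("adipose", "brain"),
      rejection_rate = colMeans(rej, na.rm = TRUE),
      mean_estimate = colMeans(est, na.rm = TRUE),
      empirical_se = apply(est, 2, stats::sd, na.rm = TRUE),
      coverage = colMeans(cov, na.rm = TRUE),
      mean_conditional_f = colMeans(cf, na.rm = TRUE),
      n_reps = spec$n_reps, stringsAsFactors = FALSE
    )
  }
  structure(do.call(rbind, rows), class = c("power_table", "data.frame"))
}

#' Synthetic stand-in for the tissue-partitioned instrument tables
#'
#' Builds instrument sets that emulate the published summary structure of
#' the adult-BMI tissue-partitioned instruments: 86 adipose and 140 brain
#' variants with mean absolute exposure effects of 0.0148 and 0.0149 SD per
#' allele (exact by rescaling), standard errors implied by MAF ~
#' Uniform(0.05, 0.5) at an exposure GWAS of n = 681,275, own-tissue PPA4
#' at or above 0.8 and small cross-tissue PPA4. These are synthetic tables,
#' not the real supplementary data.
#'
#' @param n_per_tissue Named counts, default `c(adipose = 86, brain = 140)`.
#' @param mean_abs_beta Target mean |beta| per tissue.
#' @param n_gwas Exposure GWAS sample size implying the SEs.
#' @param ppa4_own_shape,ppa4_cross_shape,ppa4_threshold As in
#'   [simulation_spec()].
#' @param seed RNG seed.
#' @return List with `sets` (named list of `instrument_set`s carrying
#'   `rsid`, `beta`, `se`, `ppa4`) and `ppa4_lookup` (cross-tissue
#'   posteriors, data.frame `rsid`, `tissue`, `ppa4`).
#' @export
synthetic_instrument_tables <- function(n_per_tissue = c(adipose = 86, brain = 140),
                                        mean_abs_beta = c(adipose = 0.0148, brain = 0.0149),
                                        n_gwas = 681275,
                                        ppa4_own_shape = c(8, 2),
                                        ppa4_cross_shape = c(1, 9),
                                        ppa4_threshold = 0.8,
                                        seed = 1L) {
  set.seed(seed)
  tissues <- names(n_per_tissue)
  sets <- list(); lookup <- list()
  offset <- 0
  for (t in tissues) {
    n <- n_per_tissue[[t]]
    maf <- stats::runif(n, 0.05, 0.5)
    se <- 1 / sqrt(2 * maf * (1 - maf) * n_gwas)
    absb <- abs(stats::rnorm(n))
    absb <- absb * mean_abs_beta[[t]] / mean(absb)
    beta <- absb * sample(c(-1, 1), n, replace = TRUE)
    rsid <- sprintf("rs%s%03d", substr(t, 1, 1), seq_len(n) + offset)
    s <- data.frame(rsid = rsid, chrom = NA_character_, pos = NA_real_,
                    effect_allele = "A", other_allele = "G", eaf = maf,
                    beta = beta, se = se, pvalue = 2 * stats::pnorm(-abs(beta / se)),
                    tissue = t, gene = NA_character_,
                    ppa4 = rbeta_trunc(n, ppa4_own_shape[1], ppa4_own_shape[2],
                                       ppa4_threshold),
                    stringsAsFactors = FALSE)
    class(s) <- c("instrument_set", "data.frame")
    attr(s, "tissue") <- t
    sets[[t]] <- s
    for (other in setdiff(tissues, t)) {
      lookup[[paste(t, other)]] <- data.frame(
        rsid = rsid, tissue = other,
        ppa4 = stats::rbeta(n, ppa4_cross_shape[1], ppa4_cross_shape[2]),
        stringsAsFactors = FALSE)
    }
    offset <- offset + n
  }
  list(sets = sets, ppa4_lookup = do.call(rbind, lookup))
}

#' Mean conditional F as a function of instrument count
#'
#' Repeatedly subsamples each tissue's instrument set to a given size,
#' forms the PPA4-weighted design on the subsample union (own-tissue PPA4
#' from the set, cross-tissue from `ppa4_lookup`, absent = 0) and averages
#' the conditional F-statistics. When a count equals the full set size for
#' every tissue the value is deterministic.
#'
#' @param sets Named list of `instrument_set`s (with `beta`, `se`, `ppa4`).
#' @param counts Integer vector of per-tissue instrument counts to assess.
#' @param n_samples Subsamples per count.
#' @param seed RNG seed.
#' @param ppa4_lookup Optional cross-tissue posteriors (`rsid`, `tissue`,
#'   `ppa4`).
#' @return data.frame: `count`, `tissue`, `mean_conditional_f`, `n_samples`.
#' @export
instrument_strength_curve <- function(sets, counts, n_samples = 100, seed = 1L,
                                      ppa4_lookup = NULL) {
  set.seed(seed)
  tissues <- names(sets)
  sizes <- vapply(sets, nrow, integer(1))
  if (any(counts > min(sizes))) stop("count exceeds available instruments", call. = FALSE)
  lookup_ppa <- function(rsid, tissue) {
    if (is.null(ppa4_lookup)) return(rep(0, length(rsid)))
    lk <- ppa4_lookup[ppa4_lookup$tissue == tissue, , drop = FALSE]
    out <- lk$ppa4[match(rsid, lk$rsid)]
    ifelse(is.na(out), 0, out)
  }
  one_draw <- function(count) {
    sub <- lapply(sets, function(s) s[sample(nrow(s), count), , drop = FALSE])
    rsid <- unlist(lapply(sub, function(s) s$rsid), use.names = FALSE)
    beta <- unlist(lapply(sub, function(s) s$beta), use.names = FALSE)
    se <- unlist(lapply(sub, function(s) s$se), use.names = FALSE)
    dup <- duplicated(rsid)
    rsid <- rsid[!dup]; beta <- beta[!dup]; se <- se[!dup]
    ppa4 <- vapply(tissues, function(t) {
      own <- sub[[t]]
      v <- lookup_ppa(rsid, t)
      hit <- match(rsid, own$rsid)
      v[!is.na(hit)] <- own$ppa4[hit[!is.na(hit)]]
      v
    }, numeric(length(rsid)))
    input <- mvmr_input(rsid, beta, se, rep(0, length(rsid)),
                        rep(1, length(rsid)), ppa4)
    conditional_f(input)
  }
  rows <- lapply(counts, function(count) {
    reps <- if (all(sizes == count)) 1L else n_samples
    fs <- vapply(seq_len(reps), function(i) one_draw(count), numeric(length(tissues)))
    data.frame(count = count, tissue = tissues,
               mean_conditional_f = rowMeans(matrix(fs, nrow = length(tissues))),
               n_samples = reps, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
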