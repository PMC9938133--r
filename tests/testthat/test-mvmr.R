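test_that("weighted design puts beta x PPA4 in each tissue column, zero when absent", {
  expo <- random_sumstats(6, seed = 1)
  expo$effect_allele <- "A"; expo$other_allele <- "G"  # no palindromes
  outc2 <- expo  # identical table; harmonisation keeps everything
  sets <- list(
    adipose = data.frame(rsid = expo$rsid[1:3], ppa4 = c(0.9, 1, 0.85)),
    brain = data.frame(rsid = expo$rsid[3:5], ppa4 = c(0.95, 1, 0.8))
  )
  input <- build_weighted_design(sets, expo, outc2)
  expect_equal(dim(input$bstar), c(5, 2))  # union of the two sets
  # SNP only in the adipose set: brain column zero
  expect_equal(input$bstar[expo$rsid[1], ],
               c(adipose = 0.9 * expo$beta[1], brain = 0))
  # SNP in both sets with ppa4 = 1 in brain
  expect_equal(input$bstar[expo$rsid[4], "brain"], expo$beta[4])
  # invariant: zero ppa4 implies zero weighted beta
  expect_true(all(input$bstar[input$ppa4 == 0] == 0))
  # cross-tissue lookup fills sub-threshold evidence
  lookup <- data.frame(rsid = expo$rsid[1], tissue = "brain", ppa4 = 0.2)
  input2 <- build_weighted_design(sets, expo, outc2, ppa4_lookup = lookup)
  expect_equal(input2$ppa4[expo$rsid[1], "brain"], 0.2)
})

test_that("disjoint indicator designs decouple into per-subset univariable IVW", {
  input <- indicator_mvmr_input(n_per_tissue = 12, seed = 2, theta = c(0.3, -0.2))
  fit <- mvmr_ivw(input)
  for (k in 1:2) {
    own <- input$ppa4[, k] == 1
    p <- make_pairs(sum(own), beta_exposure = input$beta_exposure[own],
                    beta_outcome = input$beta_outcome[own],
                    se_exposure = input$se_exposure[own],
                    se_outcome = input$se_outcome[own])
    expect_equal(fit$estimate[k], ivw(p, model = "fixed")$estimate, tolerance = 1e-12)
  }
})

test_that("collinear weighted designs abort rather than report estimates", {
  set.seed(3)
  n <- 10
  bx <- rnorm(n, 0.03, 0.01)
  ppa4 <- cbind(adipose = rep(0.9, n), brain = rep(0.9, n))  # identical columns
  input <- mvmr_input(sprintf("rs%d", 1:n), bx, rep(0.003, n),
                      0.2 * bx, rep(0.01, n), ppa4)
  expect_error(mvmr_ivw(input), "collinear")
})

test_that("simulated tissue effects (0.1, 0) are recovered in the identified regime", {
  # exact recovery holds when the tissue assignment is clean (indicator
  # PPA4); continuous own-weights rescale and cross-tissue weights dilute
  # the estimates, which the power analysis quantifies instead
  spec <- simulation_spec(n_reps = 1, seed = 99)
  ests <- sapply(1:100, function(r) {
    set.seed(9000 + r)
    pool <- simulate_exposure_pool(spec, varexp = 0.02)
    pool$ppa4_adipose <- as.numeric(pool$tissue == "adipose")
    pool$ppa4_brain <- as.numeric(pool$tissue == "brain")
    out <- simulate_outcome(pool, c(0.1, 0), 1e5)
    mvmr_ivw(sim_mvmr_input(pool, out))$estimate
  })
  m <- rowMeans(ests)
  mc_se <- apply(ests, 1, sd) / sqrt(ncol(ests))
  expect_lt(abs(m[1] - 0.1), 4 * mc_se[1] + 0.1 / 40)  # 1/F attenuation slack
  expect_lt(abs(m[2] - 0), 4 * mc_se[2])
})

test_that("conditional F reduces to the closed form when there is nothing to condition on", {
  set.seed(4)
  n <- 15
  bx <- rnorm(n, 0.03, 0.01)
  sx <- runif(n, 0.002, 0.005)
  ppa4 <- cbind(adipose = runif(n, 0.8, 1), brain = rep(0, n))
  # brain column all zero: the design builder rejects it, so construct directly
  input <- mvmr_input(sprintf("rs%d", 1:n), bx, sx, rnorm(n), rep(0.01, n), ppa4)
  f <- conditional_f(input)
  w <- 1 / sx^2
  expect_equal(unname(f["adipose"]),
               sum(w * (bx * ppa4[, 1])^2) / (n - 1), tolerance = 1e-10)
})

test_that("perfectly collinear exposure columns have conditional F of zero", {
  set.seed(5)
  n <- 10
  bx <- rnorm(n, 0.03, 0.01)
  ppa4 <- cbind(a = rep(0.9, n), b = rep(0.45, n))
  input <- mvmr_input(sprintf("rs%d", 1:n), bx, rep(0.003, n),
                      rnorm(n), rep(0.01, n), ppa4)
  f <- conditional_f(input)
  expect_equal(unname(f), c(0, 0), tolerance = 1e-16)
})

test_that("scaling one tissue's PPA4 by c scales its estimate by 1/c under orthogonality", {
  input <- indicator_mvmr_input(n_per_tissue = 10, seed = 6)
  scaled <- input
  scaled$ppa4[, "adipose"] <- 0.5 * scaled$ppa4[, "adipose"]
  scaled$bstar <- scaled$beta_exposure * scaled$ppa4
  f0 <- mvmr_ivw(input, model = "fixed")
  f1 <- mvmr_ivw(scaled, model = "fixed")
  expect_equal(f1$estimate[1], f0$estimate[1] / 0.5, tolerance = 1e-10)
  expect_equal(f1$estimate[2], f0$estimate[2], tolerance = 1e-10)
})

test_that("one-tissue multivariable input reproduces univariable IVW exactly", {
  p <- make_pairs(12, seed = 7, effect = 0.3, noise = 0.01)
  input <- mvmr_input(p$rsid, p$beta_exposure, p$se_exposure,
                      p$beta_outcome, p$se_outcome,
                      cbind(adipose = rep(1, 12)))
  fit <- mvmr_ivw(input)
  ref <- ivw(p)
  expect_equal(fit$estimate, ref$estimate, tolerance = 1e-12)
  expect_equal(fit$se, ref$se, tolerance = 1e-12)
  expect_equal(fit$cochran_q, ref$cochran_q, tolerance = 1e-10)
})

test_that("multivariable estimates match the normal-equation oracle", {
  set.seed(8)
  for (s in 1:50) {
    n <- 25
    bx <- rnorm(n, 0.03, 0.01)
    ppa4 <- cbind(a = runif(n), b = runif(n))
    by <- rnorm(n, 0, 0.02)
    sy <- runif(n, 0.005, 0.02)
    input <- mvmr_input(sprintf("rs%d", 1:n), bx, rep(0.003, n), by, sy, ppa4)
    o <- oracle_mv_wls(input$bstar, by, 1 / sy^2)
    fit <- mvmr_ivw(input)
    expect_equal(fit$estimate, unname(o$estimate), tolerance = 1e-10)
    phi <- max(1, sqrt(o$q / (n - 2)))
    expect_equal(fit$se, unname(phi * sqrt(diag(o$v_fixed))), tolerance = 1e-10)
  }
})

test_that("lowering the PPA4 threshold on bimodal evidence weakens conditional F", {
  # sharply bimodal PPA4: strong colocalizers near 1, the rest near 0.3
  set.seed(9)
  n_strong <- 20; n_weak <- 30
  mk_set <- function(prefix) {
    n <- n_strong + n_weak
    data.frame(rsid = sprintf("%s%03d", prefix, 1:n),
               chrom = "1", pos = seq_len(n) * 1e6,
               effect_allele = "A", other_allele = "G", eaf = 0.3,
               beta = rnorm(n, 0, 0.02), se = rep(0.003, n), pvalue = 1e-9,
               tissue = prefix, gene = NA_character_,
               ppa4 = c(runif(n_strong, 0.92, 1), runif(n_weak, 0.2, 0.4)))
  }
  sa <- mk_set("rsa"); sb <- mk_set("rsb")
  expo <- sumstats(rbind(sa, sb)[, c("rsid", "chrom", "pos", "effect_allele",
                                     "other_allele", "eaf", "beta", "se", "pvalue")])
  outc <- expo
  sel <- function(s, th) { out <- s[s$ppa4 >= th, ]; class(out) <- c("instrument_set", "data.frame"); out }
  sets_at <- list("0.8" = list(adipose = sel(sa, 0.8), brain = sel(sb, 0.8)),
                  "0.6" = list(adipose = sel(sa, 0.6), brain = sel(sb, 0.6)),
                  "0.2" = list(adipose = sel(sa, 0.2), brain = sel(sb, 0.2)))
  tab <- ppa_threshold_sensitivity(sets_at, expo, outc)
  for (t in c("adipose", "brain")) {
    f <- tab$conditional_f[tab$tissue == t][order(-tab$threshold[tab$tissue == t])]
    expect_true(all(diff(f) <= 1e-8))
  }
  # degenerate one-threshold grid equals a direct conditional_f call
  one <- ppa_threshold_sensitivity(sets_at["0.8"], expo, outc)
  direct <- conditional_f(build_weighted_design(sets_at[["0.8"]], expo, outc))
  expect_equal(setNames(one$conditional_f, one$tissue), direct)
})
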