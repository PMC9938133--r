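test_that("reading delimited summary statistics maps columns and enforces invariants", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(SNP = c("rs1", "rs2", "rs3"), CHR = "1", BP = 1:3 * 1e6,
                   EA = "A", OA = "G", EAF = c(0.2, 0.3, 0.4),
                   BETA = c(0.1, -0.2, 0.05), SE = c(0.01, 0.02, 0.01),
                   P = c(1e-8, 1e-4, 0.5), N = 1e5)
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_sumstats(tmp, trait_name = "bmi")
  expect_s3_class(tab, "sumstats")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$rsid, c("rs1", "rs2", "rs3"))
  expect_equal(tab$beta, df$BETA)

  # invalid rows are excluded with reasons, order preserved
  df$SE[2] <- 0
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_sumstats(tmp)
  expect_equal(tab$rsid, c("rs1", "rs3"))
  expect_equal(attr(tab, "dropped")$reason, "non-positive SE")

  # optional EAF column can be absent entirely
  df2 <- df[, setdiff(names(df), "EAF")]
  df2$SE <- 0.01
  write.table(df2, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_sumstats(tmp, dialect = c(rsid = "SNP", chrom = "CHR", pos = "BP",
                                        effect_allele = "EA", other_allele = "OA",
                                        beta = "BETA", se = "SE", pvalue = "P"))
  expect_true(all(is.na(tab$eaf)))

  # dialect naming an absent required column errors
  expect_error(read_sumstats(tmp, dialect = c(rsid = "NOPE", effect_allele = "EA",
                                              other_allele = "OA", beta = "BETA",
                                              se = "SE", pvalue = "P")),
               "required column")
})

test_that("validation drops non-positive SE, bad p-values, bad EAF, identical alleles", {
  raw <- data.frame(
    rsid = paste0("rs", 1:5),
    effect_allele = c("A", "A", "A", "A", "G"),
    other_allele = c("G", "G", "G", "G", "G"),
    eaf = c(0.5, 0.5, 1.2, 0.5, 0.5),
    beta = 0.1, se = c(0.01, -1, 0.01, 0.01, 0.01),
    pvalue = c(0.5, 0.5, 0.5, 1.5, 0.5))
  tab <- sumstats(raw)
  expect_equal(tab$rsid, "rs1")
  expect_setequal(attr(tab, "dropped")$reason,
                  c("non-positive SE", "EAF outside (0,1)",
                    "p-value outside (0,1]", "identical alleles"))
})

test_that("region exclusion removes only in-region SNPs and is idempotent", {
  tab <- sumstats(data.frame(
    rsid = c("rs_in", "rs_edge_low", "rs_out_chrom", "rs_far"),
    chrom = c("6", "6", "7", "6"),
    pos = c(3e7, 24999999, 3e7, 4e7),
    effect_allele = "A", other_allele = "G",
    beta = 0.1, se = 0.01, pvalue = 1e-9))
  out <- suppressMessages(exclude_region(tab, "6", 25e6, 35e6))
  expect_setequal(out$rsid, c("rs_edge_low", "rs_out_chrom", "rs_far"))
  again <- exclude_region(out, "6", 25e6, 35e6)
  expect_identical(as.data.frame(again), as.data.frame(out))
})

test_that("clumping applies the significance threshold strictly", {
  tab <- sumstats(data.frame(
    rsid = c("rs_a", "rs_b"), chrom = "1", pos = c(1e6, 5e8),
    effect_allele = "A", other_allele = "G",
    beta = 0.1, se = 0.01, pvalue = c(6e-8, 4e-8)))
  out <- clump(tab, p_threshold = 5e-8)
  expect_equal(out$rsid, "rs_b")
})

test_that("LD-mode clumping keeps the best of a correlated pair and all independent SNPs", {
  tab <- sumstats(data.frame(
    rsid = c("rs1", "rs2", "rs3"), chrom = "1", pos = c(1e6, 1.1e6, 5e7),
    effect_allele = "A", other_allele = "G", beta = 0.1, se = 0.01,
    pvalue = c(1e-9, 1e-8, 1e-8)))
  ld <- diag(3); dimnames(ld) <- list(tab$rsid, tab$rsid)
  ld["rs1", "rs2"] <- ld["rs2", "rs1"] <- sqrt(0.5)
  out <- clump(tab, ld = ld)
  expect_setequal(out$rsid, c("rs1", "rs3"))

  ld0 <- diag(3); dimnames(ld0) <- list(tab$rsid, tab$rsid)
  expect_equal(nrow(clump(tab, ld = ld0)), 3)

  expect_error(clump(tab, ld = ld[1:2, 1:2]), "LD matrix lacks")
})

test_that("clumping is invariant to row shuffling (ties broken by rsid)", {
  set.seed(42)
  n <- 40
  tab <- sumstats(data.frame(
    rsid = sprintf("rs%03d", sample(n)), chrom = sample(c("1", "2"), n, TRUE),
    pos = sample.int(2e8, n), effect_allele = "A", other_allele = "G",
    beta = 0.1, se = 0.01,
    pvalue = sample(c(1e-9, 5e-9, 1e-10), n, TRUE)))  # heavy ties
  ref <- clump(tab, window_bp = 1e7)
  for (s in 1:5) {
    set.seed(s)
    shuf <- restat(tab[sample(nrow(tab)), ], tab)
    expect_equal(clump(shuf, window_bp = 1e7)$rsid, ref$rsid)
  }
})

test_that("harmonisation flips swapped alleles and negates the outcome beta", {
  expo <- sumstats(data.frame(rsid = "rs1", effect_allele = "A", other_allele = "G",
                              eaf = 0.3, beta = 0.10, se = 0.01, pvalue = 1e-9))
  outc <- sumstats(data.frame(rsid = "rs1", effect_allele = "G", other_allele = "A",
                              eaf = 0.7, beta = 0.05, se = 0.01, pvalue = 0.01))
  h <- harmonise(expo, outc)
  expect_equal(h$orientation, "flipped")
  expect_equal(h$beta_outcome, -0.05)
  expect_equal(h$eaf_outcome, 0.3)
})

test_that("palindromic SNPs are oriented by allele frequency or dropped", {
  # frequencies disagree in side -> orientation resolved by flipping
  expo <- sumstats(data.frame(rsid = "rs1", effect_allele = "A", other_allele = "T",
                              eaf = 0.10, beta = 0.10, se = 0.01, pvalue = 1e-9))
  outc <- sumstats(data.frame(rsid = "rs1", effect_allele = "A", other_allele = "T",
                              eaf = 0.88, beta = 0.05, se = 0.01, pvalue = 0.01))
  h <- harmonise(expo, outc, palindromic_maf_limit = 0.42)
  expect_equal(h$orientation, "flipped")
  expect_equal(h$beta_outcome, -0.05)

  # hand enumeration of the four orientations: the only frequency-consistent
  # orientation of outcome (EAF 0.88) against exposure (EAF 0.10) is the
  # strand flip, under which the outcome effect allele is the exposure other
  # allele; agreement requires negating beta
  expect_equal(h$eaf_outcome, 1 - 0.88)

  # frequencies agree in side -> kept unchanged
  outc2 <- sumstats(data.frame(rsid = "rs1", effect_allele = "A", other_allele = "T",
                               eaf = 0.12, beta = 0.05, se = 0.01, pvalue = 0.01))
  h2 <- harmonise(expo, outc2)
  expect_equal(h2$orientation, "kept")
  expect_equal(h2$beta_outcome, 0.05)

  # MAF at 0.5: frequency uninformative
  expo3 <- sumstats(data.frame(rsid = "rs1", effect_allele = "C", other_allele = "G",
                               eaf = 0.5, beta = 0.10, se = 0.01, pvalue = 1e-9))
  outc3 <- sumstats(data.frame(rsid = "rs1", effect_allele = "C", other_allele = "G",
                               eaf = 0.5, beta = 0.05, se = 0.01, pvalue = 0.01))
  h3 <- harmonise(expo3, outc3)
  expect_equal(h3$orientation, "dropped")
  expect_equal(h3$drop_reason, "palindromic-ambiguous")
})

test_that("proxy substitution fills SNPs missing from the outcome when r2 is high enough", {
  expo <- sumstats(data.frame(rsid = c("rs1", "rs2"), effect_allele = "A",
                              other_allele = "G", eaf = 0.3, beta = 0.1,
                              se = 0.01, pvalue = 1e-9))
  outc <- sumstats(data.frame(rsid = c("rs1p", "rs9"), effect_allele = "C",
                              other_allele = "T", eaf = 0.3, beta = c(0.04, 0.02),
                              se = 0.01, pvalue = 0.01))
  proxies <- data.frame(rsid = c("rs1", "rs2"), proxy_rsid = c("rs1p", "rs9"),
                        r2 = c(0.95, 0.5), proxy_effect_allele = c("C", "C"))
  h <- harmonise(expo, outc, proxies = proxies)
  expect_equal(h$proxy_rsid[h$rsid == "rs1"], "rs1p")
  expect_equal(h$beta_outcome[h$rsid == "rs1"], 0.04)
  # r2 below the floor: not substituted
  expect_equal(h$orientation[h$rsid == "rs2"], "dropped")
  expect_equal(h$drop_reason[h$rsid == "rs2"], "missing-in-outcome")
})

test_that("harmonising a table with itself keeps every resolvable SNP without flips", {
  tab <- random_sumstats(60, seed = 5)
  # exclude palindromes whose MAF defeats frequency inference
  pal <- with(tab, (effect_allele == "A" & other_allele == "T") |
                (effect_allele == "T" & other_allele == "A") |
                (effect_allele == "C" & other_allele == "G") |
                (effect_allele == "G" & other_allele == "C"))
  informative <- !pal | pmin(tab$eaf, 1 - tab$eaf) < 0.42
  tab <- restat(tab[informative, ], tab)
  h <- harmonise(tab, tab)
  expect_true(all(h$orientation == "kept"))
  expect_equal(h$beta_outcome, h$beta_exposure)
})

test_that("re-expressing both studies on the other allele negates both betas", {
  expo <- random_sumstats(40, seed = 9)
  outc <- random_sumstats(40, seed = 10)
  outc$beta <- 0.4 * expo$beta + rnorm(40, 0, 0.002)
  outc$effect_allele <- expo$effect_allele
  outc$other_allele <- expo$other_allele
  outc$eaf <- expo$eaf
  h1 <- retained(harmonise(expo, outc))

  swap <- function(tab) {
    ea <- tab$effect_allele
    tab$effect_allele <- tab$other_allele
    tab$other_allele <- ea
    tab$beta <- -tab$beta
    tab$eaf <- 1 - tab$eaf
    tab
  }
  h2 <- retained(harmonise(restat(swap(expo), expo), restat(swap(outc), outc)))
  common <- intersect(h1$rsid, h2$rsid)
  i1 <- match(common, h1$rsid); i2 <- match(common, h2$rsid)
  expect_equal(h2$beta_exposure[i2], -h1$beta_exposure[i1])
  expect_equal(h2$beta_outcome[i2], -h1$beta_outcome[i1])
})

test_that("duplicate outcome rsids with conflicting alleles are an error", {
  expo <- sumstats(data.frame(rsid = "rs1", effect_allele = "A", other_allele = "G",
                              eaf = 0.3, beta = 0.1, se = 0.01, pvalue = 1e-9))
  outc <- sumstats(data.frame(rsid = c("rs1", "rs1"),
                              effect_allele = c("A", "C"),
                              other_allele = c("G", "T"),
                              eaf = 0.3, beta = 0.1, se = 0.01, pvalue = 0.5))
  # construct the duplicate deliberately (sumstats dedups identical keys only)
  expect_error(harmonise(expo, outc), "conflicting alleles")
})
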