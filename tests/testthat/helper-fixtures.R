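# Fixture builders: everything is generated in code, no stored data.

random_sumstats <- function(n, seed = 1, chrom = "1", trait_name = "trait",
                            trait_type = "quantitative", pos = NULL) {
  set.seed(seed)
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, n, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), character(1))
  sumstats(data.frame(
    rsid = sprintf("rs%05d", seq_len(n)),
    chrom = chrom,
    pos = pos %||% sort(sample.int(2.4e8, n)),
    effect_allele = ea, other_allele = unname(oa),
    eaf = runif(n, 0.05, 0.95),
    beta = rnorm(n, 0, 0.02),
    se = runif(n, 0.003, 0.01),
    pvalue = runif(n),
    n = 5e5
  ), trait_name = trait_name, trait_type = trait_type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Subset a sumstats table while keeping its class and trait metadata.
restat <- function(x, template) {
  structure(x, class = c("sumstats", "data.frame"),
            trait_name = attr(template, "trait_name"),
            trait_type = attr(template, "trait_type"),
            n_total = attr(template, "n_total"),
            n_case = attr(template, "n_case"),
            n_control = attr(template, "n_control"),
            dropped = attr(template, "dropped"))
}

write_sumstats_tsv <- function(tab, path,
                               header = c(rsid = "SNP", chrom = "CHR", pos = "BP",
                                          effect_allele = "EA", other_allele = "OA",
                                          eaf = "EAF", beta = "BETA", se = "SE",
                                          pvalue = "P", n = "N")) {
  df <- as.data.frame(tab)[, names(header)]
  names(df) <- unname(header)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Harmonised-pairs table built directly, bypassing allele bookkeeping, for
# estimator tests: outcome = effect * exposure + pleiotropy + noise.
make_pairs <- function(n, seed = 1, effect = 0.5, intercept = 0, noise = 0,
                       beta_exposure = NULL, beta_outcome = NULL,
                       se_exposure = NULL, se_outcome = NULL) {
  set.seed(seed)
  bx <- beta_exposure %||% rnorm(n, 0.03, 0.01)
  sy <- se_outcome %||% runif(n, 0.005, 0.02)
  by <- beta_outcome %||% (intercept + effect * bx + rnorm(n, 0, noise))
  out <- data.frame(
    rsid = sprintf("rs%04d", seq_len(n)),
    effect_allele = "A", other_allele = "G",
    beta_exposure = bx,
    se_exposure = se_exposure %||% runif(n, 0.002, 0.005),
    eaf_exposure = runif(n, 0.1, 0.9),
    beta_outcome = by, se_outcome = sy,
    eaf_outcome = runif(n, 0.1, 0.9),
    orientation = "kept", drop_reason = NA_character_,
    proxy_rsid = NA_character_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("harmonised_pairs", "data.frame")
  out
}

# Disjoint indicator-PPA4 MVMR input: adipose SNPs weight 1 in the adipose
# column and 0 in brain, and vice versa.
indicator_mvmr_input <- function(n_per_tissue = 10, seed = 1, theta = c(0.3, -0.2)) {
  set.seed(seed)
  n <- 2 * n_per_tissue
  bx <- rnorm(n, 0.03, 0.01)
  sx <- runif(n, 0.002, 0.005)
  sy <- runif(n, 0.005, 0.02)
  lab <- rep(c("adipose", "brain"), each = n_per_tissue)
  ppa4 <- cbind(adipose = as.numeric(lab == "adipose"),
                brain = as.numeric(lab == "brain"))
  by <- ifelse(lab == "adipose", theta[1], theta[2]) * bx + rnorm(n, 0, 0.005)
  mvmr_input(sprintf("rs%03d", seq_len(n)), bx, sx, by, sy, ppa4)
}
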