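# End-to-end pipeline fixture: an exposure GWAS with planted loci, a pair
# of tissue eQTL files whose signals colocalize at known loci, and an
# outcome generated from known tissue-level effects.

build_pipeline_fixture <- function(dir,
                                   n_adipose = 10, n_brain = 10, n_null = 5,
                                   theta = c(adipose = 0.3, brain = -0.2),
                                   n_region_snps = 5,
                                   seed = 1) {
  set.seed(seed)
  n_loci <- n_adipose + n_brain + n_null
  tissue_of <- c(rep("adipose", n_adipose), rep("brain", n_brain), rep("none", n_null))

  expo_rows <- list(); eqtl_rows <- list(adipose = list(), brain = list())
  out_rows <- list()
  for (l in seq_len(n_loci)) {
    chrom <- as.character((l %% 5) + 1)       # avoid chr6 (HLA default mask)
    base <- 1e6 + (l %/% 5) * 3e7             # >= 10 Mb between loci per chrom
    pos <- base + seq_len(n_region_snps) * 1000
    rsid <- sprintf("rs_l%02d_%d", l, seq_len(n_region_snps))
    causal <- 1                                # first SNP of each locus
    beta_true <- ifelse(seq_len(n_region_snps) == causal, 0.03, 0)
    se_x <- rep(0.003, n_region_snps)
    beta_x <- beta_true + rnorm(n_region_snps, 0, se_x)
    # force the causal SNP through the genome-wide threshold
    p_x <- 2 * pnorm(-abs(beta_x / se_x))
    expo_rows[[l]] <- data.frame(
      SNP = rsid, CHR = chrom, BP = pos, EA = "A", OA = "G",
      EAF = round(runif(n_region_snps, 0.2, 0.8), 3),
      BETA = beta_x, SE = se_x, P = p_x, N = 5e5)

    for (t in c("adipose", "brain")) {
      shared <- tissue_of[l] == t
      se_e <- rep(0.05, n_region_snps)
      beta_e <- if (shared) ifelse(seq_len(n_region_snps) == causal, 0.6, 0) else
        rep(0, n_region_snps)
      beta_e <- beta_e + rnorm(n_region_snps, 0, se_e)
      eqtl_rows[[t]][[l]] <- data.frame(
        SNP = rsid, CHR = chrom, BP = pos, EA = "A", OA = "G",
        EAF = round(runif(n_region_snps, 0.2, 0.8), 3),
        BETA = beta_e, SE = se_e, P = 2 * pnorm(-abs(beta_e / se_e)),
        N = 1200, GENE = sprintf("GENE_L%02d", l))
    }

    th <- switch(tissue_of[l], adipose = theta[["adipose"]],
                 brain = theta[["brain"]], none = 0)
    se_y <- rep(0.004, n_region_snps)
    out_rows[[l]] <- data.frame(
      SNP = rsid, CHR = chrom, BP = pos, EA = "A", OA = "G",
      EAF = round(runif(n_region_snps, 0.2, 0.8), 3),
      BETA = th * beta_true + rnorm(n_region_snps, 0, se_y),
      SE = se_y, P = 0.5, N = 1e5)
  }

  paths <- list(
    exposure = file.path(dir, "exposure.tsv"),
    adipose = file.path(dir, "eqtl_adipose.tsv"),
    brain = file.path(dir, "eqtl_brain.tsv"),
    outcome = file.path(dir, "outcome.tsv"),
    config = file.path(dir, "config.yaml"),
    out_dir = file.path(dir, "out")
  )
  wt <- function(rows, path) {
    write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(expo_rows, paths$exposure)
  wt(eqtl_rows$adipose, paths$adipose)
  wt(eqtl_rows$brain, paths$brain)
  wt(out_rows, paths$outcome)

  eqtl_dialect <- list(rsid = "SNP", chrom = "CHR", pos = "BP",
                       effect_allele = "EA", other_allele = "OA", eaf = "EAF",
                       beta = "BETA", se = "SE", pvalue = "P", n = "N",
                       gene_id = "GENE")
  cfg <- list(
    exposure = list(file = paths$exposure, trait_type = "quantitative"),
    outcomes = list(list(name = "disease", file = paths$outcome,
                         trait_type = "binary")),
    eqtl = list(adipose = list(file = paths$adipose, dialect = eqtl_dialect),
                brain = list(file = paths$brain, dialect = eqtl_dialect)),
    coloc = list(window_bp = 1e4),
    seed = 7,
    out_dir = paths$out_dir
  )
  yaml::write_yaml(cfg, paths$config)
  c(paths, list(planted = split(
    sprintf("rs_l%02d_1", seq_len(n_loci)), tissue_of)))
}
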