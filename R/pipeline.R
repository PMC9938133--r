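#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML file wiring the whole workflow: exposure and
#' outcome summary-statistics files, one eQTL file per tissue, thresholds,
#' region exclusions, estimator options and the seed. Missing optional keys
#' take the documented defaults; referenced files must exist.
#'
#' Top-level keys:
#' \describe{
#'   \item{exposure}{`file`, optional `dialect`, `trait_type`, `n_total`.}
#'   \item{outcomes}{list of `name`, `file`, `trait_type`, optional
#'     `dialect`, optional `exposure_file` (e.g. a sex-matched exposure
#'     GWAS substituted for sex-stratified outcomes).}
#'   \item{eqtl}{map tissue -> `file` (+ optional `dialect`); the file
#'     needs a `gene_id` column in its dialect.}
#'   \item{thresholds}{`pvalue` (default 5e-8), `r2` (0.01),
#'     `ppa4` (0.8).}
#'   \item{clump}{`window_bp` (1e7), optional `ld_file`.}
#'   \item{coloc}{`window_bp` (5e5) and prior overrides
#'     `p1`/`p2`/`p12`/`prior_sd_quant`/`prior_sd_cc`.}
#'   \item{exclude_regions}{list of `chrom`/`start`/`end`; defaults to the
#'     extended HLA region chr6:25-35 Mb.}
#'   \item{estimators}{`n_boot` (1000), `model` ("random").}
#'   \item{seed, out_dir}{Reproducibility seed and output directory.}
#' }
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    thresholds = list(pvalue = 5e-8, r2 = 0.01, ppa4 = 0.8),
    clump = list(window_bp = 1e7, ld_file = NULL),
    coloc = list(window_bp = 5e5),
    exclude_regions = list(list(chrom = "6", start = 25e6, end = 35e6)),
    estimators = list(n_boot = 1000, model = "random"),
    seed = 1L,
    out_dir = "."
  )
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) {
      cfg[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]])) {
      for (kk in names(defaults[[k]])) {
        if (is.null(cfg[[k]][[kk]])) cfg[[k]][[kk]] <- defaults[[k]][[kk]]
      }
    }
  }
  if (is.null(cfg$exposure$file)) stop("config lacks exposure.file", call. = FALSE)
  files <- c(cfg$exposure$file,
             vapply(cfg$outcomes, function(o) o$file, character(1)),
             vapply(cfg$eqtl, function(e) e$file, character(1)))
  absent <- files[!file.exists(files)]
  if (length(absent) > 0) {
    stop("config references missing file(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  th <- cfg$thresholds
  stopifnot(th$pvalue > 0, th$pvalue < 1, th$r2 > 0, th$r2 <= 1,
            th$ppa4 > 0, th$ppa4 <= 1)
  cfg$config_path <- normalizePath(path)
  class(cfg) <- "run_config"
  cfg
}

read_cfg_sumstats <- function(entry, trait_name, trait_type = "quantitative") {
  args <- list(path = entry$file, trait_name = trait_name,
               trait_type = entry$trait_type %||% trait_type)
  if (!is.null(entry$dialect)) args$dialect <- unlist(entry$dialect)
  if (!is.null(entry$n_total)) args$n_total <- entry$n_total
  do.call(read_sumstats, args)
}

provenance_header <- function(config) {
  sprintf("# tpmr %s | seed=%s | config=%s md5=%s | %s",
          as.character(utils::packageVersion("tpmr")),
          config$seed, basename(config$config_path),
          unname(tools::md5sum(config$config_path)),
          format(Sys.time(), "%Y-%m-%d"))
}

write_tsv_provenance <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive tissue-partitioned instrument sets from a run configuration
#'
#' Executes the instrument pipeline: clump the exposure GWAS to independent
#' lead SNPs (p-value and LD/distance thresholds), mask excluded regions
#' (HLA by default), then for every lead SNP and every gene with eQTL
#' signal inside the colocalization window run the approximate-Bayes-factor
#' colocalization against each tissue's eQTLs, and keep leads whose maximum
#' PPA4 reaches the threshold. Per tissue the instrument count and mean
#' absolute exposure effect are logged (the basic instrument-set QC), and a
#' tissue ending with zero instruments is a hard failure — as happens when
#' the chosen tissues are biologically irrelevant to the exposure.
#'
#' @param config A `run_config` from [read_run_config()].
#' @return List: `lead_snps` (`sumstats`), `sets` (named list of
#'   `instrument_set`), `coloc_tables` (named list of data.frames). Side
#'   effect: `instruments_<tissue>.tsv` and `coloc_<tissue>.tsv` under
#'   `out_dir`, with provenance headers.
#' @export
run_instruments <- function(config) {
  exposure <- read_cfg_sumstats(config$exposure, "exposure")
  for (reg in config$exclude_regions) {
    exposure <- exclude_region(exposure, reg$chrom, reg$start, reg$end)
  }
  ld <- NULL
  if (!is.null(config$clump$ld_file)) {
    ld <- as.matrix(utils::read.delim(config$clump$ld_file, row.names = 1,
                                      check.names = FALSE))
  }
  leads <- clump(exposure, p_threshold = config$thresholds$pvalue,
                 r2_threshold = config$thresholds$r2, ld = ld,
                 window_bp = config$clump$window_bp)
  if (nrow(leads) == 0) stop("no lead SNPs survive clumping", call. = FALSE)
  message(nrow(leads), " lead SNP(s) after clumping and region exclusion")

  pr_args <- config$coloc[intersect(names(config$coloc),
                                    c("p1", "p2", "p12", "prior_sd_quant", "prior_sd_cc"))]
  priors <- do.call(coloc_priors, pr_args)
  window <- config$coloc$window_bp
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)

  sets <- list(); tables <- list()
  for (tissue in names(config$eqtl)) {
    eqtl <- read_cfg_sumstats(config$eqtl[[tissue]], paste0(tissue, " eQTL"))
    if (!"gene_id" %in% names(eqtl)) {
      stop("eQTL table for ", tissue, " lacks a gene_id column", call. = FALSE)
    }
    results <- list()
    for (i in seq_len(nrow(leads))) {
      lo <- leads$pos[i] - window; hi <- leads$pos[i] + window
      in_region <- !is.na(exposure$chrom) & exposure$chrom == leads$chrom[i] &
        exposure$pos >= lo & exposure$pos <= hi
      exp_reg <- restat(exposure[in_region, , drop = FALSE], exposure)
      e_reg <- eqtl[!is.na(eqtl$chrom) & eqtl$chrom == leads$chrom[i] &
                      eqtl$pos >= lo & eqtl$pos <= hi, , drop = FALSE]
      genes <- unique(e_reg$gene_id)
      for (g in genes) {
        e_gene <- restat(e_reg[e_reg$gene_id == g, , drop = FALSE], eqtl)
        if (length(intersect(exp_reg$rsid, e_gene$rsid)) == 0) next
        res <- coloc_abf(exp_reg, e_gene, priors,
                         locus_id = leads$rsid[i], gene_id = g)
        res$lead_rsid <- leads$rsid[i]
        results[[length(results) + 1]] <- res
      }
    }
    tab <- if (length(results) > 0) coloc_table(results, tissue = tissue) else
      data.frame(locus_id = character(0), lead_rsid = character(0),
                 gene_id = character(0), tissue = character(0),
                 n_snps = integer(0), pp_h0 = numeric(0), pp_h1 = numeric(0),
                 pp_h2 = numeric(0), pp_h3 = numeric(0), pp_h4 = numeric(0))
    set <- select_instruments(leads, tab, ppa4_threshold = config$thresholds$ppa4,
                              tissue = tissue)
    message(sprintf("%s: %d/%d loci tested, %d instrument(s), mean |beta| = %s",
                    tissue, length(unique(tab$lead_rsid)), nrow(leads), nrow(set),
                    if (nrow(set) > 0) signif(mean(abs(set$beta)), 3) else "NA"))
    if (nrow(set) == 0) {
      stop("zero instruments colocalize for tissue '", tissue,
           "'; the tissue is likely not relevant to this exposure", call. = FALSE)
    }
    write_tsv_provenance(tab, file.path(config$out_dir,
                                        paste0("coloc_", tissue, ".tsv")), config)
    write_tsv_provenance(as.data.frame(set),
                         file.path(config$out_dir,
                                   paste0("instruments_", tissue, ".tsv")), config)
    sets[[tissue]] <- set
    tables[[tissue]] <- tab
  }
  list(lead_snps = leads, sets = sets, coloc_tables = tables)
}

# Cross-tissue PPA4 lookup assembled from the per-tissue coloc tables:
# max pp_h4 per (lead SNP, tissue), no threshold applied.
ppa4_lookup_from_tables <- function(tables) {
  rows <- lapply(names(tables), function(t) {
    tab <- tables[[t]]
    if (nrow(tab) == 0) return(NULL)
    agg <- tapply(tab$pp_h4, tab$lead_rsid, max)
    data.frame(rsid = names(agg), tissue = t, ppa4 = unname(agg),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run univariable and tissue-partitioned MR for every configured outcome
#'
#' Per outcome: (i) total-effect univariable MR using every clumped lead
#' SNP; (ii) univariable MR per tissue instrument set; (iii) the
#' PPA4-weighted multivariable model with conditional F-statistics. If the
#' outcome entry names an `exposure_file` (e.g. a sex-stratified exposure
#' GWAS for a sex-limited cancer), instrument betas are re-extracted from
#' that file before estimation.
#'
#' @param config A `run_config`.
#' @param instruments Output of [run_instruments()].
#' @param min_snps Hard floor on harmonised SNPs per analysis (default 3).
#' @return data.frame of all results (columns `outcome`, `analysis`,
#'   `exposure_label`, estimator fields); also written to `mr_results.tsv`
#'   under `out_dir`.
#' @export
run_mr <- function(config, instruments, min_snps = 3) {
  seed <- config$seed
  n_boot <- config$estimators$n_boot
  lookup <- ppa4_lookup_from_tables(instruments$coloc_tables)
  main_exposure <- read_cfg_sumstats(config$exposure, "exposure")
  all_rows <- list()

  for (oc in config$outcomes) {
    outcome <- read_cfg_sumstats(oc, oc$name, trait_type = "binary")
    exposure <- if (!is.null(oc$exposure_file)) {
      read_cfg_sumstats(list(file = oc$exposure_file,
                             dialect = oc$exposure_dialect %||% config$exposure$dialect),
                        paste0("exposure (", oc$name, "-matched)"))
    } else main_exposure
    swap_betas <- function(tab) {
      idx <- match(tab$rsid, exposure$rsid)
      ok <- !is.na(idx)
      tab <- tab[ok, , drop = FALSE]
      tab$beta <- exposure$beta[idx[ok]]
      tab$se <- exposure$se[idx[ok]]
      tab
    }

    total_pairs <- harmonise(restat(
      exposure[exposure$rsid %in% instruments$lead_snps$rsid, , drop = FALSE],
      exposure), outcome)
    if (nrow(retained(total_pairs)) < min_snps) {
      stop("fewer than ", min_snps, " SNPs harmonise for outcome ", oc$name,
           call. = FALSE)
    }
    total <- mr_all(total_pairs, seed = seed, n_boot = n_boot)
    total$outcome <- oc$name; total$analysis <- "univariable"
    total$exposure_label <- "all instruments"
    all_rows[[length(all_rows) + 1]] <- total

    sets <- lapply(instruments$sets, swap_betas)
    for (tissue in names(sets)) {
      sub <- restat(exposure[exposure$rsid %in% sets[[tissue]]$rsid, , drop = FALSE],
                    exposure)
      pairs <- harmonise(sub, outcome)
      if (nrow(retained(pairs)) >= min_snps) {
        uni <- mr_all(pairs, seed = seed, n_boot = n_boot, methods = "ivw")
        uni$outcome <- oc$name; uni$analysis <- "univariable"
        uni$exposure_label <- paste0(tissue, "-tissue instrumented")
        all_rows[[length(all_rows) + 1]] <- uni
      }
    }

    if (length(sets) >= 2) {
      input <- build_weighted_design(sets, exposure, outcome, ppa4_lookup = lookup)
      fit <- mvmr_ivw(input, model = config$estimators$model)
      mv <- data.frame(method = "MVMR-IVW (PPA4-weighted)",
                       n_snp = fit$n_snp, estimate = fit$estimate, se = fit$se,
                       ci_low = fit$ci_low, ci_high = fit$ci_high,
                       pvalue = fit$pvalue, cochran_q = fit$cochran_q,
                       q_df = fit$q_df, egger_intercept = NA_real_,
                       egger_intercept_se = NA_real_, egger_intercept_p = NA_real_,
                       seed = seed, conditional_f = fit$conditional_f,
                       outcome = oc$name, analysis = "multivariable",
                       exposure_label = paste0(fit$tissue, "-tissue instrumented"),
                       stringsAsFactors = FALSE)
      all_rows[[length(all_rows) + 1]] <- mv
    }
  }
  cols <- unique(unlist(lapply(all_rows, names)))
  all_rows <- lapply(all_rows, function(d) {
    for (c in setdiff(cols, names(d))) d[[c]] <- NA
    d[, cols]
  })
  out <- do.call(rbind, all_rows)
  rownames(out) <- NULL
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  write_tsv_provenance(out, file.path(config$out_dir, "mr_results.tsv"), config)
  out
}
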