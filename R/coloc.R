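#' Priors for single-causal-variant colocalization
#'
#' `p1`/`p2` are per-SNP priors of association with trait 1 / trait 2 only,
#' `p12` the per-SNP prior of a shared causal variant. `prior_sd_quant` and
#' `prior_sd_cc` are the prior standard deviations of the true effect used
#' in the approximate Bayes factor, for quantitative traits (SD units) and
#' case-control traits (log-odds) respectively. Defaults are the published
#' defaults of the enumeration method.
#'
#' @param p1,p2,p12 Per-SNP hypothesis priors, each in (0,1) with
#'   `p1 + p2 + p12 < 1`.
#' @param prior_sd_quant,prior_sd_cc Effect-size prior SDs (> 0).
#' @return A `coloc_priors` list.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         prior_sd_quant = 0.15, prior_sd_cc = 0.2) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, p12 > 0, p12 < 1,
            p1 + p2 + p12 < 1, prior_sd_quant > 0, prior_sd_cc > 0)
  structure(list(p1 = p1, p2 = p2, p12 = p12,
                 prior_sd_quant = prior_sd_quant, prior_sd_cc = prior_sd_cc),
            class = "coloc_priors")
}

#' Wakefield approximate log Bayes factor for a single SNP association
#'
#' With `z = beta/se`, sampling variance `V = se^2` and prior variance
#' `W = prior_sd^2`, the shrinkage weight is `r = W/(V + W)` and the log
#' Bayes factor in favour of association is
#' `log ABF = log(1 - r)/2 + r z^2 / 2`. Everything is kept in log space,
#' so |z| of order 100 (routine in biobank-scale GWAS) cannot overflow.
#'
#' @param beta,se Effect estimate and its standard error (`se > 0`).
#' @param prior_sd Prior SD of the true effect (> 0). Vectorised over all
#'   three arguments.
#' @return Numeric vector of log Bayes factors.
#' @export
wakefield_log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("se must be positive", call. = FALSE)
  if (any(prior_sd <= 0)) stop("prior_sd must be positive", call. = FALSE)
  z2 <- (beta / se)^2
  r <- prior_sd^2 / (se^2 + prior_sd^2)
  0.5 * log1p(-r) + 0.5 * r * z2
}

logsumexp <- function(x) {
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, in log space
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

prior_sd_for <- function(tab, priors) {
  if (identical(attr(tab, "trait_type"), "binary")) priors$prior_sd_cc else priors$prior_sd_quant
}

#' Colocalization posteriors for one locus by approximate Bayes factors
#'
#' Tests whether two traits share a single causal variant in a region.
#' SNPs are matched on rsid (intersection; a SNP present in only one trait
#' is ignored). Per SNP and trait a Wakefield log-ABF is computed with the
#' trait-type-appropriate prior SD; evidence for the five hypotheses
#' H0 (neither trait associated) through H4 (shared causal variant) is then
#' accumulated over single-causal-variant configurations in log space:
#' H1/H2 sum single-trait ABFs, H4 pairs same-SNP ABFs, H3 pairs
#' distinct-SNP ABFs (the product of the single-trait sums minus the
#' same-SNP sum). Posteriors are the prior-weighted softmax; they sum to 1.
#'
#' @param trait1,trait2 `sumstats` objects restricted to the locus. For a
#'   binary trait supply `trait_type = "binary"` so the case-control prior
#'   SD applies.
#' @param priors A [coloc_priors()] object.
#' @param locus_id,gene_id Optional labels carried into the result.
#' @return A `coloc_result` list: `locus_id`, `gene_id`, `lead_rsid` (SNP
#'   with the largest summed log-ABF), `n_snps`, `snp` (per-SNP data.frame
#'   with `lbf1`, `lbf2`), and `pp` (named vector `pp_h0` ... `pp_h4`;
#'   `pp_h4` is the PPA4 used downstream).
#' @export
coloc_abf <- function(trait1, trait2, priors = coloc_priors(),
                      locus_id = NA_character_, gene_id = NA_character_) {
  common <- intersect(trait1$rsid, trait2$rsid)
  if (length(common) == 0) stop("no overlapping SNPs between traits", call. = FALSE)
  t1 <- trait1[match(common, trait1$rsid), , drop = FALSE]
  t2 <- trait2[match(common, trait2$rsid), , drop = FALSE]
  if (any(is.na(t1$se)) || any(is.na(t2$se))) {
    stop("missing standard errors in colocalization region", call. = FALSE)
  }
  lbf1 <- wakefield_log_abf(t1$beta, t1$se, prior_sd_for(trait1, priors))
  lbf2 <- wakefield_log_abf(t2$beta, t2$se, prior_sd_for(trait2, priors))

  lsum1 <- logsumexp(lbf1)
  lsum2 <- logsumexp(lbf2)
  lsum12 <- logsumexp(lbf1 + lbf2)
  lh <- c(
    h0 = 0,
    h1 = log(priors$p1) + lsum1,
    h2 = log(priors$p2) + lsum2,
    h3 = log(priors$p1) + log(priors$p2) +
      (if (length(common) > 1) logdiffexp(lsum1 + lsum2, lsum12) else -Inf),
    h4 = log(priors$p12) + lsum12
  )
  denom <- logsumexp(lh)
  pp <- exp(lh - denom)
  names(pp) <- paste0("pp_", names(lh))
  structure(list(
    locus_id = locus_id,
    gene_id = gene_id,
    lead_rsid = common[which.max(lbf1 + lbf2)],
    n_snps = length(common),
    snp = data.frame(rsid = common, lbf1 = lbf1, lbf2 = lbf2,
                     stringsAsFactors = FALSE),
    pp = pp,
    priors = priors
  ), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc> locus %s gene %s: %d SNPs\n", x$locus_id, x$gene_id, x$n_snps))
  print(round(x$pp, 4))
  invisible(x)
}

#' Flatten colocalization results to one row per (locus, gene)
#' @param results List of `coloc_result` objects.
#' @param tissue Tissue label attached to every row.
#' @return data.frame with `locus_id`, `lead_rsid`, `gene_id`, `tissue`,
#'   `n_snps`, `pp_h0` ... `pp_h4`.
#' @export
coloc_table <- function(results, tissue = NA_character_) {
  rows <- lapply(results, function(r) {
    cbind(data.frame(locus_id = r$locus_id, lead_rsid = r$lead_rsid,
                     gene_id = r$gene_id, tissue = tissue,
                     n_snps = r$n_snps, stringsAsFactors = FALSE),
          as.data.frame(as.list(r$pp)))
  })
  do.call(rbind, rows)
}

#' Select tissue instruments from colocalization evidence
#'
#' A lead SNP enters the instrument set iff its maximum `pp_h4` over all
#' genes tested at its locus reaches `ppa4_threshold`; that maximum becomes
#' the SNP's tissue PPA4 and the gene attaining it is recorded.
#'
#' @param lead_snps `sumstats` of clumped lead SNPs (exposure estimates).
#' @param results data.frame from [coloc_table()] (or rbind of several),
#'   with `lead_rsid`, `gene_id`, `pp_h4` and optionally `tissue`.
#' @param ppa4_threshold Inclusion threshold in (0, 1]; the method authors
#'   recommend 0.8.
#' @param tissue Tissue label for the returned set (defaults to the label
#'   in `results` if unique).
#' @return An `instrument_set` data.frame: `rsid`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`,
#'   `tissue`, `gene`, `ppa4`.
#' @export
select_instruments <- function(lead_snps, results, ppa4_threshold = 0.8,
                               tissue = NULL) {
  if (ppa4_threshold <= 0 || ppa4_threshold > 1) {
    stop("ppa4_threshold must be in (0, 1]", call. = FALSE)
  }
  if (is.null(tissue)) {
    tissue <- unique(stats::na.omit(results$tissue))
    tissue <- if (length(tissue) == 1) tissue else NA_character_
  }
  out <- lead_snps[0, c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                        "eaf", "beta", "se", "pvalue")]
  out$tissue <- character(0); out$gene <- character(0); out$ppa4 <- numeric(0)
  for (i in seq_len(nrow(lead_snps))) {
    hits <- results[results$lead_rsid == lead_snps$rsid[i], , drop = FALSE]
    if (nrow(hits) == 0) next
    best <- which.max(hits$pp_h4)
    if (hits$pp_h4[best] >= ppa4_threshold) {
      row <- lead_snps[i, c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                            "eaf", "beta", "se", "pvalue")]
      row$tissue <- tissue
      row$gene <- hits$gene_id[best]
      row$ppa4 <- hits$pp_h4[best]
      out <- rbind(out, row)
    }
  }
  rownames(out) <- NULL
  class(out) <- c("instrument_set", "data.frame")
  attr(out, "tissue") <- tissue
  attr(out, "ppa4_threshold") <- ppa4_threshold
  out
}
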