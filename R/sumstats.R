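#' Construct a validated summary-statistics table
#'
#' Builds a `sumstats` object (a `data.frame` with trait metadata attached)
#' from per-SNP association estimates. Rows violating the per-record
#' invariants are removed and recorded, with reasons, in the `dropped`
#' attribute rather than raising an error, so that a noisy GWAS file can be
#' ingested in one pass.
#'
#' Required columns are `rsid`, `effect_allele`, `other_allele`, `beta`,
#' `se`, `pvalue`. Optional columns: `chrom`, `pos`, `eaf`, `n`, `gene_id`
#' (the latter for eQTL tables). Alleles are upper-cased. Enforced
#' invariants: `se > 0`; `pvalue` in (0, 1]; `eaf` strictly inside (0, 1)
#' when present; `effect_allele != other_allele`; no duplicated
#' (`rsid`, allele pair).
#'
#' @param x data.frame of per-SNP estimates.
#' @param trait_name Label for the trait.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param n_total,n_case,n_control Optional study-level sample sizes.
#'   Binary traits need `n_case`/`n_control` before colocalization.
#' @return A `sumstats` data.frame, row order preserved, with attributes
#'   `trait_name`, `trait_type`, `n_total`, `n_case`, `n_control` and
#'   `dropped` (data.frame of excluded rows with a `reason` column).
#' @export
sumstats <- function(x, trait_name = "trait", trait_type = c("quantitative", "binary"),
                     n_total = NA_real_, n_case = NA_real_, n_control = NA_real_) {
  trait_type <- match.arg(trait_type)
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pvalue")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("summary statistics lack required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in c("chrom", "pos", "eaf", "n")) {
    if (!col %in% names(x)) x[[col]] <- if (col == "chrom") NA_character_ else NA_real_
  }
  x$rsid <- as.character(x$rsid)
  x$chrom <- as.character(x$chrom)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) x[[col]] <- as.numeric(x[[col]])

  reason <- rep(NA_character_, nrow(x))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- FALSE
    ifelse(bad & is.na(reason), why, reason)
  }
  reason <- flag(is.na(x$beta) | is.na(x$se) | is.na(x$pvalue) | is.na(x$rsid) |
                   x$rsid == "", "missing required value")
  reason <- flag(x$se <= 0, "non-positive SE")
  reason <- flag(x$pvalue <= 0 | x$pvalue > 1, "p-value outside (0,1]")
  reason <- flag(!is.na(x$eaf) & (x$eaf <= 0 | x$eaf >= 1), "EAF outside (0,1)")
  reason <- flag(x$effect_allele == x$other_allele, "identical alleles")
  key <- paste(x$rsid, x$effect_allele, x$other_allele)
  reason <- flag(duplicated(key), "duplicate (rsid, alleles)")

  dropped <- x[!is.na(reason), , drop = FALSE]
  dropped$reason <- reason[!is.na(reason)]
  out <- x[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("sumstats", "data.frame"),
            trait_name = trait_name, trait_type = trait_type,
            n_total = n_total, n_case = n_case, n_control = n_control,
            dropped = dropped)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> %s (%s): %d SNPs",
              attr(x, "trait_name"), attr(x, "trait_type"), nrow(x)))
  nd <- nrow(attr(x, "dropped") %||% data.frame())
  if (nd > 0) cat(sprintf(" (%d rows excluded at validation)", nd))
  cat("\n")
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rebuild sumstats attributes after a row subset, keeping metadata.
restat <- function(x, template) {
  structure(x,
            class = c("sumstats", "data.frame"),
            trait_name = attr(template, "trait_name"),
            trait_type = attr(template, "trait_type"),
            n_total = attr(template, "n_total"),
            n_case = attr(template, "n_case"),
            n_control = attr(template, "n_control"),
            dropped = attr(template, "dropped"))
}

#' Read GWAS or eQTL summary statistics from delimited text
#'
#' Reads a tab- or comma-delimited file with a header row and maps its
#' columns onto the canonical `sumstats` layout via a dialect (a named list
#' `canonical = file_column`). The dialect must cover at least `rsid`,
#' `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`; `chrom`, `pos`,
#' `eaf`, `n` and `gene_id` are optional. Row order is preserved; invalid
#' rows are excluded with reasons (see [sumstats()]).
#'
#' @param path Path to the file. Delimiter is inferred from the header line
#'   (tab wins over comma) unless `delim` is given.
#' @param dialect Named list/character vector mapping canonical names to
#'   file column names. Defaults to a common GWAS layout
#'   (`SNP,CHR,BP,EA,OA,EAF,BETA,SE,P,N`).
#' @param delim Field delimiter override.
#' @inheritParams sumstats
#' @return A `sumstats` object.
#' @export
read_sumstats <- function(path,
                          dialect = c(rsid = "SNP", chrom = "CHR", pos = "BP",
                                      effect_allele = "EA", other_allele = "OA",
                                      eaf = "EAF", beta = "BETA", se = "SE",
                                      pvalue = "P", n = "N"),
                          delim = NULL,
                          trait_name = basename(path),
                          trait_type = "quantitative",
                          n_total = NA_real_, n_case = NA_real_, n_control = NA_real_) {
  if (!file.exists(path)) stop("cannot read summary statistics: ", path, call. = FALSE)
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.delim(path, sep = delim, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  dialect <- unlist(dialect)
  dialect <- dialect[dialect %in% names(raw)]
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pvalue")
  miss <- setdiff(required, names(dialect))
  if (length(miss) > 0) {
    stop("dialect does not resolve required column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  mapped <- raw[, unname(dialect), drop = FALSE]
  names(mapped) <- names(dialect)
  out <- sumstats(mapped, trait_name = trait_name, trait_type = trait_type,
                  n_total = n_total, n_case = n_case, n_control = n_control)
  if (nrow(out) == 0) stop("no valid rows in ", basename(path), call. = FALSE)
  out
}

#' Exclude SNPs inside a genomic region
#'
#' Removes every record on the region's chromosome with position inside the
#' 1-based inclusive interval. The canonical use is masking the extended HLA
#' region (chr6, 25-35 Mb), where strong long-range linkage disequilibrium
#' makes colocalization evidence unreliable.
#'
#' @param x A `sumstats` object with `chrom`/`pos` populated.
#' @param chrom Chromosome label.
#' @param start,end Interval bounds, 1-based inclusive, `start <= end`.
#' @return The filtered `sumstats`; the number of removals is reported via
#'   `message()`.
#' @examples
#' tab <- sumstats(data.frame(
#'   rsid = c("rs1", "rs2"), chrom = "6", pos = c(3e7, 2.4e7),
#'   effect_allele = "A", other_allele = "G",
#'   beta = 0.1, se = 0.01, pvalue = 1e-10))
#' nrow(exclude_region(tab, "6", 25e6, 35e6))  # 1
#' @export
exclude_region <- function(x, chrom, start, end) {
  stopifnot(length(chrom) == 1, length(start) == 1, length(end) == 1, start <= end)
  inside <- !is.na(x$chrom) & x$chrom == as.character(chrom) &
    !is.na(x$pos) & x$pos >= start & x$pos <= end
  if (any(inside)) {
    message(sum(inside), " SNP(s) removed in region ", chrom, ":", start, "-", end)
  }
  out <- x[!inside, , drop = FALSE]
  rownames(out) <- NULL
  restat(out, x)
}

#' Greedy p-value clumping to approximately independent lead SNPs
#'
#' Ranks SNPs by ascending p-value and keeps a SNP iff its p-value is below
#' `p_threshold` and it is independent of every SNP already kept. With an LD
#' matrix, independence means r-squared below `r2_threshold` against all kept
#' SNPs; without one, it means a physical distance of at least `window_bp`
#' from every kept SNP on the same chromosome (different chromosomes are
#' always independent). Ties in p-value are broken by rsid in lexicographic
#' order, so the result is invariant to input row order.
#'
#' @param x A `sumstats` object.
#' @param p_threshold Significance threshold; the genome-wide convention is
#'   `5e-8` (strictly below).
#' @param r2_threshold r-squared ceiling for LD-based clumping; `0.01` keeps
#'   only robustly independent loci.
#' @param ld Optional square symmetric correlation matrix (entries r, not
#'   r-squared) with rsid dimnames covering every candidate SNP.
#' @param window_bp Distance window for LD-free clumping.
#' @return `sumstats` of lead SNPs, ordered by ascending p-value.
#' @export
clump <- function(x, p_threshold = 5e-8, r2_threshold = 0.01,
                  ld = NULL, window_bp = 1e7) {
  cand <- x[!is.na(x$pvalue) & x$pvalue < p_threshold, , drop = FALSE]
  cand <- cand[order(cand$pvalue, cand$rsid), , drop = FALSE]
  if (nrow(cand) == 0) return(restat(cand, x))
  if (!is.null(ld)) {
    absent <- setdiff(cand$rsid, rownames(ld))
    if (length(absent) > 0) {
      stop("LD matrix lacks SNP(s): ", paste(utils::head(absent, 5), collapse = ", "),
           call. = FALSE)
    }
  }
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    kept <- which(keep)
    ok <- if (length(kept) == 0) {
      TRUE
    } else if (!is.null(ld)) {
      r <- ld[cand$rsid[i], cand$rsid[kept]]
      all(r^2 < r2_threshold)
    } else {
      same <- cand$chrom[kept] == cand$chrom[i]
      all(is.na(same) | !same | abs(cand$pos[kept] - cand$pos[i]) >= window_bp)
    }
    keep[i] <- ok
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  restat(out, x)
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) {
  !is.na(a1) & !is.na(a2) & a1 %in% names(COMPLEMENT) & unname(COMPLEMENT[a1]) == a2
}

flip_alleles <- function(a) {
  out <- unname(COMPLEMENT[a])
  out[is.na(out)] <- a[is.na(out)]
  out
}

#' Harmonise exposure and outcome summary statistics to a shared effect allele
#'
#' For every exposure SNP, expresses the outcome association on the exposure
#' effect allele. Outcome rows whose alleles are swapped (or strand-flipped)
#' relative to the exposure have their beta negated and EAF reflected.
#' Palindromic SNPs (A/T, C/G), whose strand cannot be resolved from alleles,
#' are oriented by comparing allele frequencies when both minor-allele
#' frequencies are below `palindromic_maf_limit`, and dropped as ambiguous
#' otherwise (or when either EAF is missing). SNPs absent from the outcome
#' are substituted by a proxy in strong LD when a proxy table offers one with
#' r-squared at or above `proxy_r2_min`, and dropped otherwise. Every
#' decision is recorded per SNP.
#'
#' @param exposure,outcome `sumstats` objects.
#' @param palindromic_maf_limit Frequency-inference limit for palindromic
#'   SNPs; both MAFs must fall below it (default 0.42, the common
#'   two-sample-MR convention).
#' @param proxies Optional data.frame with columns `rsid` (requested),
#'   `proxy_rsid`, `r2`, and optionally `proxy_effect_allele` naming the
#'   proxy allele that tags the requested effect allele (defaults to the
#'   proxy's outcome effect allele).
#' @param proxy_r2_min Minimum proxy r-squared (default 0.8).
#' @return A `harmonised_pairs` data.frame with one row per exposure SNP:
#'   `rsid`, `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `eaf_exposure`, `beta_outcome`, `se_outcome`, `eaf_outcome`,
#'   `orientation` (`kept`/`flipped`/`dropped`), `drop_reason`
#'   (`palindromic-ambiguous`, `allele-mismatch`, `missing-in-outcome`) and
#'   `proxy_rsid` (non-NA where a proxy was substituted).
#' @export
harmonise <- function(exposure, outcome, palindromic_maf_limit = 0.42,
                      proxies = NULL, proxy_r2_min = 0.8) {
  okey <- outcome$rsid
  if (anyDuplicated(okey)) {
    dup <- okey[duplicated(okey)]
    conflicting <- vapply(unique(dup), function(r) {
      rows <- outcome[okey == r, c("effect_allele", "other_allele")]
      nrow(unique(rows)) > 1
    }, logical(1))
    if (any(conflicting)) {
      stop("outcome has duplicate rsid with conflicting alleles: ",
           paste(unique(dup)[conflicting], collapse = ", "), call. = FALSE)
    }
    outcome <- outcome[!duplicated(okey), , drop = FALSE]
  }
  oidx <- match(exposure$rsid, outcome$rsid)

  n <- nrow(exposure)
  out <- data.frame(
    rsid = exposure$rsid,
    effect_allele = exposure$effect_allele,
    other_allele = exposure$other_allele,
    beta_exposure = exposure$beta,
    se_exposure = exposure$se,
    eaf_exposure = exposure$eaf,
    pvalue_exposure = exposure$pvalue,
    beta_outcome = NA_real_,
    se_outcome = NA_real_,
    eaf_outcome = NA_real_,
    pvalue_outcome = NA_real_,
    orientation = NA_character_,
    drop_reason = NA_character_,
    proxy_rsid = NA_character_,
    stringsAsFactors = FALSE
  )

  for (i in seq_len(n)) {
    j <- oidx[i]
    proxy_used <- NA_character_
    ea <- out$effect_allele[i]; oa <- out$other_allele[i]
    if (is.na(j) && !is.null(proxies)) {
      cand <- proxies[proxies$rsid == out$rsid[i] & proxies$r2 >= proxy_r2_min, , drop = FALSE]
      if (nrow(cand) > 0) {
        cand <- cand[order(-cand$r2), , drop = FALSE]
        for (k in seq_len(nrow(cand))) {
          jj <- match(cand$proxy_rsid[k], outcome$rsid)
          if (!is.na(jj)) {
            j <- jj
            proxy_used <- cand$proxy_rsid[k]
            # Alleles of the proxy stand in for the requested SNP's alleles:
            # the stated proxy effect allele tags the exposure effect allele.
            pea <- cand$proxy_effect_allele[k] %||% NA_character_
            if (!is.na(pea)) {
              ea <- toupper(pea)
              oa <- setdiff(c(outcome$effect_allele[j], outcome$other_allele[j]), ea)[1]
            } else {
              ea <- outcome$effect_allele[j]
              oa <- outcome$other_allele[j]
            }
            break
          }
        }
      }
    }
    if (is.na(j)) {
      out$orientation[i] <- "dropped"
      out$drop_reason[i] <- "missing-in-outcome"
      next
    }
    o_ea <- outcome$effect_allele[j]; o_oa <- outcome$other_allele[j]
    o_beta <- outcome$beta[j]; o_eaf <- outcome$eaf[j]
    palindromic <- is_palindromic(ea, oa)

    if (palindromic) {
      aligned <- (o_ea == ea && o_oa == oa)
      swapped <- (o_ea == oa && o_oa == ea)
      if (!aligned && !swapped) {
        out$orientation[i] <- "dropped"; out$drop_reason[i] <- "allele-mismatch"; next
      }
      e_eaf <- out$eaf_exposure[i]
      if (swapped) { o_beta <- -o_beta; o_eaf <- 1 - o_eaf }
      if (is.na(e_eaf) || is.na(o_eaf)) {
        out$orientation[i] <- "dropped"; out$drop_reason[i] <- "palindromic-ambiguous"; next
      }
      maf_e <- pmin(e_eaf, 1 - e_eaf); maf_o <- pmin(o_eaf, 1 - o_eaf)
      if (maf_e >= palindromic_maf_limit || maf_o >= palindromic_maf_limit) {
        out$orientation[i] <- "dropped"; out$drop_reason[i] <- "palindromic-ambiguous"; next
      }
      same_side <- (e_eaf < 0.5) == (o_eaf < 0.5)
      if (same_side) {
        out$orientation[i] <- if (swapped) "flipped" else "kept"
      } else {
        o_beta <- -o_beta; o_eaf <- 1 - o_eaf
        out$orientation[i] <- if (swapped) "kept" else "flipped"
      }
    } else {
      if (o_ea == ea && o_oa == oa) {
        out$orientation[i] <- "kept"
      } else if (o_ea == oa && o_oa == ea) {
        o_beta <- -o_beta; o_eaf <- 1 - o_eaf
        out$orientation[i] <- "flipped"
      } else if (flip_alleles(o_ea) == ea && flip_alleles(o_oa) == oa) {
        out$orientation[i] <- "kept"   # strand flip, same orientation
      } else if (flip_alleles(o_ea) == oa && flip_alleles(o_oa) == ea) {
        o_beta <- -o_beta; o_eaf <- 1 - o_eaf
        out$orientation[i] <- "flipped"
      } else {
        out$orientation[i] <- "dropped"; out$drop_reason[i] <- "allele-mismatch"; next
      }
    }
    out$beta_outcome[i] <- o_beta
    out$se_outcome[i] <- outcome$se[j]
    out$eaf_outcome[i] <- o_eaf
    out$pvalue_outcome[i] <- outcome$pvalue[j]
    out$proxy_rsid[i] <- proxy_used
  }
  class(out) <- c("harmonised_pairs", "data.frame")
  attr(out, "exposure_trait") <- attr(exposure, "trait_name")
  attr(out, "outcome_trait") <- attr(outcome, "trait_name")
  out
}

#' Retained rows of a harmonised pair table
#' @param pairs A `harmonised_pairs` data.frame.
#' @return The subset with an outcome estimate (orientation not `dropped`).
#' @export
retained <- function(pairs) {
  pairs[pairs$orientation != "dropped", , drop = FALSE]
}

#' Write harmonised pairs to TSV
#' @param pairs A `harmonised_pairs` data.frame.
#' @param path Output path.
#' @export
write_harmonised <- function(pairs, path) {
  utils::write.table(as.data.frame(pairs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
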