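#' Phenotype quality control for perinatal weight data
#'
#' Applies the standard exclusions for placental-weight analyses:
#' implausible weights (< 200 g or > 1500 g), weights more than 5 s.d.
#' from the within-cohort mean (computed once, before any exclusion, for
#' determinism), and deliveries outside 37 completed weeks to 42 weeks 6
#' days of gestation (259 to 300 days, both ends inclusive).
#'
#' @param phenotypes data.frame with at least `pw_g`, `ga_days` and
#'   `cohort_id` columns.
#' @return list with `kept` (filtered data.frame) and `report` (named
#'   integer counts of rows failing each filter; a row failing several
#'   filters is counted under each).
#' @export
apply_qc <- function(phenotypes) {
  stopifnot(all(c("pw_g", "ga_days", "cohort_id") %in% names(phenotypes)))
  low <- phenotypes$pw_g < 200
  high <- phenotypes$pw_g > 1500
  # within-cohort mean/sd on the full (pre-exclusion) table, single pass
  mu <- stats::ave(phenotypes$pw_g, phenotypes$cohort_id, FUN = mean)
  sd_ <- stats::ave(phenotypes$pw_g, phenotypes$cohort_id, FUN = stats::sd)
  outlier <- abs(phenotypes$pw_g - mu) > 5 * sd_
  preterm <- phenotypes$ga_days < 259
  postterm <- phenotypes$ga_days > 300
  drop <- low | high | outlier | preterm | postterm
  kept <- phenotypes[!drop, , drop = FALSE]
  if (nrow(kept) == 0)
    warning("all rows excluded by phenotype QC")
  list(kept = kept,
       report = c(pw_below_200g = sum(low), pw_above_1500g = sum(high),
                  pw_beyond_5sd = sum(outlier), ga_below_259d = sum(preterm),
                  ga_above_300d = sum(postterm), total_excluded = sum(drop)))
}

#' Within-cohort z-scoring of weight phenotypes
#'
#' Each individual z-score uses the unadjusted within-cohort mean and
#' s.d. of the raw phenotype. Applied after QC.
#'
#' @param phenotypes filtered data.frame with `pw_g`, `cohort_id` and
#'   optionally `bw_g`.
#' @return the data.frame with `pw_z` (and `bw_z` when `bw_g` present)
#'   appended.
#' @export
zscore_phenotype <- function(phenotypes) {
  tab <- table(phenotypes$cohort_id)
  if (any(tab < 2))
    stop("cohorts with fewer than 2 rows have undefined s.d.: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  zs <- function(x, g) {
    mu <- stats::ave(x, g, FUN = mean)
    sd_ <- stats::ave(x, g, FUN = stats::sd)
    if (any(sd_ == 0))
      stop("constant phenotype within a cohort: s.d. is zero")
    (x - mu) / sd_
  }
  phenotypes$pw_z <- zs(phenotypes$pw_g, phenotypes$cohort_id)
  if ("bw_g" %in% names(phenotypes))
    phenotypes$bw_z <- zs(phenotypes$bw_g, phenotypes$cohort_id)
  phenotypes
}

#' Per-variant association scan for one genome of the trio
#'
#' Ordinary least squares of the standardized phenotype on the allele
#' count of the chosen genome plus covariates (sex, and optionally
#' standardized gestational age), one variant at a time:
#' `pw_z ~ dosage + sex (+ ga_std)`. Slopes are in phenotype-s.d. units
#' per effect allele; p-values are two-sided from the t distribution.
#' Monomorphic variants are emitted with missing statistics.
#'
#' @param dosages numeric matrix (samples x variants) of allele counts
#'   for the genome being tested.
#' @param phenotype numeric vector of standardized phenotype values
#'   aligned with the dosage rows.
#' @param covariates data.frame or matrix of covariates (may be NULL).
#' @param variants data.frame of variant metadata (chrom, pos, id plus
#'   ref/alt used as other/effect allele); optional.
#' @param n_studies study count recorded in the output (default 1).
#' @return a `gwas_records` data.frame: id, chrom, pos, ea, oa, eaf,
#'   beta, se, p, n, n_studies.
#' @export
run_single_genome_gwas <- function(dosages, phenotype, covariates = NULL,
                                   variants = NULL, n_studies = 1L) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages)
  if (length(phenotype) != n)
    stop("phenotype length does not match dosage rows")
  if (is.null(covariates)) {
    covm <- matrix(numeric(0), n, 0)
  } else {
    covm <- as.matrix(covariates)
  }
  base <- cbind(Intercept = rep(1, n), covm)
  qrb <- qr(base)
  if (qrb$rank < ncol(base)) {
    bad <- colnames(base)[-qrb$pivot[seq_len(qrb$rank)]]
    stop("rank-deficient covariate design; offending columns: ",
         paste(bad, collapse = ", "))
  }
  m <- ncol(dosages)
  if (is.null(variants)) {
    variants <- data.frame(chrom = "1", pos = seq_len(m),
                           ref = "A", alt = "G",
                           id = sprintf("v%d", seq_len(m)),
                           stringsAsFactors = FALSE)
  }
  beta <- se <- p <- eaf <- rep(NA_real_, m)
  df <- n - ncol(base) - 1L
  for (j in seq_len(m)) {
    g <- dosages[, j]
    eaf[j] <- mean(g) / 2
    if (stats::var(g) == 0) next  # monomorphic: missing stats
    fit <- stats::lm.fit(cbind(base, g = g), phenotype)
    k <- length(fit$coefficients)
    rss <- sum(fit$residuals^2)
    XtXinv_gg <- chol2inv(fit$qr$qr[seq_len(k), seq_len(k), drop = FALSE])
    # coefficient order after pivoting
    ord <- fit$qr$pivot
    gidx <- which(ord == k)
    s2 <- rss / df
    beta[j] <- fit$coefficients["g"]
    se[j] <- sqrt(s2 * XtXinv_gg[gidx, gidx])
    p[j] <- 2 * stats::pt(abs(beta[j] / se[j]), df, lower.tail = FALSE)
  }
  structure(data.frame(id = variants$id, chrom = variants$chrom,
                       pos = variants$pos, ea = variants$alt,
                       oa = variants$ref, eaf = eaf, beta = beta, se = se,
                       p = p, n = n, n_studies = as.integer(n_studies),
                       stringsAsFactors = FALSE),
            class = c("gwas_records", "data.frame"))
}

#' Harmonize one set of summary statistics to a reference orientation
#'
#' Records whose effect/other alleles are swapped relative to the
#' reference have their beta sign flipped and EAF complemented; records
#' whose allele pair neither matches nor swaps are dropped with a
#' warning. Strand flips are not attempted.
#'
#' @param records a `gwas_records` data.frame.
#' @param reference a `gwas_records` data.frame defining the orientation.
#' @return harmonized records restricted to resolvable variants.
#' @export
harmonize_alleles <- function(records, reference) {
  i <- match(records$id, reference$id)
  keep <- !is.na(i)
  records <- records[keep, , drop = FALSE]
  ref <- reference[i[keep], , drop = FALSE]
  same <- records$ea == ref$ea & records$oa == ref$oa
  swap <- records$ea == ref$oa & records$oa == ref$ea
  bad <- !(same | swap)
  if (any(bad)) {
    warning(sum(bad), " variant(s) dropped: irreconcilable allele pairs")
    records <- records[!bad, , drop = FALSE]
    same <- same[!bad]; swap <- swap[!bad]
  }
  records$beta[swap] <- -records$beta[swap]
  records$eaf[swap] <- 1 - records$eaf[swap]
  records$ea[swap] <- records$oa[swap]
  records$oa[swap] <- ref$ea[match(records$id[swap], ref$id)]
  records
}

#' Fixed-effects inverse-variance meta-analysis across cohorts
#'
#' Per-variant inverse-variance weighting: weights `w_i = 1/se_i^2`,
#' combined effect `sum(w b)/sum(w)`, combined SE `1/sqrt(sum(w))`, and
#' Cochran's Q heterogeneity statistic with k-1 degrees of freedom.
#' Studies are harmonized to the first cohort's allele orientation
#' before combining.
#'
#' @param cohort_records list of `gwas_records` data.frames, one per
#'   cohort.
#' @return a `gwas_records` data.frame with `q` and `q_df` columns added;
#'   `n` is summed across contributing studies, `n_studies` counts them.
#' @export
meta_fixed_effects <- function(cohort_records) {
  stopifnot(length(cohort_records) >= 1)
  ref <- cohort_records[[1]]
  harm <- lapply(cohort_records, harmonize_alleles, reference = ref)
  ids <- unique(unlist(lapply(harm, `[[`, "id")))
  k <- length(harm)
  out <- ref[match(ids, ref$id), c("id", "chrom", "pos", "ea", "oa"),
             drop = FALSE]
  out$eaf <- out$beta <- out$se <- out$p <- NA_real_
  out$n <- 0L; out$n_studies <- 0L
  out$q <- out$q_df <- NA_real_
  for (r in seq_along(ids)) {
    id <- ids[r]
    b <- se <- nn <- af <- numeric(0)
    for (h in harm) {
      j <- match(id, h$id)
      if (!is.na(j) && !is.na(h$beta[j]) && !is.na(h$se[j])) {
        b <- c(b, h$beta[j]); se <- c(se, h$se[j])
        nn <- c(nn, h$n[j]); af <- c(af, h$eaf[j])
      }
    }
    if (length(b) == 0) next
    w <- 1 / se^2
    bm <- sum(w * b) / sum(w)
    sm <- 1 / sqrt(sum(w))
    out$beta[r] <- bm
    out$se[r] <- sm
    out$p[r] <- 2 * stats::pnorm(abs(bm / sm), lower.tail = FALSE)
    out$eaf[r] <- sum(nn * af) / sum(nn)
    out$n[r] <- sum(nn)
    out$n_studies[r] <- length(b)
    if (length(b) > 1) {
      out$q[r] <- sum(w * (b - bm)^2)
      out$q_df[r] <- length(b) - 1
    }
  }
  rownames(out) <- NULL
  structure(out, class = c("gwas_records", "data.frame"))
}

#' Filter meta-analysis records on study count and sample size
#'
#' Retains variants present in at least two studies and with at least
#' 5,000 contributing individuals (both thresholds configurable).
#'
#' @param records meta-analysis `gwas_records`.
#' @param min_studies minimum number of contributing studies (default 2).
#' @param min_n minimum total sample size (default 5000).
#' @return filtered records.
#' @export
filter_meta <- function(records, min_studies = 2L, min_n = 5000L) {
  keep <- records$n_studies >= min_studies & records$n >= min_n
  records[keep, , drop = FALSE]
}

#' Define genome-wide significant loci
#'
#' Variants with p below the threshold are clustered by single linkage
#' within chromosomes: consecutive significant variants no more than the
#' window apart share a locus; a gap greater than the window starts a new
#' one. The lead SNP of a locus is its smallest-p member (ties broken by
#' smaller position).
#'
#' @param records `gwas_records` with p-values.
#' @param p_threshold significance threshold (default 5e-8).
#' @param window_kb clustering distance in kilobases (default 500).
#' @return data.frame with one row per locus: chrom, start, end,
#'   n_variants, lead_id, lead_pos, lead_p, member ids (comma-separated).
#' @export
define_loci <- function(records, p_threshold = 5e-8, window_kb = 500) {
  sig <- records[!is.na(records$p) & records$p < p_threshold, , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_variants = integer(0),
                      lead_id = character(0), lead_pos = integer(0),
                      lead_p = numeric(0), members = character(0),
                      stringsAsFactors = FALSE))
  window <- window_kb * 1000
  out <- NULL
  for (chr in unique(sig$chrom)) {
    s <- sig[sig$chrom == chr, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    gap <- c(FALSE, diff(s$pos) > window)
    grp <- cumsum(gap)
    for (g in unique(grp)) {
      mem <- s[grp == g, , drop = FALSE]
      lead <- mem[order(mem$p, mem$pos), , drop = FALSE][1, ]
      out <- rbind(out, data.frame(
        chrom = chr, start = min(mem$pos), end = max(mem$pos),
        n_variants = nrow(mem), lead_id = lead$id, lead_pos = lead$pos,
        lead_p = lead$p, members = paste(mem$id, collapse = ","),
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
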