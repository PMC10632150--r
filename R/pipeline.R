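#' Run the per-genome GWAS for a simulated study
#'
#' For each cohort: applies phenotype QC, z-scores placental weight
#' within cohort, and regresses `pw_z ~ dosage + sex + ga_std` for the
#' requested genome using only the trios assigned to that genome's GWAS
#' by the study's overlap scheme. Per-cohort records are then combined
#' by fixed-effects meta-analysis when there is more than one cohort.
#'
#' @param study a `trio_study` from [simulate_study()].
#' @param genome `"child"`, `"mother"` or `"father"`.
#' @param qc apply the phenotype QC filters first (default TRUE).
#' @return a `gwas_records` data.frame (meta-analyzed across cohorts).
#' @export
study_gwas <- function(study, genome = c("child", "mother", "father"),
                       qc = TRUE) {
  genome <- match.arg(genome)
  per_cohort <- vector("list", length(study$cohorts))
  for (k in seq_along(study$cohorts)) {
    co <- study$cohorts[[k]]
    phen <- co$phenotypes
    keep_rows <- seq_len(nrow(phen))
    if (qc) {
      qcres <- apply_qc(phen)
      keep_rows <- match(qcres$kept$iid, phen$iid)
      phen <- qcres$kept
    }
    phen <- zscore_phenotype(phen)
    idx <- intersect(study$truth$membership[[k]][[genome]], keep_rows)
    sel <- match(idx, keep_rows)
    dos <- switch(genome,
                  child = child_dosage(co$trios),
                  mother = co$trios$mother,
                  father = co$trios$father)[idx, , drop = FALSE]
    ga_std <- (phen$ga_days[sel] - mean(phen$ga_days[sel])) /
      stats::sd(phen$ga_days[sel])
    covs <- cbind(sex = phen$sex[sel], ga_std = ga_std)
    per_cohort[[k]] <- run_single_genome_gwas(
      dos, phen$pw_z[sel], covariates = covs,
      variants = co$trios$variants)
  }
  if (length(per_cohort) == 1) per_cohort[[1]]
  else meta_fixed_effects(per_cohort)
}

#' Assemble the WLM input triple from three per-genome GWAS
#'
#' Matches the child, mother and father records on variant id (alleles
#' are harmonized to the child orientation) and returns the per-variant
#' triple expected by [wlm_partition()]. Variants missing from any of
#' the three GWAS are excluded.
#'
#' @param child,mother,father `gwas_records` data.frames.
#' @return data.frame with id/chrom/pos and beta/se/n per genome.
#' @export
gwas_triple <- function(child, mother, father) {
  mother <- harmonize_alleles(mother, child)
  father <- harmonize_alleles(father, child)
  ids <- Reduce(intersect, list(child$id, mother$id, father$id))
  ic <- match(ids, child$id); im <- match(ids, mother$id)
  iff <- match(ids, father$id)
  ok <- !is.na(child$beta[ic]) & !is.na(mother$beta[im]) &
    !is.na(father$beta[iff])
  ic <- ic[ok]; im <- im[ok]; iff <- iff[ok]
  data.frame(id = child$id[ic], chrom = child$chrom[ic],
             pos = child$pos[ic], ea = child$ea[ic], oa = child$oa[ic],
             beta_c = child$beta[ic], se_c = child$se[ic], n_c = child$n[ic],
             beta_m = mother$beta[im], se_m = mother$se[im],
             n_m = mother$n[im],
             beta_f = father$beta[iff], se_f = father$se[iff],
             n_f = father$n[iff],
             stringsAsFactors = FALSE)
}
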