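# shared fixtures: all synthetic, generated in code at test time

# one-cohort study with a single (or few) variant(s) and chosen effects
make_study <- function(n, eta_c = 0, eta_m = 0, eta_f = 0, delta = 0,
                       seed = 1, m = 1, p = c(0.5, 0.5), ...) {
  simulate_study(simulation_config(
    trios_per_cohort = n, n_variants = m,
    allele_freq_range = p, eta_c = eta_c, eta_m = eta_m,
    eta_f = eta_f, delta_poe = delta, seed = seed, ...))
}

# standardized phenotype + aligned covariates for cohort 1 of a study,
# skipping QC (simulated data are clean; QC is tested separately).
# scale = "generative" divides by the known 132.5 g generative SD so
# coefficients sit on the same scale as the generative effects;
# "zscore" uses the within-cohort sample SD as on real data.
study_pheno <- function(study, scale = c("generative", "zscore")) {
  scale <- match.arg(scale)
  ph <- study$cohorts[[1]]$phenotypes
  z <- if (scale == "generative") {
    (ph$pw_g - mean(ph$pw_g)) / study$config$pw_sd_g
  } else {
    zscore_phenotype(ph)$pw_z
  }
  ga_std <- (ph$ga_days - mean(ph$ga_days)) / sd(ph$ga_days)
  list(z = z, cov = cbind(sex = ph$sex, ga_std = ga_std))
}

# marginal GWAS triple for one simulated study (full-trio overlap)
study_triple <- function(study, qc = FALSE) {
  gwas_triple(study_gwas(study, "child", qc = qc),
              study_gwas(study, "mother", qc = qc),
              study_gwas(study, "father", qc = qc))
}

# overlap terms implied by full-trio sampling: for null variants the
# child/parent marginal estimates correlate like the genotypes (0.5),
# mother/father estimates are uncorrelated
full_trio_overlap <- function(n) {
  c(t_cm = estimate_overlap_term(n, n, n, 0.5),
    t_cf = estimate_overlap_term(n, n, n, 0.5),
    t_mf = estimate_overlap_term(n, n, n, 0))
}

# build a trio_genotypes object from explicit matrices (tiny fixtures)
manual_trios <- function(hap_m, hap_p, mother, father, freqs = NULL) {
  m <- ncol(hap_m)
  out <- list(hap_maternal = hap_m, hap_paternal = hap_p,
              mother = mother, father = father,
              freqs = freqs %||% rep(0.5, m),
              variants = data.frame(chrom = "1", pos = seq_len(m) * 1e5,
                                    ref = "A", alt = "G",
                                    id = sprintf("rs%06d", seq_len(m)),
                                    stringsAsFactors = FALSE))
  class(out) <- "trio_genotypes"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
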