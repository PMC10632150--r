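#' Build a simulation configuration for synthetic trio cohorts
#'
#' Defines the generative model used by [simulate_study()]: parental
#' genotypes drawn under Hardy-Weinberg equilibrium and random mating,
#' Mendelian transmission with tracked parental origin, and a phenotype
#' built from additive fetal, maternal and paternal per-allele effects
#' plus an optional effect carried only by the maternally transmitted
#' allele (a parent-of-origin effect, as seen at imprinted loci).
#'
#' Effect sizes are in phenotype standard-deviation units per effect
#' allele; the phenotype is materialized in grams via `pw_mean_g` and
#' `pw_sd_g`. Birth weight is generated alongside placental weight with
#' its own effect vectors and a correlated residual.
#'
#' @param n_cohorts number of cohorts to simulate.
#' @param trios_per_cohort complete mother-father-child trios per cohort
#'   (at least 2).
#' @param n_variants number of independent biallelic variants.
#' @param allele_freq_range length-2 numeric, effect-allele frequencies are
#'   drawn uniformly from this open interval; both ends strictly in (0,1).
#' @param eta_c,eta_m,eta_f per-variant conditional fetal, maternal and
#'   paternal effects (s.d. units per allele); scalars are recycled.
#' @param delta_poe per-variant effect of the maternally transmitted allele
#'   only, net of the additive terms (s.d. units).
#' @param beta_sex effect of sex (coded 0/1) on the phenotype, s.d. units.
#' @param beta_ga effect of standardized gestational duration, s.d. units
#'   per standardized day.
#' @param resid_sd residual standard deviation of the latent phenotype
#'   (s.d. units, must be positive).
#' @param pw_mean_g,pw_sd_g mean and s.d. of placental weight in grams used
#'   to materialize the latent scale; `pw_sd_g` defaults to 132.5 g, the
#'   conversion constant used throughout the package.
#' @param bw_mean_g,bw_sd_g same for birth weight.
#' @param ga_mean_days,ga_sd_days gestational duration distribution (days).
#' @param bw_eta_c,bw_eta_m,bw_eta_f per-variant effects on birth weight;
#'   default to the placental-weight effects scaled by `bw_share`.
#' @param bw_share scaling applied to PW effects to obtain default BW
#'   effects (captures shared genetics of the two phenotypes).
#' @param bw_resid_cor correlation between the PW and BW residuals.
#' @param overlap_scheme one of `"full-trios"` (the child, mother and
#'   father GWAS all use every trio), `"disjoint"` (trios split into three
#'   non-overlapping groups, one per GWAS) or `"mixed"` (a fraction
#'   `overlap_fraction` shared by all three, the rest disjoint).
#' @param overlap_fraction fraction of trios in all three GWAS when
#'   `overlap_scheme = "mixed"`.
#' @param genotype_error_rate per-variant probability that a child's
#'   haplotype origin labels are flipped (mis-phasing); scalar or
#'   per-variant vector.
#' @param variant_spacing_bp physical spacing of variants on the single
#'   synthetic chromosome, base pairs.
#' @param seed integer seed controlling all randomness of the simulation.
#'
#' @return an object of class `triopart_config` (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(trios_per_cohort = 100, n_variants = 5,
#'                          eta_c = 0.3, seed = 1)
#' study <- simulate_study(cfg)
#' str(study$phenotypes)
simulation_config <- function(n_cohorts = 1,
                              trios_per_cohort = 1000,
                              n_variants = 10,
                              allele_freq_range = c(0.1, 0.9),
                              eta_c = 0, eta_m = 0, eta_f = 0,
                              delta_poe = 0,
                              beta_sex = 0.1,
                              beta_ga = 0.3,
                              resid_sd = 1,
                              pw_mean_g = 670, pw_sd_g = 132.5,
                              bw_mean_g = 3500, bw_sd_g = 500,
                              ga_mean_days = 280, ga_sd_days = 9,
                              bw_eta_c = NULL, bw_eta_m = NULL,
                              bw_eta_f = NULL,
                              bw_share = 0.6,
                              bw_resid_cor = 0.3,
                              overlap_scheme = c("full-trios", "disjoint", "mixed"),
                              overlap_fraction = 0.5,
                              genotype_error_rate = 0,
                              variant_spacing_bp = 100000L,
                              seed = 1L) {
  overlap_scheme <- match.arg(overlap_scheme)
  stopifnot(n_cohorts >= 1, n_variants >= 1)
  if (trios_per_cohort < 2)
    stop("trios_per_cohort must be at least 2")
  if (length(allele_freq_range) != 2 ||
      allele_freq_range[1] <= 0 || allele_freq_range[2] >= 1 ||
      allele_freq_range[1] > allele_freq_range[2])
    stop("allele_freq_range must lie strictly inside (0, 1)")
  if (resid_sd <= 0) stop("resid_sd must be positive")
  if (pw_sd_g <= 0) stop("pw_sd_g must be positive")
  if (any(genotype_error_rate < 0) || any(genotype_error_rate > 1))
    stop("genotype_error_rate must be in [0, 1]")
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must be in [0, 1]")

  recycle <- function(x, nm) {
    if (length(x) == 1) x <- rep(x, n_variants)
    if (length(x) != n_variants)
      stop(sprintf("%s must have length 1 or n_variants (%d)", nm, n_variants))
    x
  }
  eta_c <- recycle(eta_c, "eta_c")
  eta_m <- recycle(eta_m, "eta_m")
  eta_f <- recycle(eta_f, "eta_f")
  delta_poe <- recycle(delta_poe, "delta_poe")
  if (is.null(bw_eta_c)) bw_eta_c <- bw_share * eta_c
  if (is.null(bw_eta_m)) bw_eta_m <- bw_share * eta_m
  if (is.null(bw_eta_f)) bw_eta_f <- bw_share * eta_f
  bw_eta_c <- recycle(bw_eta_c, "bw_eta_c")
  bw_eta_m <- recycle(bw_eta_m, "bw_eta_m")
  bw_eta_f <- recycle(bw_eta_f, "bw_eta_f")
  genotype_error_rate <- recycle(genotype_error_rate, "genotype_error_rate")

  out <- list(
    n_cohorts = as.integer(n_cohorts),
    trios_per_cohort = as.integer(trios_per_cohort),
    n_variants = as.integer(n_variants),
    allele_freq_range = as.numeric(allele_freq_range),
    eta_c = eta_c, eta_m = eta_m, eta_f = eta_f, delta_poe = delta_poe,
    beta_sex = beta_sex, beta_ga = beta_ga, resid_sd = resid_sd,
    pw_mean_g = pw_mean_g, pw_sd_g = pw_sd_g,
    bw_mean_g = bw_mean_g, bw_sd_g = bw_sd_g,
    ga_mean_days = ga_mean_days, ga_sd_days = ga_sd_days,
    bw_eta_c = bw_eta_c, bw_eta_m = bw_eta_m, bw_eta_f = bw_eta_f,
    bw_resid_cor = bw_resid_cor,
    overlap_scheme = overlap_scheme,
    overlap_fraction = overlap_fraction,
    genotype_error_rate = genotype_error_rate,
    variant_spacing_bp = as.integer(variant_spacing_bp),
    seed = as.integer(seed)
  )
  class(out) <- "triopart_config"
  out
}

#' @export
print.triopart_config <- function(x, ...) {
  cat("triopart simulation config:",
      x$n_cohorts, "cohort(s) x", x$trios_per_cohort, "trios,",
      x$n_variants, "variants; overlap:", x$overlap_scheme, "\n")
  invisible(x)
}
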