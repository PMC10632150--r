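#' Draw parental genotypes under Hardy-Weinberg equilibrium
#'
#' Mother and father dosages at each variant are independent
#' Binomial(2, p) draws, i.e. random mating with no assortment,
#' inbreeding or LD between variants. This is the population model under
#' which offspring and parental genomes have correlation 1/2, the fixed
#' path coefficient used by the latent covariance model.
#'
#' @param config a [simulation_config()] object.
#' @param cohort_index which cohort to draw (affects the RNG substream).
#' @param freqs optional per-variant allele frequencies; drawn uniformly
#'   from `config$allele_freq_range` when `NULL`.
#' @return list with integer matrices `mother`, `father`
#'   (trios x variants, entries 0/1/2), the per-variant `freqs`, and a
#'   `variants` data.frame (chrom, pos, ref, alt, id).
#' @export
simulate_parents <- function(config, cohort_index = 1L, freqs = NULL) {
  stopifnot(inherits(config, "triopart_config"))
  n <- config$trios_per_cohort
  m <- config$n_variants
  set.seed(config$seed + 1000L * (cohort_index - 1L))
  if (is.null(freqs)) {
    freqs <- stats::runif(m, config$allele_freq_range[1],
                          config$allele_freq_range[2])
  }
  if (any(freqs <= 0) || any(freqs >= 1))
    stop("allele frequencies must lie strictly inside (0, 1)")
  mother <- matrix(stats::rbinom(n * m, 2L, rep(freqs, each = n)), n, m)
  father <- matrix(stats::rbinom(n * m, 2L, rep(freqs, each = n)), n, m)
  variants <- data.frame(
    chrom = "1",
    pos = seq_len(m) * config$variant_spacing_bp,
    ref = "A", alt = "G",
    id = sprintf("rs%06d", seq_len(m)),
    stringsAsFactors = FALSE
  )
  list(mother = mother, father = father, freqs = freqs, variants = variants)
}

#' Transmit one allele from each parent to the child, tracking origin
#'
#' Each child haplotype is a uniformly chosen allele of the corresponding
#' parent: a homozygous parent transmits its allele deterministically, a
#' heterozygous parent transmits the effect allele with probability 1/2.
#' Origin labels (which haplotype came from the mother) are recorded, so
#' the transmitted/non-transmitted decomposition downstream has ground
#' truth to recover.
#'
#' @param parents output of [simulate_parents()].
#' @param seed integer seed for the transmission draws.
#' @return an object of class `trio_genotypes`: list with integer matrices
#'   `hap_maternal`, `hap_paternal` (child haplotypes by declared origin,
#'   entries 0/1), `mother`, `father` dosage matrices, `freqs`, `variants`.
#' @export
transmit_haplotypes <- function(parents, seed = 1L) {
  mo <- parents$mother; fa <- parents$father
  if (!all(mo %in% 0:2) || !all(fa %in% 0:2))
    stop("parental dosages must be in {0, 1, 2}")
  set.seed(seed)
  draw <- function(dos) {
    # transmitted allele: 0 if dosage 0, 1 if dosage 2, Bernoulli(1/2) if het
    h <- matrix(0L, nrow(dos), ncol(dos))
    h[dos == 2L] <- 1L
    het <- dos == 1L
    h[het] <- stats::rbinom(sum(het), 1L, 0.5)
    h
  }
  out <- list(hap_maternal = draw(mo), hap_paternal = draw(fa),
              mother = mo, father = fa,
              freqs = parents$freqs, variants = parents$variants)
  class(out) <- "trio_genotypes"
  out
}

#' Child dosage from phased haplotypes
#' @param trios a `trio_genotypes` object.
#' @return integer matrix of child allele counts.
#' @export
child_dosage <- function(trios) {
  trios$hap_maternal + trios$hap_paternal
}

#' Flip child haplotype origin labels at random (mis-phasing)
#'
#' Simulates phasing error: with the given per-variant probability a
#' trio's maternal/paternal origin labels at that variant are exchanged.
#' The child's dosage is untouched -- only the declared parental origin is
#' wrong, which is exactly the failure mode the Mendelian-error swap rule
#' detects.
#'
#' @param trios a `trio_genotypes` object.
#' @param rate scalar or per-variant flip probability in \[0, 1\].
#' @param seed integer seed.
#' @return a `trio_genotypes` object with labels flipped.
#' @export
inject_genotype_errors <- function(trios, rate, seed = 1L) {
  m <- ncol(trios$hap_maternal)
  if (length(rate) == 1) rate <- rep(rate, m)
  stopifnot(length(rate) == m, all(rate >= 0), all(rate <= 1))
  set.seed(seed)
  n <- nrow(trios$hap_maternal)
  flip <- matrix(stats::rbinom(n * m, 1L, rep(rate, each = n)) == 1L, n, m)
  hm <- trios$hap_maternal; hp <- trios$hap_paternal
  tmp <- hm[flip]
  hm[flip] <- hp[flip]
  hp[flip] <- tmp
  trios$hap_maternal <- hm
  trios$hap_paternal <- hp
  trios
}

#' Generate placental- and birth-weight phenotypes from trio genotypes
#'
#' The latent standardized phenotype is
#' \deqn{z = \sum_j [\eta_{c,j}(g_c - 2p_j) + \eta_{m,j}(g_m - 2p_j) +
#'       \eta_{f,j}(g_f - 2p_j) + \delta_j(h_{mt} - p_j)]
#'       + \beta_{sex} sex + \beta_{ga} ga_{std} + \epsilon,}
#' with \eqn{\epsilon \sim N(0, \sigma^2_{resid})}; dosages are centred at
#' their expectation so the covariate terms do not shift the mean. Grams
#' are obtained as `pw_mean_g + pw_sd_g * z`. Birth weight uses its own
#' effect vectors and a residual correlated with the PW residual.
#'
#' @param trios a `trio_genotypes` object.
#' @param config a [simulation_config()] object.
#' @param cohort_id label written into the phenotype table.
#' @param seed integer seed for covariates and residuals.
#' @return data.frame with columns `cohort_id`, `iid`, `sex`, `ga_days`,
#'   `pw_g`, `bw_g` (one row per trio, i.e. per child).
#' @export
generate_phenotypes <- function(trios, config, cohort_id = "cohort1",
                                seed = 1L) {
  m <- ncol(trios$hap_maternal)
  if (length(config$eta_c) != m)
    stop("effect vector length does not match number of variants")
  n <- nrow(trios$hap_maternal)
  set.seed(seed)
  sex <- stats::rbinom(n, 1L, 0.5)
  ga_days <- stats::rnorm(n, config$ga_mean_days, config$ga_sd_days)
  ga_std <- (ga_days - config$ga_mean_days) / config$ga_sd_days

  gc <- child_dosage(trios)
  p2 <- matrix(2 * trios$freqs, n, m, byrow = TRUE)
  pc <- matrix(trios$freqs, n, m, byrow = TRUE)
  genetic <- function(ec, em, ef, dl) {
    as.vector((gc - p2) %*% ec + (trios$mother - p2) %*% em +
              (trios$father - p2) %*% ef +
              (trios$hap_maternal - pc) %*% dl)
  }
  g_pw <- genetic(config$eta_c, config$eta_m, config$eta_f, config$delta_poe)
  g_bw <- genetic(config$bw_eta_c, config$bw_eta_m, config$bw_eta_f,
                  rep(0, m))
  e1 <- stats::rnorm(n, 0, config$resid_sd)
  e2 <- stats::rnorm(n, 0, config$resid_sd)
  r <- config$bw_resid_cor
  e_bw <- r * e1 + sqrt(1 - r^2) * e2
  z_pw <- g_pw + config$beta_sex * sex + config$beta_ga * ga_std + e1
  z_bw <- g_bw + config$beta_sex * sex + config$beta_ga * ga_std + e_bw
  data.frame(
    cohort_id = cohort_id,
    iid = sprintf("%s_child%05d", cohort_id, seq_len(n)),
    sex = sex,
    ga_days = ga_days,
    pw_g = config$pw_mean_g + config$pw_sd_g * z_pw,
    bw_g = config$bw_mean_g + config$bw_sd_g * z_bw,
    stringsAsFactors = FALSE
  )
}

#' GWAS membership lists under a sample-overlap scheme
#'
#' Decides which trios contribute to each of the three per-genome GWAS.
#' With `"full-trios"` all trios enter all three analyses (maximal sample
#' overlap); with `"disjoint"` the trios are split into three groups, one
#' per genome, so the GWAS share no individuals; `"mixed"` shares a
#' fraction of trios across all three and splits the remainder.
#'
#' @param n number of trios.
#' @param scheme overlap scheme string.
#' @param fraction shared fraction for `"mixed"`.
#' @return list with integer index vectors `child`, `mother`, `father`.
#' @export
overlap_membership <- function(n, scheme = c("full-trios", "disjoint", "mixed"),
                               fraction = 0.5) {
  scheme <- match.arg(scheme)
  idx <- seq_len(n)
  if (scheme == "full-trios")
    return(list(child = idx, mother = idx, father = idx))
  if (scheme == "disjoint") {
    grp <- rep(1:3, length.out = n)[order(idx)]
    return(list(child = idx[grp == 1], mother = idx[grp == 2],
                father = idx[grp == 3]))
  }
  n_shared <- floor(n * fraction)
  shared <- idx[seq_len(n_shared)]
  rest <- idx[idx > n_shared]
  grp <- rep(1:3, length.out = length(rest))
  list(child = c(shared, rest[grp == 1]),
       mother = c(shared, rest[grp == 2]),
       father = c(shared, rest[grp == 3]))
}

#' Simulate a complete multi-cohort trio study
#'
#' Runs [simulate_parents()], [transmit_haplotypes()],
#' [inject_genotype_errors()] and [generate_phenotypes()] for each cohort
#' and collects a truth registry recording the generative effects, the
#' realized allele frequencies and the GWAS membership lists implied by
#' the overlap scheme.
#'
#' @param config a [simulation_config()] object.
#' @return list of class `trio_study`: `cohorts` (each with `trios` and
#'   `phenotypes`), `truth` (effects, freqs per cohort, membership),
#'   `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "triopart_config"))
  cohorts <- vector("list", config$n_cohorts)
  freqs_by_cohort <- vector("list", config$n_cohorts)
  membership <- vector("list", config$n_cohorts)
  for (k in seq_len(config$n_cohorts)) {
    par <- simulate_parents(config, cohort_index = k)
    trios <- transmit_haplotypes(par, seed = config$seed + 1000L * (k - 1L) + 1L)
    if (any(config$genotype_error_rate > 0))
      trios <- inject_genotype_errors(trios, config$genotype_error_rate,
                                      seed = config$seed + 1000L * (k - 1L) + 2L)
    cid <- sprintf("cohort%d", k)
    phen <- generate_phenotypes(trios, config, cohort_id = cid,
                                seed = config$seed + 1000L * (k - 1L) + 3L)
    cohorts[[k]] <- list(trios = trios, phenotypes = phen, cohort_id = cid)
    freqs_by_cohort[[k]] <- par$freqs
    membership[[k]] <- overlap_membership(config$trios_per_cohort,
                                          config$overlap_scheme,
                                          config$overlap_fraction)
  }
  truth <- list(
    eta_c = config$eta_c, eta_m = config$eta_m, eta_f = config$eta_f,
    delta_poe = config$delta_poe,
    freqs = freqs_by_cohort,
    membership = membership
  )
  out <- list(cohorts = cohorts, truth = truth, config = config)
  class(out) <- "trio_study"
  out
}
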