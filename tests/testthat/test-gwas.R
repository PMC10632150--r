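test_that("phenotype QC applies the published exclusion rules", {
  ph <- data.frame(
    cohort_id = "a",
    pw_g = c(150, 700, 1600, 700, 700, 700, 700, 700, 710, 690, 705),
    ga_days = c(280, 280, 280, 250, 305, 259, 300, 280, 280, 280, 280))
  res <- apply_qc(ph)
  expect_equal(unname(res$report["pw_below_200g"]), 1)   # 150 g out
  expect_equal(unname(res$report["pw_above_1500g"]), 1)  # 1600 g out
  expect_equal(unname(res$report["ga_below_259d"]), 1)   # 250 d out
  expect_equal(unname(res$report["ga_above_300d"]), 1)   # 305 d out
  # inclusive gestational bounds: 259 and 300 days retained
  expect_true(all(c(259, 300) %in% res$kept$ga_days))
  expect_true(700 %in% res$kept$pw_g)
})

test_that("the 5-s.d. filter removes exactly the constructed outlier", {
  # enough rows that one extreme value can exceed 5 pre-exclusion s.d.
  set.seed(55)
  base <- round(rnorm(60, 680, 40))
  out_val <- 1400  # below the 1500 g hard cap, far beyond 5 s.d.
  x <- c(base, out_val)
  stopifnot(abs(out_val - mean(x)) > 5 * sd(x))
  ph <- data.frame(cohort_id = "a", pw_g = x, ga_days = 280)
  res <- apply_qc(ph)
  expect_equal(unname(res$report["pw_beyond_5sd"]), 1)
  expect_equal(nrow(res$kept), length(base))
  expect_false(out_val %in% res$kept$pw_g)
})

test_that("z-scoring standardizes each cohort independently", {
  ph <- data.frame(cohort_id = c("a", "a", "b", "b"),
                   pw_g = c(600, 800, 300, 500), ga_days = 280)
  z <- zscore_phenotype(ph)
  # hand-computed: each cohort has mean +-100 gap, sd = sqrt(2)*100
  expect_equal(z$pw_z, c(-1, 1, -1, 1) / sqrt(2))
  # affine invariance: grams -> kilograms leaves z unchanged
  ph2 <- ph; ph2$pw_g <- ph$pw_g / 1000 + 5
  expect_equal(zscore_phenotype(ph2)$pw_z, z$pw_z)
})

test_that("degenerate cohorts are rejected by z-scoring", {
  expect_error(zscore_phenotype(
    data.frame(cohort_id = "a", pw_g = c(700, 700, 700), ga_days = 280)),
    "constant")
  expect_error(zscore_phenotype(
    data.frame(cohort_id = c("a", "b", "b"), pw_g = c(1, 2, 3),
               ga_days = 280)),
    "fewer than 2")
})

test_that("per-variant slopes match the closed-form OLS oracle", {
  set.seed(77)
  n <- 30
  g <- rbinom(n, 2, 0.4)
  sex <- rbinom(n, 1, 0.5)
  y <- 0.25 * g + 0.1 * sex + rnorm(n)
  rec <- run_single_genome_gwas(matrix(g, ncol = 1), y,
                                covariates = cbind(sex = sex))
  oracle <- summary(lm(y ~ g + sex))$coefficients
  expect_equal(rec$beta, oracle["g", "Estimate"], tolerance = 1e-10)
  expect_equal(rec$se, oracle["g", "Std. Error"], tolerance = 1e-10)
  expect_equal(rec$p, oracle["g", "Pr(>|t|)"], tolerance = 1e-10)
})

test_that("monomorphic variants get missing statistics, EAF retained", {
  y <- rnorm(20)
  dos <- cbind(rep(2L, 20), rbinom(20, 2, 0.5))
  rec <- run_single_genome_gwas(dos, y)
  expect_true(is.na(rec$beta[1]))
  expect_equal(rec$eaf[1], 1)
  expect_false(is.na(rec$beta[2]))
})

test_that("null association scan has nominal type-I error", {
  set.seed(101)
  n <- 300; m <- 400
  dos <- matrix(rbinom(n * m, 2, 0.3), n, m)
  y <- rnorm(n)
  rec <- run_single_genome_gwas(dos, y)
  rate <- mean(rec$p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / m))
})

test_that("rank-deficient covariate designs are reported by column", {
  y <- rnorm(10)
  dos <- matrix(rbinom(10, 2, 0.5), ncol = 1)
  covs <- cbind(a = rep(1, 10), b = rep(2, 10))
  expect_error(run_single_genome_gwas(dos, y, covariates = covs),
               "rank-deficient")
})

test_that("fixed-effects meta matches the closed-form IVW oracle", {
  mk <- function(beta, se, n = 4000, ea = "G", oa = "A") {
    structure(data.frame(id = "rs1", chrom = "1", pos = 100, ea = ea,
                         oa = oa, eaf = 0.3, beta = beta, se = se,
                         p = 0.5, n = n, n_studies = 1L),
              class = c("gwas_records", "data.frame"))
  }
  meta <- meta_fixed_effects(list(mk(0.1, 0.1), mk(0.3, 0.1)))
  expect_equal(meta$beta, 0.2, tolerance = 1e-12)
  expect_equal(meta$se, 0.1 / sqrt(2), tolerance = 1e-12)
  expect_equal(meta$n, 8000)
  expect_equal(meta$n_studies, 2L)
  # k identical studies: se_meta = se / sqrt(k)
  meta3 <- meta_fixed_effects(list(mk(0.2, 0.07), mk(0.2, 0.07),
                                   mk(0.2, 0.07)))
  expect_equal(meta3$se, 0.07 / sqrt(3), tolerance = 1e-12)
  expect_equal(meta3$q, 0, tolerance = 1e-12)
  # single study passes through, Q undefined
  meta1 <- meta_fixed_effects(list(mk(0.1, 0.1)))
  expect_equal(meta1$beta, 0.1)
  expect_true(is.na(meta1$q))
  # swapped alleles in study 2 harmonize to the same answer
  metaswap <- meta_fixed_effects(list(mk(0.1, 0.1),
                                      mk(-0.3, 0.1, ea = "A", oa = "G")))
  expect_equal(metaswap$beta, 0.2, tolerance = 1e-12)
})

test_that("fixed-effects meta agrees with an independent implementation", {
  skip_if_not_installed("metafor")
  set.seed(5)
  b <- rnorm(6, 0.1, 0.05); s <- runif(6, 0.02, 0.1)
  recs <- lapply(seq_along(b), function(i)
    structure(data.frame(id = "rs1", chrom = "1", pos = 1, ea = "G",
                         oa = "A", eaf = 0.5, beta = b[i], se = s[i],
                         p = 0.5, n = 1000, n_studies = 1L),
              class = c("gwas_records", "data.frame")))
  meta <- meta_fixed_effects(recs)
  or <- metafor::rma(yi = b, sei = s, method = "FE")
  expect_equal(meta$beta, as.numeric(or$beta), tolerance = 1e-10)
  expect_equal(meta$se, or$se, tolerance = 1e-10)
  expect_equal(meta$q, or$QE, tolerance = 1e-10)
})

test_that("Cochran's Q is chi-squared under a fixed effect", {
  set.seed(31)
  k <- 5; reps <- 400
  qs <- replicate(reps, {
    se <- rep(0.1, k)
    b <- 0.2 + se * rnorm(k)
    w <- 1 / se^2
    bm <- sum(w * b) / sum(w)
    sum(w * (b - bm)^2)
  })
  expect_lt(abs(mean(qs) - (k - 1)), 3 * sqrt(2 * (k - 1) / reps))
})

test_that("meta filter drops sparse and small-sample variants", {
  rec <- data.frame(id = paste0("rs", 1:4), chrom = "1", pos = 1:4,
                    ea = "G", oa = "A", eaf = 0.5, beta = 0, se = 1,
                    p = 0.5, n = c(10000, 4999, 5000, 10000),
                    n_studies = c(1L, 3L, 2L, 2L))
  kept <- filter_meta(rec)
  expect_identical(kept$id, c("rs3", "rs4"))  # rs1: 1 study; rs2: n<5000
  expect_equal(nrow(filter_meta(rec[0, ])), 0)
})

test_that("locus definition follows the >500 kb single-linkage rule", {
  mk <- function(pos, p) data.frame(id = sprintf("s%d", seq_along(pos)),
                                    chrom = "1", pos = pos, ea = "G",
                                    oa = "A", eaf = 0.5, beta = 0, se = 1,
                                    p = p, n = 1e5, n_studies = 3L)
  # two significant SNPs 600 kb apart: separate loci
  loci <- define_loci(mk(c(1e6, 1.6e6), c(1e-9, 1e-10)))
  expect_equal(nrow(loci), 2)
  # chain at 300-kb spacing spanning 900 kb: one locus by single linkage
  loci2 <- define_loci(mk(c(1e6, 1.3e6, 1.6e6, 1.9e6), rep(1e-9, 4)))
  expect_equal(nrow(loci2), 1)
  expect_equal(loci2$n_variants, 4)
  # brute-force clustering oracle on a random configuration
  set.seed(8)
  pos <- sort(sample.int(1e7, 30))
  pvals <- 10^runif(30, -12, -4)
  loci3 <- define_loci(mk(pos, pvals))
  sig <- pos[pvals < 5e-8]
  oracle_groups <- if (length(sig)) cumsum(c(1, diff(sig) > 5e5)) else integer(0)
  expect_equal(nrow(loci3), length(unique(oracle_groups)))
  # no significant variants: empty
  expect_equal(nrow(define_loci(mk(1e6, 1e-4))), 0)
  # lead is the smallest p, ties broken by position
  loci4 <- define_loci(mk(c(1e6, 1.1e6), c(1e-9, 1e-9)))
  expect_equal(loci4$lead_pos, 1e6)
})
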