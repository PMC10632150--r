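test_that("coloc posteriors sum to one and follow the threshold rule", {
  set.seed(11)
  for (i in 1:50) {
    m <- sample(3:40, 1)
    beta_a <- rnorm(m, 0, 0.1); beta_b <- rnorm(m, 0, 0.1)
    res <- colocalization_abf(beta_a, runif(m, 0.01, 0.1),
                              beta_b, runif(m, 0.01, 0.1))
    expect_equal(sum(res$pp), 1, tolerance = 1e-9)
    expect_true(all(res$pp >= 0))
    expect_equal(res$verdict, coloc_verdict(res$pp))
  }
  # verdict is a pure threshold rule over random probability vectors
  for (i in 1:200) {
    pp <- stats::runif(5); pp <- pp / sum(pp)
    names(pp) <- paste0("PP", 0:4)
    v <- coloc_verdict(pp)
    expected <- if (pp["PP4"] > 0.8) "colocalized"
                else if (pp["PP3"] > 0.8) "distinct" else "undetermined"
    expect_equal(v, expected)
  }
})

test_that("shared and distinct causal variants are told apart", {
  # identical strong single-variant signal: colocalized
  se <- rep(0.02, 20)
  beta <- rep(0, 20); beta[7] <- 0.2
  res <- colocalization_abf(beta, se, beta, se)
  expect_equal(res$verdict, "colocalized")
  # two different lone causal variants: distinct
  beta2 <- rep(0, 20); beta2[15] <- 0.2
  res2 <- colocalization_abf(beta, se, beta2, se)
  expect_equal(res2$verdict, "distinct")
  # both null: PP0 dominates
  res3 <- colocalization_abf(rep(0, 20), se, rep(0, 20), se)
  expect_equal(res3$verdict, "undetermined")
  expect_gt(res3$pp["PP0"], 0.9)
})

test_that("hypothesis sums match a hand-computed 3-variant region", {
  # direct enumeration of the H0-H4 sums from per-variant ABFs
  beta_a <- c(0.1, 0.02, -0.03); se_a <- c(0.03, 0.04, 0.05)
  beta_b <- c(0.08, -0.01, 0.02); se_b <- c(0.04, 0.03, 0.06)
  W <- 0.15^2
  abf <- function(b, s) {
    r <- W / (W + s^2)
    sqrt(1 - r) * exp(r * (b / s)^2 / 2)
  }
  a <- abf(beta_a, se_a); b <- abf(beta_b, se_b)
  p1 <- 1e-4; p2 <- 1e-4; p12 <- 1e-5
  h0 <- 1
  h1 <- p1 * sum(a)
  h2 <- p2 * sum(b)
  h3 <- p1 * p2 * (sum(a) * sum(b) - sum(a * b))
  h4 <- p12 * sum(a * b)
  expected <- c(h0, h1, h2, h3, h4) / sum(h0, h1, h2, h3, h4)
  res <- colocalization_abf(beta_a, se_a, beta_b, se_b)
  expect_equal(unname(res$pp), expected, tolerance = 1e-9)
})

test_that("coloc input contracts are enforced", {
  expect_error(colocalization_abf(0.1, 0.1, 0.1, 0.1), "at least 2")
})

test_that("PW/BW classification matches the CI truth table", {
  # worked example: PW 0.30 (SE 0.02) vs BW 0.05 (SE 0.02):
  # intervals (0.2608, 0.3392) and (0.0108, 0.0892) are disjoint
  expect_equal(classify_pw_bw(0.30, 0.02, 0.05, 0.02),
               "predominantly or only PW")
  # identical estimates: full overlap
  expect_equal(classify_pw_bw(0.30, 0.02, 0.30, 0.02),
               "PW and BW same direction")
  # disjoint and opposite with p < 0.05
  expect_equal(classify_pw_bw(0.30, 0.02, -0.10, 0.03),
               "PW and BW opposite directions")
  # missing BW proxy
  expect_equal(classify_pw_bw(0.30, 0.02, NA, NA), "no BW proxy")
  # exhaustive enumeration of overlap x sign x significance cells
  zq <- qnorm(0.975)
  grid <- expand.grid(overlap = c(TRUE, FALSE), sign = c(1, -1),
                      sig = c(TRUE, FALSE))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    pw <- 0.3; pw_se <- 0.02
    bw_se <- if (g$sig) 0.02 else 0.2
    bw <- if (g$overlap) g$sign * 0.29 else g$sign * 0.05
    if (g$overlap && g$sign < 0) bw <- 0.28  # keep overlap feasible
    lo_p <- pw - zq * pw_se; hi_p <- pw + zq * pw_se
    lo_b <- bw - zq * bw_se; hi_b <- bw + zq * bw_se
    disjoint <- hi_p < lo_b || hi_b < lo_p
    p_bw <- 2 * pnorm(abs(bw / bw_se), lower.tail = FALSE)
    expected <- if (!disjoint) "PW and BW same direction"
      else if (pw * bw < 0 && p_bw < 0.05) "PW and BW opposite directions"
      else "predominantly or only PW"
    expect_equal(classify_pw_bw(pw, pw_se, bw, bw_se), expected)
  }
})

test_that("single-instrument IVW equals the Wald ratio exactly", {
  res <- mr_estimate(0.2, 0.02, 0.11, 0.03, method = "ivw")
  expect_equal(res$estimate, 0.11 / 0.2, tolerance = 1e-12)
})

test_that("IVW equals weighted least squares through the origin", {
  set.seed(13)
  for (i in 1:10) {
    k <- sample(5:30, 1)
    bx <- runif(k, 0.05, 0.3)
    se_out <- runif(k, 0.01, 0.1)
    by <- 0.4 * bx + se_out * rnorm(k)
    res <- mr_estimate(bx, rep(0.01, k), by, se_out, method = "ivw")
    fit <- lm(by ~ 0 + bx, weights = 1 / se_out^2)
    expect_equal(res$estimate, unname(coef(fit)["bx"]), tolerance = 1e-10)
    # fixed-effect SE: 1/sqrt(sum w bx^2)
    expect_equal(res$se, 1 / sqrt(sum(bx^2 / se_out^2)), tolerance = 1e-12)
  }
})

test_that("IVW recovers the causal slope from valid instruments", {
  set.seed(17)
  k <- 20
  bx <- runif(k, 0.05, 0.3); se_x <- rep(0.01, k)
  se_y <- rep(0.02, k)
  by <- 0.5 * bx + se_y * rnorm(k)
  res <- mr_estimate(bx, se_x, by, se_y, method = "ivw")
  expect_lt(abs(res$estimate - 0.5), 3 * res$se)
  expect_equal(unname(res$ci), res$estimate + c(-1, 1) * qnorm(0.975) * res$se)
})

test_that("Egger detects directional pleiotropy and corrects the slope", {
  set.seed(19)
  k <- 40
  bx <- runif(k, 0.1, 0.4)
  se_y <- rep(0.02, k)
  pleio <- 0.05  # constant directional pleiotropy on every instrument
  by <- 0.3 * bx + pleio + se_y * rnorm(k)
  egger <- mr_estimate(bx, rep(0.01, k), by, se_y, method = "egger")
  ivw <- mr_estimate(bx, rep(0.01, k), by, se_y, method = "ivw")
  expect_gt(abs(egger$intercept / egger$intercept_se), 2)
  expect_lt(abs(egger$estimate - 0.3), abs(ivw$estimate - 0.3))
  # under no pleiotropy Egger and IVW agree
  by0 <- 0.3 * bx + se_y * rnorm(k)
  e0 <- mr_estimate(bx, rep(0.01, k), by0, se_y, method = "egger")
  i0 <- mr_estimate(bx, rep(0.01, k), by0, se_y, method = "ivw")
  expect_lt(abs(e0$estimate - i0$estimate), 3 * e0$se)
})

test_that("weighted median resists 40% invalid instruments", {
  set.seed(23)
  k <- 25; n_bad <- 10
  bx <- runif(k, 0.1, 0.4)
  se_y <- rep(0.02, k)
  # invalid instruments with balanced-sign pleiotropy (40% of the set)
  pleio <- c(rep(c(0.15, -0.15), n_bad / 2), rep(0, k - n_bad))
  by <- 0.5 * bx + pleio + se_y * rnorm(k)
  wm <- mr_estimate(bx, rep(0.005, k), by, se_y,
                    method = "weighted-median", n_boot = 300, seed = 2)
  expect_lt(abs(wm$estimate - 0.5), 3 * wm$se)
  pwm <- mr_estimate(bx, rep(0.005, k), by, se_y,
                     method = "penalized-weighted-median",
                     n_boot = 300, seed = 2)
  expect_lt(abs(pwm$estimate - 0.5), 3 * pwm$se)
  # under directional pleiotropy the median is less biased than IVW
  pleio_dir <- c(rep(0.15, n_bad), rep(0, k - n_bad))
  by2 <- 0.5 * bx + pleio_dir + se_y * rnorm(k)
  wm2 <- mr_estimate(bx, rep(0.005, k), by2, se_y,
                     method = "weighted-median", n_boot = 300, seed = 3)
  ivw2 <- mr_estimate(bx, rep(0.005, k), by2, se_y, method = "ivw")
  expect_lt(abs(wm2$estimate - 0.5), abs(ivw2$estimate - 0.5))
})

test_that("instrument-count requirements are enforced", {
  expect_error(mr_estimate(c(0.1, 0.2), c(0.01, 0.01), c(0.1, 0.1),
                           c(0.02, 0.02), method = "egger"),
               "at least 3")
})

test_that("liability transformation uses the standard factor", {
  expect_equal(liability_adjust(0, 0.3), 0)
  # K = 0.5: factor 0.25 / dnorm(0)
  expect_equal(liability_adjust(1, 0.5), 0.25 / dnorm(0),
               tolerance = 1e-12)
  # forward then inverse at the preeclampsia prevalence is the identity
  b <- 0.543
  expect_equal(liability_adjust(liability_adjust(b, 0.046),
                                0.046, inverse = TRUE),
               b, tolerance = 1e-12)
  expect_error(liability_adjust(1, 0), "prevalence")
  expect_error(liability_adjust(1, 1), "prevalence")
})

test_that("s.d.-to-grams conversion uses the 132.5 g constant", {
  expect_equal(sd_to_grams(1), 132.5)
  expect_equal(sd_to_grams(0), 0)
  expect_equal(grams_to_sd(sd_to_grams(0.358)), 0.358, tolerance = 1e-12)
  expect_equal(sd_to_grams(2, sd_g = 100), 200)
})
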