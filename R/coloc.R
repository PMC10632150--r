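#' Bayesian colocalization of two association signals via approximate
#' Bayes factors
#'
#' For each variant the approximate Bayes factor against the null is
#' computed from the estimate and its standard error (Wakefield's
#' approximation): with `V = se^2`, `W` the prior variance of the true
#' effect and `r = W / (W + V)`,
#' `log ABF = 0.5 * (log(1 - r) + r * z^2)`. Per-region sums over the
#' five hypotheses (H0 no association; H1/H2 association in one trait
#' only; H3 two distinct causal variants; H4 one shared causal variant)
#' are combined with the prior probabilities `p1`, `p2`, `p12` to give
#' posterior probabilities PP0..PP4. The verdict is `colocalized` when
#' PP4 > 0.8, `distinct` when PP3 > 0.8, otherwise `undetermined`.
#'
#' @param beta_a,se_a effect estimates and SEs for trait A over the
#'   region's variants.
#' @param beta_b,se_b same for trait B, on matched variants.
#' @param p1,p2 prior probability a variant is causal for A only / B
#'   only (default 1e-4 each).
#' @param p12 prior probability a variant is causal for both (default
#'   1e-5).
#' @param prior_sd prior standard deviation of true effects under the
#'   alternative, in phenotype-s.d. units (default 0.15, the usual
#'   quantitative-trait convention).
#' @return list of class `coloc_result`: `pp` (named PP0..PP4 summing to
#'   1), `verdict`, `n_variants`.
#' @export
colocalization_abf <- function(beta_a, se_a, beta_b, se_b,
                               p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                               prior_sd = 0.15) {
  m <- length(beta_a)
  if (m < 2 || length(beta_b) != m)
    stop("need at least 2 shared variants with matched estimates")
  stopifnot(all(se_a > 0), all(se_b > 0),
            p1 > 0, p1 < 1, p2 > 0, p2 < 1, p12 > 0, p12 < 1)
  labf <- function(beta, se) {
    V <- se^2
    r <- prior_sd^2 / (prior_sd^2 + V)
    0.5 * (log(1 - r) + r * (beta / se)^2)
  }
  l1 <- labf(beta_a, se_a)
  l2 <- labf(beta_b, se_b)
  lsum <- function(x) {
    mx <- max(x)
    mx + log(sum(exp(x - mx)))
  }
  # log of sum_{i != j} exp(l1_i + l2_j) = log(S1*S2 - sum_i exp(l1_i+l2_i))
  s1 <- lsum(l1)
  s2 <- lsum(l2)
  s12 <- lsum(l1 + l2)
  lh <- c(
    h0 = 0,
    h1 = log(p1) + s1,
    h2 = log(p2) + s2,
    h3 = log(p1) + log(p2) + s1 + s2 + log1p(-exp(s12 - s1 - s2)),
    h4 = log(p12) + s12
  )
  pp <- exp(lh - lsum(lh))
  names(pp) <- paste0("PP", 0:4)
  verdict <- coloc_verdict(pp)
  out <- list(pp = pp, verdict = verdict, n_variants = m)
  class(out) <- "coloc_result"
  out
}

#' Threshold rule turning coloc posteriors into a verdict
#' @param pp named numeric vector PP0..PP4.
#' @param threshold posterior probability cutoff (default 0.8).
#' @return `"colocalized"`, `"distinct"` or `"undetermined"`.
#' @export
coloc_verdict <- function(pp, threshold = 0.8) {
  if (pp["PP4"] > threshold) "colocalized"
  else if (pp["PP3"] > threshold) "distinct"
  else "undetermined"
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalization over", x$n_variants, "variants:\n")
  print(round(x$pp, 4))
  cat("verdict:", x$verdict, "\n")
  invisible(x)
}

#' Classify a variant's placental-weight vs birth-weight association
#'
#' Compares the 95% confidence intervals of a variant's effect on
#' placental weight and on birth weight (same s.d. scale, same effect
#' allele). Disjoint CIs mean the association is specific:
#' `"predominantly or only PW"` -- unless the BW effect runs in the
#' opposite direction with p < 0.05, in which case the label is
#' `"PW and BW opposite directions"`. Overlapping CIs give
#' `"PW and BW same direction"`. A missing BW estimate yields
#' `"no BW proxy"`.
#'
#' @param pw_beta,pw_se placental-weight effect and SE.
#' @param bw_beta,bw_se birth-weight effect and SE (NA allowed).
#' @param bw_p optional BW p-value; computed from the z ratio when NULL.
#' @return character label (vectorized over variants).
#' @export
classify_pw_bw <- function(pw_beta, pw_se, bw_beta, bw_se, bw_p = NULL) {
  if (is.null(bw_p))
    bw_p <- 2 * stats::pnorm(abs(bw_beta / bw_se), lower.tail = FALSE)
  zq <- stats::qnorm(0.975)
  lo_p <- pw_beta - zq * pw_se; hi_p <- pw_beta + zq * pw_se
  lo_b <- bw_beta - zq * bw_se; hi_b <- bw_beta + zq * bw_se
  disjoint <- hi_p < lo_b | hi_b < lo_p
  opposite <- pw_beta * bw_beta < 0 & bw_p < 0.05
  label <- ifelse(is.na(bw_beta) | is.na(bw_se), "no BW proxy",
           ifelse(!disjoint, "PW and BW same direction",
           ifelse(opposite, "PW and BW opposite directions",
                  "predominantly or only PW")))
  label
}
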