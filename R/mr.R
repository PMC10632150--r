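#' Two-sample Mendelian randomization estimators
#'
#' Estimates the causal effect of an exposure on an outcome from
#' per-instrument summary associations. Methods:
#' \describe{
#'   \item{ivw}{inverse-variance weighted: the slope of the outcome
#'     betas on the exposure betas through the origin with weights
#'     `1/se_out^2`; equals the weighted average of Wald ratios.}
#'   \item{egger}{adds a free intercept; a nonzero intercept signals
#'     directional pleiotropy and the slope is the pleiotropy-adjusted
#'     causal estimate. SEs use the weighted-regression formula with the
#'     residual standard deviation floored at 1 (multiplicative
#'     random-effects convention).}
#'   \item{weighted-median}{the weighted median of per-instrument Wald
#'     ratios (inverse-variance weights); consistent when at least half
#'     the weight comes from valid instruments. SE by parametric
#'     bootstrap.}
#'   \item{penalized-weighted-median}{downweights instruments with large
#'     contributions to heterogeneity (Cochran Q) before taking the
#'     weighted median.}
#' }
#'
#' @param beta_exp,se_exp per-SNP exposure associations, harmonized to
#'   the exposure-increasing allele.
#' @param beta_out,se_out per-SNP outcome associations on the same
#'   alleles.
#' @param method one of `"ivw"`, `"egger"`, `"weighted-median"`,
#'   `"penalized-weighted-median"`.
#' @param n_boot bootstrap replicates for median SEs (default 1000).
#' @param seed seed for the bootstrap.
#' @return object of class `mr_result`: list with `method`, `estimate`,
#'   `se`, `ci` (95%), `p`, `n_snps`, and for Egger `intercept` and
#'   `intercept_se`.
#' @export
mr_estimate <- function(beta_exp, se_exp, beta_out, se_out,
                        method = c("ivw", "egger", "weighted-median",
                                   "penalized-weighted-median"),
                        n_boot = 1000L, seed = 1L) {
  method <- match.arg(method)
  k <- length(beta_exp)
  stopifnot(length(se_exp) == k, length(beta_out) == k,
            length(se_out) == k, all(se_exp > 0), all(se_out > 0))
  if (k < 1) stop("at least one instrument required")
  if (method != "ivw" && k < 3)
    stop("at least 3 instruments required for ", method)

  # orient to the exposure-increasing allele
  flip <- sign(beta_exp)
  flip[flip == 0] <- 1
  bx <- beta_exp * flip
  by <- beta_out * flip

  res <- switch(method,
    "ivw" = mr_ivw(bx, by, se_out),
    "egger" = mr_egger(bx, by, se_out),
    "weighted-median" = mr_wmedian(bx, se_exp, by, se_out,
                                   penalized = FALSE, n_boot, seed),
    "penalized-weighted-median" = mr_wmedian(bx, se_exp, by, se_out,
                                             penalized = TRUE, n_boot, seed)
  )
  res$method <- method
  res$n_snps <- k
  res$ci <- res$estimate + c(-1, 1) * stats::qnorm(0.975) * res$se
  res$p <- 2 * stats::pnorm(abs(res$estimate / res$se), lower.tail = FALSE)
  class(res) <- "mr_result"
  res
}

mr_ivw <- function(bx, by, se_out) {
  w <- 1 / se_out^2
  est <- sum(w * bx * by) / sum(w * bx^2)
  se <- 1 / sqrt(sum(w * bx^2))
  list(estimate = est, se = se)
}

mr_egger <- function(bx, by, se_out) {
  w <- 1 / se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  infl <- max(1, sm$sigma)  # floor residual SD at 1
  co <- sm$coefficients
  list(estimate = co["bx", "Estimate"],
       se = co["bx", "Std. Error"] / sm$sigma * infl,
       intercept = co["(Intercept)", "Estimate"],
       intercept_se = co["(Intercept)", "Std. Error"] / sm$sigma * infl)
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  if (all(cw < 0.5)) return(x[length(x)])
  below <- max(which(cw < 0.5), 0)
  if (below == 0) return(x[1])
  # linear interpolation between bracketing order statistics
  x[below] + (x[below + 1] - x[below]) *
    (0.5 - cw[below]) / (cw[below + 1] - cw[below])
}

penalize_weights <- function(ratio, w, est) {
  q <- w * (ratio - est)^2
  pq <- stats::pchisq(q, df = 1, lower.tail = FALSE)
  w * pmin(1, 20 * pq)
}

mr_wmedian <- function(bx, se_exp, by, se_out, penalized, n_boot, seed) {
  ratio <- by / bx
  se_ratio <- se_out / abs(bx)   # first-order Wald-ratio SE
  w <- 1 / se_ratio^2
  point <- function(r, wt) {
    if (penalized) {
      ivw0 <- sum(wt * r) / sum(wt)
      wt <- penalize_weights(r, wt, ivw0)
    }
    weighted_median(r, wt)
  }
  est <- point(ratio, w)
  set.seed(seed)
  boots <- replicate(n_boot, {
    bx_b <- bx + se_exp * stats::rnorm(length(bx))
    by_b <- by + se_out * stats::rnorm(length(by))
    r_b <- by_b / bx_b
    w_b <- (abs(bx_b) / se_out)^2
    point(r_b, w_b)
  })
  list(estimate = est, se = stats::sd(boots))
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR (%s, %d SNPs): estimate %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$method, x$n_snps, x$estimate, x$se, x$ci[1], x$ci[2], x$p))
  if (!is.null(x$intercept))
    cat(sprintf("  Egger intercept %.4f (SE %.4f)\n",
                x$intercept, x$intercept_se))
  invisible(x)
}

#' Observed-to-liability scale conversion for binary-outcome effects
#'
#' Rescales an observed-scale effect on a binary trait with population
#' prevalence `K` to the latent liability scale using the standard
#' factor `K(1-K) / phi(Phi^-1(1-K))`, where `phi`/`Phi` are the
#' standard-normal density and distribution functions. The inverse
#' transform divides by the same factor, so analyses run on the
#' liability scale (e.g. partitioning of disease log-odds effects) can
#' be mapped back to log odds ratios.
#'
#' @param beta effect estimate(s) on the observed scale (e.g. log OR).
#' @param prevalence population prevalence `K` in (0, 1); e.g. 0.046 for
#'   preeclampsia.
#' @param inverse if `TRUE`, maps a liability-scale effect back to the
#'   observed scale.
#' @return rescaled effect(s).
#' @export
liability_adjust <- function(beta, prevalence, inverse = FALSE) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly inside (0, 1)")
  z <- stats::qnorm(1 - prevalence)
  factor <- prevalence * (1 - prevalence) / stats::dnorm(z)
  if (inverse) beta / factor else beta * factor
}

#' Convert an effect in phenotype s.d. units to grams
#'
#' @param beta effect(s) in s.d. units.
#' @param sd_g grams per phenotype s.d.; defaults to 132.5 g, the
#'   placental-weight conversion constant used throughout.
#' @return effect(s) in grams.
#' @export
sd_to_grams <- function(beta, sd_g = 132.5) {
  stopifnot(is.finite(sd_g), sd_g > 0)
  beta * sd_g
}

#' @rdname sd_to_grams
#' @export
grams_to_sd <- function(beta, sd_g = 132.5) beta / sd_g
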