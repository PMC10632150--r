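#' Weighted linear model: partition marginal GWAS effects into
#' conditional fetal, maternal and paternal components
#'
#' Marginal per-genome GWAS slopes (beta_c, beta_m, beta_f) mix the three
#' underlying conditional effects through the relatedness of the genomes.
#' With offspring-parent genotype correlation 1/2 the mixing matrix is
#' `A = [[1, 1/2, 1/2], [1/2, 1, 0], [1/2, 0, 1]]` and its inverse gives
#' the partitioned (conditional) effects:
#' \deqn{\eta_c = 2\beta_c - \beta_m - \beta_f}
#' \deqn{\eta_m = -\beta_c + 3/2\,\beta_m + 1/2\,\beta_f}
#' \deqn{\eta_f = -\beta_c + 1/2\,\beta_m + 3/2\,\beta_f}
#'
#' @param beta_c,beta_m,beta_f marginal child/mother/father GWAS effects
#'   (vectors of equal length), on a shared effect-allele orientation.
#' @return data.frame with columns `eta_c`, `eta_m`, `eta_f`.
#' @export
wlm_point_estimates <- function(beta_c, beta_m, beta_f) {
  if (any(is.na(beta_c)) || any(is.na(beta_m)) || any(is.na(beta_f)))
    stop("the weighted linear model requires all three marginal estimates")
  stopifnot(length(beta_c) == length(beta_m),
            length(beta_m) == length(beta_f))
  data.frame(
    eta_c = 2 * beta_c - beta_m - beta_f,
    eta_m = -beta_c + 1.5 * beta_m + 0.5 * beta_f,
    eta_f = -beta_c + 0.5 * beta_m + 1.5 * beta_f
  )
}

#' The WLM coefficient matrix (inverse of the genome mixing matrix)
#' @return 3x3 numeric matrix with rows (eta_c, eta_m, eta_f) and columns
#'   (beta_c, beta_m, beta_f).
#' @export
wlm_coef_matrix <- function() {
  matrix(c(2, -1, -1,
           -1, 1.5, 0.5,
           -1, 0.5, 1.5), 3, 3, byrow = TRUE,
         dimnames = list(c("eta_c", "eta_m", "eta_f"),
                         c("beta_c", "beta_m", "beta_f")))
}

#' Sample-overlap term between two GWAS
#'
#' When two GWAS share individuals their effect estimates are correlated;
#' for null variants the correlation is `t_ij = n_shared * rho /
#' sqrt(n_i * n_j)`, where rho is the phenotypic correlation of the two
#' analyses in the overlapping samples. The same quantity is estimable as
#' the intercept of a bivariate LD score regression, which may be
#' supplied verbatim instead.
#'
#' @param n_shared individuals in both analyses.
#' @param n_i,n_j analysis sample sizes.
#' @param rho correlation of the two phenotype residuals in the overlap.
#' @return the dimensionless overlap term in \[-1, 1\].
#' @export
estimate_overlap_term <- function(n_shared, n_i, n_j, rho) {
  if (n_shared < 0 || n_shared > min(n_i, n_j))
    stop("n_shared must satisfy 0 <= n_shared <= min(n_i, n_j)")
  if (abs(rho) > 1) stop("|rho| must be <= 1")
  n_shared * rho / sqrt(n_i * n_j)
}

#' Standard errors of the partitioned effects
#'
#' The partitioned effects are fixed linear combinations of the three
#' marginal estimates, so their variances follow from the delta method.
#' In the default `"full"` mode every pairwise covariance
#' `sigma_ij = t_ij * sigma_i * sigma_j` enters:
#' \deqn{Var(\eta_c) = 4\sigma_c^2 + \sigma_m^2 + \sigma_f^2
#'   - 4\sigma_{cm} - 4\sigma_{cf} + 2\sigma_{mf}}
#' \deqn{Var(\eta_m) = \sigma_c^2 + 9/4\,\sigma_m^2 + 1/4\,\sigma_f^2
#'   - 3\sigma_{cm} - \sigma_{cf} + 3/2\,\sigma_{mf}}
#' \deqn{Var(\eta_f) = \sigma_c^2 + 1/4\,\sigma_m^2 + 9/4\,\sigma_f^2
#'   - \sigma_{cm} - 3\sigma_{cf} + 3/2\,\sigma_{mf}}
#' A `"paper"` compatibility mode retains a single covariance term per
#' component (mother-father for the fetal component, child-father for the
#' maternal, child-mother for the paternal), matching a reduced published
#' form of the corrections.
#'
#' @param se_c,se_m,se_f marginal standard errors (vectors).
#' @param overlap named list or vector with `t_cm`, `t_cf`, `t_mf`
#'   overlap terms (see [estimate_overlap_term()]); defaults to zero
#'   (disjoint samples).
#' @param mode `"full"` (all three covariances) or `"paper"` (reduced).
#' @return data.frame with columns `se_eta_c`, `se_eta_m`, `se_eta_f`.
#' @export
wlm_standard_errors <- function(se_c, se_m, se_f,
                                overlap = c(t_cm = 0, t_cf = 0, t_mf = 0),
                                mode = c("full", "paper")) {
  mode <- match.arg(mode)
  overlap <- as.list(overlap)
  t_cm <- overlap$t_cm %||% 0
  t_cf <- overlap$t_cf %||% 0
  t_mf <- overlap$t_mf %||% 0
  if (any(abs(c(t_cm, t_cf, t_mf)) > 1))
    stop("overlap terms must have magnitude <= 1")
  s_cm <- t_cm * se_c * se_m
  s_cf <- t_cf * se_c * se_f
  s_mf <- t_mf * se_m * se_f
  if (mode == "full") {
    v_c <- 4 * se_c^2 + se_m^2 + se_f^2 - 4 * s_cm - 4 * s_cf + 2 * s_mf
    v_m <- se_c^2 + 2.25 * se_m^2 + 0.25 * se_f^2 -
      3 * s_cm - s_cf + 1.5 * s_mf
    v_f <- se_c^2 + 0.25 * se_m^2 + 2.25 * se_f^2 -
      s_cm - 3 * s_cf + 1.5 * s_mf
  } else {
    v_c <- 4 * se_c^2 + se_m^2 + se_f^2 + 2 * s_mf
    v_m <- se_c^2 + 2.25 * se_m^2 + 0.25 * se_f^2 - s_cf
    v_f <- se_c^2 + 0.25 * se_m^2 + 2.25 * se_f^2 - s_cm
  }
  bad <- which(v_c <= 0 | v_m <= 0 | v_f <= 0)
  if (length(bad))
    stop("non-positive partitioned variance at index ",
         paste(bad, collapse = ", "),
         "; check overlap terms t_cm=", t_cm, " t_cf=", t_cf,
         " t_mf=", t_mf)
  data.frame(se_eta_c = sqrt(v_c), se_eta_m = sqrt(v_m),
             se_eta_f = sqrt(v_f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full WLM on a triple of harmonized GWAS records
#'
#' Combines [wlm_point_estimates()], [wlm_standard_errors()] and a
#' two-sided z test per component, and classifies the mode of
#' association with [classify_mode()].
#'
#' @param triple data.frame with columns `beta_c`, `se_c`, `beta_m`,
#'   `se_m`, `beta_f`, `se_f` (one row per variant), plus optional id
#'   columns carried through.
#' @param overlap overlap terms as in [wlm_standard_errors()].
#' @param se_mode `"full"` or `"paper"`.
#' @param n_tests Bonferroni denominator for classification (default 37).
#' @return data.frame adding eta/se/z/p per component and `mode`.
#' @export
wlm_partition <- function(triple, overlap = c(t_cm = 0, t_cf = 0, t_mf = 0),
                          se_mode = "full", n_tests = 37) {
  est <- wlm_point_estimates(triple$beta_c, triple$beta_m, triple$beta_f)
  se <- wlm_standard_errors(triple$se_c, triple$se_m, triple$se_f,
                            overlap = overlap, mode = se_mode)
  out <- cbind(triple, est, se)
  for (comp in c("c", "m", "f")) {
    z <- out[[paste0("eta_", comp)]] / out[[paste0("se_eta_", comp)]]
    out[[paste0("z_", comp)]] <- z
    out[[paste0("p_", comp)]] <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  }
  out$mode <- classify_mode(out$eta_c, out$se_eta_c, out$p_c,
                            out$eta_m, out$se_eta_m, out$p_m,
                            n_tests = n_tests)
  out
}

#' Classify mode of association from partitioned estimates
#'
#' A variant is `fetal-only` when the fetal p-value clears the Bonferroni
#' threshold `0.05/n_tests` and the fetal and maternal 95% CIs are
#' disjoint; `maternal-only` is symmetric. When both p-values clear the
#' threshold the variant is `fetal-and-maternal-same` or
#' `fetal-and-maternal-opposite` depending on the sign product of the two
#' estimates. Anything else is `unclassified`. CI overlap uses closed
#' intervals: touching endpoints count as overlapping.
#'
#' @param eta_c,se_c,p_c fetal estimate, SE and p.
#' @param eta_m,se_m,p_m maternal estimate, SE and p.
#' @param n_tests Bonferroni denominator (default 37, the number of
#'   signals classified in the motivating analysis).
#' @return character vector of labels.
#' @export
classify_mode <- function(eta_c, se_c, p_c, eta_m, se_m, p_m, n_tests = 37) {
  stopifnot(n_tests >= 1)
  thr <- 0.05 / n_tests
  zq <- stats::qnorm(0.975)
  lo_c <- eta_c - zq * se_c; hi_c <- eta_c + zq * se_c
  lo_m <- eta_m - zq * se_m; hi_m <- eta_m + zq * se_m
  disjoint <- hi_c < lo_m | hi_m < lo_c  # closed intervals: strict
  sig_c <- p_c < thr
  sig_m <- p_m < thr
  label <- rep("unclassified", length(eta_c))
  label[sig_c & sig_m & eta_c * eta_m > 0] <- "fetal-and-maternal-same"
  label[sig_c & sig_m & eta_c * eta_m < 0] <- "fetal-and-maternal-opposite"
  only_c <- sig_c & !sig_m & disjoint
  only_m <- sig_m & !sig_c & disjoint
  label[only_c] <- "fetal-only"
  label[only_m] <- "maternal-only"
  label
}
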