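#' Fixed biometric path matrix linking latent to observed genetic values
#'
#' Rows index the observed per-genome GWAS (child, mother, father) and
#' columns the latent direct genetic components (fetal, maternal,
#' paternal). The off-diagonal 1/2 entries encode the relatedness of the
#' genomes under random mating: a child's GWAS picks up half of each
#' parental component, and each parent's GWAS picks up half of the fetal
#' component; mother and father are unrelated.
#'
#' @return the 3x3 matrix `A = [[1, 1/2, 1/2], [1/2, 1, 0], [1/2, 0, 1]]`.
#' @export
build_path_matrix <- function() {
  matrix(c(1, 0.5, 0.5,
           0.5, 1, 0,
           0.5, 0, 1), 3, 3, byrow = TRUE,
         dimnames = list(c("child", "mother", "father"),
                         c("fetal", "maternal", "paternal")))
}

# vech index for 3x3 symmetric matrices (diagonal first convention not
# used; standard column-major lower triangle)
.vech_idx <- cbind(row = c(1, 2, 3, 2, 3, 3), col = c(1, 1, 1, 2, 2, 3))

.vech <- function(S) S[lower.tri(S, diag = TRUE)]

.unvech <- function(v) {
  S <- matrix(0, 3, 3)
  S[lower.tri(S, diag = TRUE)] <- v
  S[upper.tri(S)] <- t(S)[upper.tri(S)]
  S
}

# 6x6 matrix of the linear map vech(S_obs) -> vech(Ainv S_obs Ainv')
.latent_map <- function() {
  Ainv <- solve(build_path_matrix())
  L <- matrix(0, 6, 6)
  for (k in 1:6) {
    e <- numeric(6); e[k] <- 1
    L[, k] <- .vech(Ainv %*% .unvech(e) %*% t(Ainv))
  }
  L
}

#' Solve the latent genetic covariance model in closed form
#'
#' Given the 3x3 genetic covariance matrix of the child, maternal and
#' paternal GWAS (as estimated upstream by LD score regression), returns
#' the latent fetal/maternal/paternal SNP heritabilities and their
#' pairwise covariances. Because every path coefficient is fixed and the
#' model has six free parameters for six observed moments, the model is
#' saturated and the solution is the exact linear inversion
#' `S_latent = A^-1 S_obs A^-T` -- no iterative fitting is needed.
#' When a 6x6 sampling covariance of the unique observed elements is
#' supplied, standard errors are propagated through the same linear map.
#'
#' @param observed 3x3 symmetric genetic covariance matrix, ordered
#'   (child GWAS, maternal GWAS, paternal GWAS).
#' @param sampling_cov optional 6x6 sampling covariance of
#'   `vech(observed)` (order: 11, 21, 31, 22, 32, 33).
#' @param method `"closed-form"` (default) or `"dwls"`; the diagonally
#'   weighted least-squares fit minimizes the weighted moment distance
#'   numerically and coincides with the closed form because the model is
#'   saturated (provided as a numerical cross-check mode).
#' @param psd_project if `TRUE`, a latent matrix with negative
#'   eigenvalues is projected to the nearest positive semidefinite
#'   matrix (off by default; the raw solution is reported and flagged).
#' @return object of class `latent_genetic_params`: list with `h2`
#'   (named fetal/maternal/paternal variances), `cov` (named fm/fp/mp
#'   covariances), `latent` (the 3x3 matrix), `se` (named, when
#'   sampling_cov given), `psd` flag.
#' @export
solve_latent <- function(observed, sampling_cov = NULL,
                         method = c("closed-form", "dwls"),
                         psd_project = FALSE) {
  method <- match.arg(method)
  observed <- as.matrix(observed)
  if (!isTRUE(all.equal(observed, t(observed), tolerance = 1e-8)))
    stop("observed genetic covariance matrix must be symmetric")
  A <- build_path_matrix()
  Ainv <- solve(A)
  if (method == "closed-form") {
    latent <- Ainv %*% observed %*% t(Ainv)
  } else {
    W <- if (is.null(sampling_cov)) diag(6) else diag(1 / diag(sampling_cov))
    obj <- function(v) {
      d <- .vech(build_path_matrix() %*% .unvech(v) %*%
                   t(build_path_matrix())) - .vech(observed)
      sum(d * (W %*% d))
    }
    start <- .vech(Ainv %*% observed %*% t(Ainv))
    opt <- stats::optim(start, obj, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 1000))
    latent <- .unvech(opt$par)
  }
  latent <- (latent + t(latent)) / 2
  ev <- eigen(latent, symmetric = TRUE, only.values = TRUE)$values
  psd <- min(ev) > -1e-10
  if (!psd) {
    warning("latent genetic covariance matrix is not positive ",
            "semidefinite (min eigenvalue ", signif(min(ev), 3),
            "); possible nonadditive effects or sampling noise")
    if (psd_project) {
      ed <- eigen(latent, symmetric = TRUE)
      latent <- ed$vectors %*% diag(pmax(ed$values, 0)) %*% t(ed$vectors)
    }
  }
  dimnames(latent) <- list(c("fetal", "maternal", "paternal"),
                           c("fetal", "maternal", "paternal"))
  se <- NULL
  if (!is.null(sampling_cov)) {
    L <- .latent_map()
    V <- L %*% as.matrix(sampling_cov) %*% t(L)
    se_v <- sqrt(pmax(diag(V), 0))
    se <- c(h2_fetal = se_v[1], cov_fm = se_v[2], cov_fp = se_v[3],
            h2_maternal = se_v[4], cov_mp = se_v[5], h2_paternal = se_v[6])
  }
  out <- list(
    h2 = c(fetal = latent[1, 1], maternal = latent[2, 2],
           paternal = latent[3, 3]),
    cov = c(fm = latent[1, 2], fp = latent[1, 3], mp = latent[2, 3]),
    latent = latent, se = se, psd = psd
  )
  class(out) <- "latent_genetic_params"
  out
}

#' Forward map: observed genetic covariance implied by latent parameters
#'
#' @param latent 3x3 latent covariance matrix, or a
#'   `latent_genetic_params` object.
#' @return 3x3 observed covariance `A S_latent A'` for the (child,
#'   mother, father) GWAS.
#' @export
predict_observed <- function(latent) {
  if (inherits(latent, "latent_genetic_params")) latent <- latent$latent
  A <- build_path_matrix()
  S <- A %*% as.matrix(latent) %*% t(A)
  dimnames(S) <- list(c("child", "mother", "father"),
                      c("child", "mother", "father"))
  S
}

#' @export
print.latent_genetic_params <- function(x, ...) {
  cat("Latent genetic decomposition (fixed-path biometric model)\n")
  cat(sprintf("  h2 fetal    = %.4f\n", x$h2["fetal"]))
  cat(sprintf("  h2 maternal = %.4f\n", x$h2["maternal"]))
  cat(sprintf("  h2 paternal = %.4f\n", x$h2["paternal"]))
  cat(sprintf("  cov(f,m) = %.4f  cov(f,p) = %.4f  cov(m,p) = %.4f\n",
              x$cov["fm"], x$cov["fp"], x$cov["mp"]))
  if (!x$psd) cat("  [warning: latent matrix not PSD]\n")
  invisible(x)
}
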