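#' Resolve transmitted and non-transmitted alleles from phased trios
#'
#' Reads the maternally and paternally transmitted allele counts (mt, pt)
#' directly from the child's origin-labelled haplotypes and derives the
#' non-transmitted counts by subtraction from the parental dosages
#' (mnt = mother - mt, pnt = father - pt). A trio is flagged as a
#' Mendelian error at a variant when a labelled child allele cannot have
#' come from the corresponding parent (e.g. the maternal-labelled allele
#' is 1 but the mother carries no copy); such trios are excluded from
#' transmission fits at that variant.
#'
#' @param trios a `trio_genotypes` object.
#' @return list of matrices (trios x variants): `mt`, `mnt`, `pt`, `pnt`,
#'   logical `mendelian_error`, plus the variant metadata.
#' @export
resolve_transmission <- function(trios) {
  mt <- trios$hap_maternal
  pt <- trios$hap_paternal
  mo <- trios$mother
  fa <- trios$father
  err_m <- (mt == 1L & mo == 0L) | (mt == 0L & mo == 2L)
  err_p <- (pt == 1L & fa == 0L) | (pt == 0L & fa == 2L)
  mend <- err_m | err_p
  mnt <- mo - mt
  pnt <- fa - pt
  # out-of-range values only occur at error trios; keep them flagged
  list(mt = mt, mnt = mnt, pt = pt, pnt = pnt,
       mendelian_error = mend, variants = trios$variants)
}

#' Per-variant Mendelian-error share among informative trios
#'
#' A trio is informative for phase checking at a variant when at least
#' one parent is homozygous there and the child is heterozygous: a
#' homozygous child carries two identical alleles, so an origin-label
#' flip there is both harmless and undetectable, and a trio whose
#' parents are both heterozygous is compatible with any labelling.
#' Only over detectable trios does a systematically mis-phased variant
#' show an error share approaching one (and above the 50% swap
#' threshold); counting undetectable trios would dilute the share below
#' one half even under complete label flipping. The share is the
#' fraction of informative trios flagged as Mendelian errors.
#'
#' @param decomp output of [resolve_transmission()].
#' @param trios the `trio_genotypes` the decomposition came from.
#' @return numeric vector, one share per variant; `NA` with a warning
#'   where no trio is informative.
#' @export
mendelian_error_share <- function(decomp, trios) {
  informative <- ((trios$mother != 1L) | (trios$father != 1L)) &
    (decomp$mt != decomp$pt)
  n_inf <- colSums(informative)
  n_err <- colSums(decomp$mendelian_error & informative)
  share <- ifelse(n_inf > 0, n_err / n_inf, NA_real_)
  if (any(n_inf == 0))
    warning("no informative trios (both parents heterozygous) at ",
            sum(n_inf == 0), " variant(s); share undefined")
  share
}

#' Swap child origin labels at variants with majority Mendelian errors
#'
#' A Mendelian-error share strictly above 50% at a variant indicates the
#' child's haplotype origin labels are systematically flipped there; the
#' maternal/paternal labels are exchanged (and the non-transmitted
#' alleles recomputed). A share of exactly 0.5 or below leaves the
#' variant unchanged. The rule is idempotent: after a swap the
#' re-estimated share falls below 0.5, so a second application is a
#' no-op.
#'
#' @param trios a `trio_genotypes` object.
#' @param share per-variant error share from [mendelian_error_share()].
#' @return list with the (possibly label-swapped) `trios`, the refreshed
#'   `decomp`, and logical `swapped` per variant.
#' @export
swap_if_flipped <- function(trios, share) {
  swapped <- !is.na(share) & share > 0.5
  if (any(swapped)) {
    tmp <- trios$hap_maternal[, swapped, drop = FALSE]
    trios$hap_maternal[, swapped] <- trios$hap_paternal[, swapped]
    trios$hap_paternal[, swapped] <- tmp
  }
  list(trios = trios, decomp = resolve_transmission(trios),
       swapped = swapped)
}

# shared OLS helper: fit y ~ X (X includes intercept), return coef table
ols_fit <- function(X, y, label) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[-qrx$pivot[seq_len(qrx$rank)]]
    stop("collinear design in ", label, "; offending columns: ",
         paste(bad, collapse = ", "),
         ". A larger or more variable sample may be needed.")
  }
  fit <- stats::lm.fit(X, y)
  df <- length(y) - ncol(X)
  s2 <- sum(fit$residuals^2) / df
  R <- qr.R(qrx)
  XtXinv <- chol2inv(R)
  ord <- qrx$pivot
  se <- numeric(ncol(X))
  se[ord] <- sqrt(s2 * diag(XtXinv))
  est <- fit$coefficients
  tval <- est / se
  data.frame(term = colnames(X), estimate = est, se = se,
             p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
             row.names = NULL, stringsAsFactors = FALSE)
}

build_covm <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(numeric(0), n, 0))
  as.matrix(covariates)
}

#' Trio conditional regression: phenotype on all three genomes at once
#'
#' Fits `phenotype ~ child + mother + father (+ covariates)` by OLS at
#' one variant. The three slopes are the conditional fetal, maternal and
#' paternal effects, estimated jointly from genotyped trios -- the
#' individual-level counterpart of the summary-level WLM.
#'
#' @param phenotype standardized phenotype vector.
#' @param child,mother,father dosage vectors for one variant.
#' @param covariates optional covariate matrix/data.frame.
#' @return object of class `poe_fit`: coefficient table plus `n` and
#'   `design` label.
#' @export
fit_trio_conditional <- function(phenotype, child, mother, father,
                                 covariates = NULL) {
  n <- length(phenotype)
  X <- cbind(Intercept = rep(1, n), child = child, mother = mother,
             father = father, build_covm(covariates, n))
  out <- list(coefficients = ols_fit(X, phenotype, "trio conditional model"),
              n = n, design = "child+mother+father")
  class(out) <- "poe_fit"
  out
}

#' Transmission regression: phenotype on the four allele classes
#'
#' Fits `phenotype ~ mnt + mt + pt + pnt (+ covariates)` on resolved,
#' Mendelian-error-free trios. Under a purely fetal additive effect the
#' mt and pt coefficients coincide; a maternal indirect effect loads on
#' mt and mnt equally; a parent-of-origin effect separates mt from pt.
#'
#' @param phenotype standardized phenotype vector.
#' @param decomp output of [resolve_transmission()].
#' @param variant column index of the variant to fit.
#' @param covariates optional covariates.
#' @return a `poe_fit`.
#' @export
fit_transmission_model <- function(phenotype, decomp, variant = 1L,
                                   covariates = NULL) {
  keep <- !decomp$mendelian_error[, variant]
  y <- phenotype[keep]
  n <- length(y)
  covm <- build_covm(covariates, length(phenotype))
  X <- cbind(Intercept = rep(1, n),
             mnt = decomp$mnt[keep, variant],
             mt = decomp$mt[keep, variant],
             pt = decomp$pt[keep, variant],
             pnt = decomp$pnt[keep, variant],
             covm[keep, , drop = FALSE])
  out <- list(coefficients = ols_fit(X, y, "transmission model"),
              n = n, design = "mnt+mt+pt+pnt")
  class(out) <- "poe_fit"
  out
}

#' Parent-of-origin test: maternal-transmitted allele net of additive
#' effects
#'
#' Fits `phenotype ~ mt + child + mother + father (+ covariates)`. The mt
#' coefficient measures the extra effect of the maternally transmitted
#' allele beyond what the three additive genome dosages explain, i.e. a
#' parent-of-origin effect; its z test gives the POE p-value.
#'
#' @param phenotype standardized phenotype vector.
#' @param decomp output of [resolve_transmission()].
#' @param trios the corresponding `trio_genotypes`.
#' @param variant column index of the variant.
#' @param covariates optional covariates.
#' @return a `poe_fit`.
#' @export
fit_poe_conditional <- function(phenotype, decomp, trios, variant = 1L,
                                covariates = NULL) {
  keep <- !decomp$mendelian_error[, variant]
  y <- phenotype[keep]
  n <- length(y)
  covm <- build_covm(covariates, length(phenotype))
  gc <- child_dosage(trios)
  X <- cbind(Intercept = rep(1, n),
             mt = decomp$mt[keep, variant],
             child = gc[keep, variant],
             mother = trios$mother[keep, variant],
             father = trios$father[keep, variant],
             covm[keep, , drop = FALSE])
  out <- list(coefficients = ols_fit(X, y, "parent-of-origin model"),
              n = n, design = "mt+child+mother+father")
  class(out) <- "poe_fit"
  out
}

#' @export
print.poe_fit <- function(x, ...) {
  cat("triopart fit (", x$design, "), n = ", x$n, "\n", sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Extract one coefficient from a `poe_fit`
#' @param fit a `poe_fit`.
#' @param term coefficient name (e.g. `"mt"`, `"child"`).
#' @return named numeric vector with estimate, se, p.
#' @export
coef_of <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) stop("no term '", term, "' in fit")
  c(estimate = fit$coefficients$estimate[i],
    se = fit$coefficients$se[i],
    p = fit$coefficients$p[i])
}
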