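#' Rank-normalize an expression matrix across contexts, per gene
#'
#' For each gene, the expression values across tissues or cell types are
#' replaced by their ranks (midranks for ties) scaled by the number of
#' contexts, so every gene's profile lies in (0, 1] with 1 marking its
#' top context. This removes between-gene scale differences so that
#' set-vs-background comparisons within a context are comparisons of
#' relative specificity, not absolute abundance.
#'
#' @param mat numeric matrix, genes in rows, contexts (tissues or cell
#'   types) in columns; nonnegative, at least 2 columns.
#' @return matrix of the same shape with normalized ranks; genes whose
#'   values are all equal get the common midrank and are reported in the
#'   `"flat_genes"` attribute.
#' @export
rank_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 contexts")
  if (any(mat < 0)) stop("expression values must be nonnegative")
  ranks <- t(apply(mat, 1, function(x) rank(x, ties.method = "average")))
  out <- ranks / ncol(mat)
  dimnames(out) <- dimnames(mat)
  flat <- which(apply(mat, 1, function(x) length(unique(x)) == 1))
  attr(out, "flat_genes") <- names(flat) %||% integer(0)
  out
}

#' Expression enrichment of a gene set in one context
#'
#' Wilcoxon rank-sum test comparing the normalized ranks of the test
#' genes against all remaining genes in the chosen context. The test is
#' two-sided by default with the direction of enrichment reported
#' (`"higher"` when the set's median normalized rank exceeds the
#' background's); a one-sided p for the reported direction is p/2 when
#' the direction matches the hypothesis.
#'
#' @param normalized matrix from [rank_normalize()].
#' @param gene_set character vector of row names; must be a nonempty
#'   strict subset of the matrix rows.
#' @param context column name or index.
#' @param alternative passed to [stats::wilcox.test()]; default
#'   `"two.sided"`.
#' @return list with `p`, `direction`, `statistic`, `n_set`, `n_background`.
#' @export
enrichment_test <- function(normalized, gene_set, context,
                            alternative = "two.sided") {
  if (length(gene_set) == 0) stop("gene set is empty")
  miss <- setdiff(gene_set, rownames(normalized))
  if (length(miss))
    stop("gene set members not in matrix: ", paste(miss, collapse = ", "))
  if (length(unique(gene_set)) >= nrow(normalized))
    stop("gene set must be a strict subset of the matrix rows")
  in_set <- rownames(normalized) %in% gene_set
  x <- normalized[in_set, context]
  y <- normalized[!in_set, context]
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative)
  )
  list(p = wt$p.value,
       direction = if (stats::median(x) >= stats::median(y)) "higher"
                   else "lower",
       statistic = unname(wt$statistic),
       n_set = length(x), n_background = length(y))
}

#' Bonferroni-corrected significance threshold
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of tests (e.g. 61 tissues or 32 cell types).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(m >= 1)
  alpha / m
}
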