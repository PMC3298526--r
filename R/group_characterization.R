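#' Per-group alteration frequency of one gene
#'
#' Percentage of patients in each survival group in which the gene carries
#' the requested alteration.
#'
#' @param calls an `alteration_calls` object.
#' @param groups named integer vector of group labels (1/2), names =
#'   sample ids (e.g. from [two_means_1d()] on a pathway's activity row).
#' @param gene gene identifier.
#' @param direction `"deletion"` or `"amplification"` for CNV calls;
#'   `"methylated"` for methylation calls.
#' @return named numeric vector `c(group1 = , group2 = )`, percents in
#'   \[0, 100\].
#' @export
alteration_frequency <- function(calls, groups, gene,
                                 direction = c("deletion", "amplification",
                                               "methylated")) {
  direction <- match.arg(direction)
  mat <- switch(direction,
                deletion = calls$deleted,
                amplification = calls$amplified,
                methylated = calls$methylated)
  if (is.null(mat))
    stop("direction '", direction, "' not available for ", calls$kind,
         " calls")
  if (!gene %in% rownames(mat)) stop("gene absent from calls: ", gene)
  common <- intersect(names(groups), colnames(mat))
  if (length(common) == 0L) stop("no overlap between groups and calls")
  g <- groups[common]
  v <- mat[gene, common]
  vapply(c(group1 = 1L, group2 = 2L),
         function(k) 100 * sum(v[g == k]) / sum(g == k), 1)
}

#' Correlation between two data layers for one gene within a group
#'
#' Pearson (default) or Spearman correlation across the group's samples
#' between the gene's values in two layers (e.g. CNV vs expression,
#' methylation vs expression, methylation vs CNV), with the two-sided
#' p-value of [stats::cor.test()].
#'
#' @param layer_a,layer_b numeric matrices (genes x samples).
#' @param gene gene identifier present in both layers.
#' @param group_samples sample ids of the group (>= 5 required).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `r`, `p_value`, `n`; `r` is `NA` with
#'   `p_value = NA` when either vector has zero variance.
#' @export
layer_correlation <- function(layer_a, layer_b, gene, group_samples,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!gene %in% rownames(layer_a) || !gene %in% rownames(layer_b))
    stop("gene absent from a layer: ", gene)
  common <- intersect(intersect(colnames(layer_a), colnames(layer_b)),
                      group_samples)
  if (length(common) < 5L) stop("need at least 5 samples in the group")
  a <- layer_a[gene, common]
  b <- layer_b[gene, common]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = length(common)))
  ct <- stats::cor.test(a, b, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(common))
}

#' Per-group co-expression of a gene pair
#'
#' Correlation between two genes' expression within each survival group,
#' with a "strong correlation" flag (`r >= r_threshold` and
#' `p < alpha`) used for presence/absence contrasts across groups and
#' datasets (the oncogene co-expression pattern seen in better-prognosis
#' groups).
#'
#' @param m expression matrix.
#' @param gene_a,gene_b gene identifiers.
#' @param groups named group labels (1/2) as in [alteration_frequency()].
#' @param method `"pearson"` or `"spearman"`.
#' @param r_threshold,alpha thresholds for the `strong` flag.
#' @return a `data.frame` with one row per group: `group`, `r`,
#'   `p_value`, `n`, `strong`.
#' @export
gene_pair_correlation <- function(m, gene_a, gene_b, groups,
                                  method = c("pearson", "spearman"),
                                  r_threshold = 0.3, alpha = 0.05) {
  method <- match.arg(method)
  if (!gene_a %in% rownames(m) || !gene_b %in% rownames(m))
    stop("gene absent from expression matrix")
  common <- intersect(names(groups), colnames(m))
  rows <- lapply(c(1L, 2L), function(k) {
    s <- common[groups[common] == k]
    if (length(s) < 5L)
      return(data.frame(group = k, r = NA_real_, p_value = NA_real_,
                        n = length(s), strong = NA))
    a <- m[gene_a, s]; b <- m[gene_b, s]
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      return(data.frame(group = k, r = NA_real_, p_value = NA_real_,
                        n = length(s), strong = NA))
    ct <- stats::cor.test(a, b, method = method, exact = FALSE)
    data.frame(group = k, r = unname(ct$estimate), p_value = ct$p.value,
               n = length(s),
               strong = unname(ct$estimate) >= r_threshold &
                 ct$p.value < alpha)
  })
  do.call(rbind, rows)
}

#' Characterize the survival groups of one pathway
#'
#' For a pathway and a two-group stratification of samples: per-gene
#' deletion and amplification frequencies per group, and the CNV-expression
#' correlation per gene and group.
#'
#' @param pathway_id pathway to characterize.
#' @param ps a `pathway_set`.
#' @param expression expression matrix.
#' @param cnv_calls `alteration_calls` from [call_cnv()].
#' @param cnv CNV log-ratio matrix (for the correlation layer).
#' @param groups named group labels (1/2).
#' @return a `data.frame` with one row per (gene, group): frequencies in
#'   percent and CNV-expression correlation.
#' @export
characterize_pathway <- function(pathway_id, ps, expression, cnv_calls, cnv,
                                 groups) {
  genes <- intersect(pathway_genes(ps, pathway_id), rownames(cnv_calls$altered))
  rows <- lapply(genes, function(g) {
    del <- alteration_frequency(cnv_calls, groups, g, "deletion")
    amp <- alteration_frequency(cnv_calls, groups, g, "amplification")
    do.call(rbind, lapply(c(1L, 2L), function(k) {
      s <- names(groups)[groups == k]
      corr <- tryCatch(layer_correlation(cnv, expression, g, s),
                       error = function(e) list(r = NA_real_,
                                                p_value = NA_real_))
      data.frame(pathway_id = pathway_id, gene = g, group = k,
                 deletion_pct = unname(del[k]), amplification_pct =
                   unname(amp[k]),
                 cnv_expr_r = corr$r, cnv_expr_p = corr$p_value,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
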