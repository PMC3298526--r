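#' Call copy-number alterations from log2 ratios
#'
#' A gene is called altered in a patient when its log2 ratio exceeds
#' `amp_threshold` (amplification) or falls below `del_threshold`
#' (deletion); both inequalities are strict, so a value exactly at a
#' threshold is not altered.
#'
#' @param source numeric matrix of CNV log2 ratios (genes x patients), as
#'   returned by `read_matrix(kind = "cnv")`.
#' @param amp_threshold amplification threshold (default +0.3).
#' @param del_threshold deletion threshold (default -0.3).
#' @return an object of class `alteration_calls`: list with binary
#'   matrices `altered`, `amplified`, `deleted`, the `kind`, and the
#'   thresholds used.
#' @export
call_cnv <- function(source, amp_threshold = 0.3, del_threshold = -0.3) {
  if (amp_threshold <= del_threshold)
    stop("config error: amp_threshold must exceed del_threshold")
  amp <- (source > amp_threshold) * 1L
  del <- (source < del_threshold) * 1L
  structure(list(kind = "cnv", altered = pmax(amp, del) * 1L,
                 amplified = amp, deleted = del,
                 thresholds = c(amp = amp_threshold, del = del_threshold)),
            class = "alteration_calls")
}

#' Call methylation status from beta values
#'
#' Betas strictly above `threshold` are tagged methylated (altered); a
#' value exactly at the threshold is unmethylated.
#'
#' @param source numeric matrix of beta values in \[0, 1\].
#' @param threshold methylation cut (default 0.5).
#' @return an `alteration_calls` object (the `methylated` matrix equals
#'   `altered`).
#' @export
call_methylation <- function(source, threshold = 0.5) {
  if (any(source < 0 | source > 1))
    stop("range error: beta values outside [0,1]")
  meth <- (source > threshold) * 1L
  structure(list(kind = "methylation", altered = meth, methylated = meth,
                 thresholds = c(beta = threshold)),
            class = "alteration_calls")
}

#' Per-patient hypergeometric pathway-alteration p-value
#'
#' With `M` genes tested of which `K` are altered in the patient, and a
#' pathway of `N` genes of which `x` are altered, the reported value is the
#' exclusive upper tail
#' \deqn{p = 1 - \sum_{i=0}^{x} \binom{K}{i}\binom{M-K}{N-i} / \binom{M}{N}
#'  = P(X > x),}
#' computed in log space (so M in the tens of thousands is safe) and
#' clamped to \[0, 1\]. Under this convention a patient with `K = 0` or
#' with `x` at its maximum gets p = 0 exactly. `inclusive = TRUE` computes
#' the conventional inclusive tail \eqn{P(X \ge x)} instead.
#'
#' @param x number of altered genes of the pathway in this patient.
#' @param M total number of genes tested.
#' @param K number of altered genes in this patient.
#' @param N number of genes in the pathway.
#' @param inclusive use the inclusive tail \eqn{P(X \ge x)}.
#' @return p-value in \[0, 1\].
#' @export
patient_pathway_p <- function(x, M, K, N, inclusive = FALSE) {
  if (K > M || N > M) stop("domain error: K and N must not exceed M")
  if (x > min(K, N) || x < 0) stop("domain error: x outside [0, min(K, N)]")
  q <- if (inclusive) x - 1 else x
  p <- stats::phyper(q, m = K, n = M - K, k = N, lower.tail = FALSE)
  min(max(p, 0), 1)
}

#' Fisher's omnibus combination of independent p-values
#'
#' Statistic \eqn{-2 \sum_j \ln p_j}, compared against the chi-square
#' distribution with 2n degrees of freedom. Zero p-values are floored at
#' 1e-300 with a warning (the exclusive hypergeometric tail produces exact
#' zeros).
#'
#' @param p_values vector of p-values in \[0, 1\].
#' @return list with `statistic`, `df`, and `combined_p` (in (0, 1\]).
#' @export
fisher_omnibus <- function(p_values) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0,1]")
  if (any(p_values == 0)) {
    warning(sum(p_values == 0), " zero p-value(s) floored at 1e-300")
    p_values[p_values == 0] <- 1e-300
  }
  stat <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  # the chi-square tail underflows for extreme statistics; keep p in (0, 1]
  cp <- max(stats::pchisq(stat, df = df, lower.tail = FALSE),
            .Machine$double.xmin)
  list(statistic = stat, df = df, combined_p = cp)
}

#' Scan all pathways for genomic targeting
#'
#' For each pathway: a per-patient hypergeometric p-value
#' ([patient_pathway_p()]) over the universe of `M` tested genes (genes
#' present in both the call matrix and at least one pathway), combined
#' across patients with [fisher_omnibus()]. A pathway is flagged targeted
#' when its combined p falls below the Bonferroni per-test level
#' `alpha / (number of pathways tested)`.
#'
#' @param calls an `alteration_calls` object.
#' @param ps a `pathway_set`.
#' @param alpha family-wise level (default 0.05).
#' @param inclusive tail convention passed to [patient_pathway_p()]. The
#'   scan defaults to the inclusive tail \eqn{P(X \ge x)}: for a discrete
#'   count the exclusive tail is anti-conservative (its null exceedance
#'   probability is \eqn{P(X \ge x)}, not \eqn{P(X > x)}), which the
#'   omnibus combination across patients amplifies into certain family-wise
#'   false flagging; the inclusive tail is the valid per-patient p-value.
#'   Set `FALSE` for the literal exclusive form.
#' @return a `data.frame` of class `targeting_result`: `pathway_id`,
#'   `n_genes` (pathway genes in the universe), `fisher_stat`, `df`,
#'   `combined_p`, `bonferroni_alpha`, `targeted`; per-patient p-values in
#'   the `"patient_p"` attribute; the gene universe size in `"M"`.
#' @export
targeting_scan <- function(calls, ps, alpha = 0.05, inclusive = TRUE) {
  universe_all <- unique(unlist(lapply(pathway_ids(ps),
                                       function(pid) pathway_genes(ps, pid))))
  universe <- intersect(rownames(calls$altered), universe_all)
  M <- length(universe)
  if (M == 0L) stop("no gene shared between calls and pathways")
  A <- calls$altered[universe, , drop = FALSE]
  K <- colSums(A)
  pw <- pathway_ids(ps)
  in_universe <- lapply(pw, function(pid) intersect(pathway_genes(ps, pid),
                                                    universe))
  names(in_universe) <- pw
  tested <- pw[vapply(in_universe, length, 1L) > 0L]
  dropped <- setdiff(pw, tested)
  if (length(dropped) > 0L)
    message(length(dropped), " pathway(s) with no gene in the call matrix ",
            "excluded: ", paste(dropped, collapse = ", "))
  bon <- alpha / length(tested)
  patient_p <- list()
  n_zero <- 0L
  rows <- lapply(tested, function(pid) {
    genes <- in_universe[[pid]]
    N <- length(genes)
    x <- colSums(A[genes, , drop = FALSE])
    pj <- vapply(seq_along(K), function(j)
      patient_pathway_p(x[j], M, K[j], N, inclusive = inclusive), 1)
    n_zero <<- n_zero + sum(pj == 0)
    fo <- suppressWarnings(fisher_omnibus(pj))
    patient_p[[pid]] <<- pj
    data.frame(pathway_id = pid, n_genes = N, fisher_stat = fo$statistic,
               df = fo$df, combined_p = fo$combined_p,
               bonferroni_alpha = bon, targeted = fo$combined_p < bon,
               stringsAsFactors = FALSE)
  })
  if (n_zero > 0L)
    message(n_zero, " exact-zero patient p-value(s) floored at 1e-300 ",
            "(exclusive-tail convention)")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "patient_p") <- patient_p
  attr(out, "M") <- M
  class(out) <- c("targeting_result", "data.frame")
  out
}

#' Write a targeting result table
#' @param result a `targeting_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_targeting_result <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
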