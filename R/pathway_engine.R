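#' Activity of a single interaction
#'
#' The probability that an interaction fires: the product over its promoter
#' genes of P(up) times the product over its inhibitor genes of 1 - P(up).
#' Input genes without a posterior are dropped; if no input genes remain the
#' interaction is unscoreable and `NA` is returned.
#'
#' @param interaction list with elements `promoters`, `inhibitors`,
#'   `outputs` (character vectors of gene symbols).
#' @param posteriors named numeric vector, P(up) per gene for one sample.
#' @return probability in \[0, 1\], or `NA` if no input gene has a
#'   posterior.
#' @export
interaction_activity <- function(interaction, posteriors) {
  pro <- intersect(interaction$promoters, names(posteriors))
  inh <- intersect(interaction$inhibitors, names(posteriors))
  if (length(pro) + length(inh) == 0L) return(NA_real_)
  prod(posteriors[pro]) * prod(1 - posteriors[inh])
}

#' Consistency of a single interaction
#'
#' Compares the expected with the observed state of the interaction's
#' output genes. With activity `a` and mean output up-posterior `q`, an
#' activating interaction expects the output up when it fires:
#' `a * q + (1 - a) * (1 - q)`. If the interaction represses its output,
#' the complementary form `a * (1 - q) + (1 - a) * q` applies.
#'
#' @param interaction as in [interaction_activity()]; must have at least
#'   one output gene with a posterior, otherwise `NA` is returned and the
#'   interaction is excluded from the pathway consistency mean.
#' @param posteriors named numeric vector of P(up) for one sample.
#' @param inhibitory_output set `TRUE` if the interaction represses its
#'   output gene(s).
#' @return probability in \[0, 1\], or `NA`.
#' @export
interaction_consistency <- function(interaction, posteriors,
                                    inhibitory_output = FALSE) {
  out <- intersect(interaction$outputs, names(posteriors))
  if (length(out) == 0L) return(NA_real_)
  a <- interaction_activity(interaction, posteriors)
  if (is.na(a)) return(NA_real_)
  q <- mean(posteriors[out])
  if (inhibitory_output) a * (1 - q) + (1 - a) * q
  else a * q + (1 - a) * (1 - q)
}

#' Score every pathway in every sample
#'
#' For each pathway and sample, activity is the arithmetic mean of
#' [interaction_activity()] over scoreable interactions and consistency the
#' mean of [interaction_consistency()] over interactions that have output
#' genes. Pathways whose member-gene coverage in the model collection falls
#' below `min_coverage`, or with no scoreable interaction, are excluded and
#' reported.
#'
#' @param ps a `pathway_set`.
#' @param models a `gene_state_models` collection (from [fit_all_genes()]).
#' @param min_coverage minimum fraction of pathway member genes that must
#'   have a fitted model (default 0.5).
#' @return an object of class `pathway_scores`: list with `activity` and
#'   `consistency` matrices (pathways x samples), per-pathway `coverage`,
#'   and `excluded` pathway ids.
#' @export
score_pathways <- function(ps, models, min_coverage = 0.5) {
  P <- posterior_matrix(models)
  samples <- colnames(P)
  pw_ids <- pathway_ids(ps)
  act <- cons <- matrix(NA_real_, length(pw_ids), ncol(P),
                        dimnames = list(pw_ids, samples))
  coverage <- stats::setNames(numeric(length(pw_ids)), pw_ids)
  excluded <- character(0)
  for (pid in pw_ids) {
    genes <- pathway_genes(ps, pid)
    coverage[pid] <- mean(genes %in% rownames(P))
    if (coverage[pid] < min_coverage) {
      excluded <- c(excluded, pid)
      next
    }
    ints <- ps$pathways[[pid]]
    a_rows <- lapply(ints, function(it) {
      pro <- intersect(it$promoters, rownames(P))
      inh <- intersect(it$inhibitors, rownames(P))
      if (length(pro) + length(inh) == 0L) return(NULL)
      a <- rep(1, ncol(P))
      for (g in pro) a <- a * P[g, ]
      for (g in inh) a <- a * (1 - P[g, ])
      a
    })
    scoreable <- !vapply(a_rows, is.null, TRUE)
    if (!any(scoreable)) {
      excluded <- c(excluded, pid)
      next
    }
    A <- do.call(rbind, a_rows[scoreable])
    act[pid, ] <- colMeans(A)
    c_rows <- mapply(function(it, a) {
      if (is.null(a)) return(NULL)
      out <- intersect(it$outputs, rownames(P))
      if (length(out) == 0L) return(NULL)
      q <- if (length(out) == 1L) P[out, ] else colMeans(P[out, , drop = FALSE])
      a * q + (1 - a) * (1 - q)
    }, ints, a_rows, SIMPLIFY = FALSE)
    c_keep <- !vapply(c_rows, is.null, TRUE)
    if (any(c_keep))
      cons[pid, ] <- colMeans(do.call(rbind, c_rows[c_keep]))
  }
  if (length(excluded) > 0L)
    message(length(excluded), " pathway(s) excluded (low coverage or no ",
            "scoreable interaction): ", paste(excluded, collapse = ", "))
  keep <- setdiff(pw_ids, excluded)
  structure(list(activity = act[keep, , drop = FALSE],
                 consistency = cons[keep, , drop = FALSE],
                 coverage = coverage, excluded = excluded),
            class = "pathway_scores")
}

#' @export
print.pathway_scores <- function(x, ...) {
  cat("pathway_scores:", nrow(x$activity), "pathways x",
      ncol(x$activity), "samples;", length(x$excluded), "excluded\n")
  invisible(x)
}

#' Write pathway score matrices as tab-delimited files
#' @param scores a `pathway_scores` object.
#' @param activity_path,consistency_path output paths (either may be
#'   `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_pathway_scores <- function(scores, activity_path = NULL,
                                 consistency_path = NULL) {
  if (!is.null(activity_path)) write_matrix(scores$activity, activity_path)
  if (!is.null(consistency_path))
    write_matrix(scores$consistency, consistency_path)
  invisible(c(activity_path, consistency_path))
}
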