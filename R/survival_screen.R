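#' Exact two-group clustering of one-dimensional values
#'
#' The K = 2 optimum that K-means seeks in one dimension can be found
#' exactly: in sorted order the two optimal clusters are contiguous, so the
#' best of the n - 1 sorted split points (minimum total within-cluster sum
#' of squares) is the global optimum. Ties in the criterion are broken
#' toward the more balanced split, then toward the smaller lower cluster;
#' the result is deterministic. The lower-mean cluster is labelled 1.
#'
#' @param values numeric vector (length >= 4, not all identical).
#' @return integer vector of labels in \{1, 2\}, parallel to `values`.
#' @export
two_means_1d <- function(values) {
  n <- length(values)
  if (n < 4L) stop("need at least 4 values to cluster")
  if (max(values) - min(values) == 0)
    stop("unclusterable feature: all values identical")
  o <- order(values)
  s <- values[o]
  cs <- cumsum(s)
  css <- cumsum(s^2)
  k <- seq_len(n - 1L)
  wss <- (css[k] - cs[k]^2 / k) +
    ((css[n] - css[k]) - (cs[n] - cs[k])^2 / (n - k))
  best <- which(wss <= min(wss) + 1e-12 * max(abs(wss), 1))
  if (length(best) > 1L) {
    bal <- abs(best - n / 2)
    best <- best[bal == min(bal)]
    best <- min(best)
  }
  g <- integer(n)
  g[o[seq_len(best)]] <- 1L
  g[o[(best + 1L):n]] <- 2L
  g
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times positive survival/censoring times.
#' @param events binary event indicators (1 = event, 0 = censored).
#' @return a `data.frame` of class `km_curve` with one row per distinct
#'   event time: `time`, `n_risk`, `n_event`, `surv` (the right-continuous
#'   survival estimate after that time); S(0) = 1.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty input")
  if (any(times <= 0)) stop("times must be positive")
  if (!all(events %in% c(0, 1))) stop("events must be binary")
  ut <- sort(unique(times[events == 1]))
  if (length(ut) == 0L) {
    out <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), surv = numeric(0))
    class(out) <- c("km_curve", "data.frame")
    return(out)
  }
  n_risk <- vapply(ut, function(t) sum(times >= t), 1)
  n_event <- vapply(ut, function(t) sum(times == t & events == 1), 1)
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    surv = surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#' @param km a `km_curve` from [km_estimate()].
#' @param t times at which to evaluate S(t).
#' @return survival probabilities (right-continuous step function, S(0)=1).
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(tt) {
    i <- sum(km$time <= tt)
    if (i == 0L) 1 else km$surv[i]
  }, 1)
}

#' Two-group log-rank test
#'
#' Standard (rho = 0) log-rank chi-square with 1 degree of freedom, using
#' the hypergeometric variance with the tie correction, identical to the
#' statistic of the conventional survival-analysis implementations.
#'
#' @param times positive times.
#' @param events binary event indicators.
#' @param groups two-level group labels.
#' @return list with `statistic` (nonnegative) and `p_value` (chi-square
#'   upper tail, 1 df). Identical survival experience gives statistic 0 and
#'   p = 1.
#' @export
logrank_test <- function(times, events, groups) {
  g <- as.integer(factor(groups))
  if (length(unique(g)) != 2L) stop("exactly two non-empty groups required")
  ut <- sort(unique(times[events == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ut) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1L)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1L)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (v > 0) o_minus_e^2 / v else 0
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Screen features for survival stratification
#'
#' For every feature (a gene's expression or a pathway's score across
#' samples): cluster the samples into two groups with [two_means_1d()],
#' then test the groups' survival curves with [logrank_test()]. Features
#' with p below `alpha` are flagged significant. Unclusterable (constant)
#' features are skipped and reported. Only samples present in both the
#' feature matrix and the clinical table are used.
#'
#' @param feature_matrix numeric matrix, features x samples.
#' @param clinical clinical table (`sample_id`, `time`, `event`).
#' @param alpha significance threshold on the raw log-rank p (default
#'   0.05).
#' @param feature_kind label recorded per feature (e.g. `"gene"`,
#'   `"pathway_activity"`).
#' @param adjust `"none"` (default; raw p-values, robustness coming from
#'   cross-cohort intersection) or `"BH"` for Benjamini-Hochberg.
#' @return a `data.frame` of class `screen_report`: `feature_id`,
#'   `feature_kind`, `n1`, `n2`, `statistic`, `p_value`, `significant`;
#'   skipped features in the `"skipped"` attribute.
#' @export
screen_features <- function(feature_matrix, clinical, alpha = 0.05,
                            feature_kind = "gene",
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  al <- align_samples(feature_matrix, clinical)
  m <- al$m
  cl <- al$clinical
  skipped <- character(0)
  rows <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    if (max(v) - min(v) == 0 || length(v) < 4L) {
      skipped <- c(skipped, rownames(m)[i])
      next
    }
    grp <- two_means_1d(v)
    lr <- logrank_test(cl$time, cl$event, grp)
    rows[[i]] <- data.frame(feature_id = rownames(m)[i],
                            feature_kind = feature_kind,
                            n1 = sum(grp == 1L), n2 = sum(grp == 2L),
                            statistic = lr$statistic, p_value = lr$p_value,
                            stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0L)
    message(length(skipped), " unclusterable feature(s) skipped")
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(feature_id = character(0), feature_kind = character(0),
                      n1 = integer(0), n2 = integer(0),
                      statistic = numeric(0), p_value = numeric(0))
  p_use <- if (adjust == "BH") stats::p.adjust(out$p_value, "BH")
           else out$p_value
  out$significant <- p_use < alpha
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("screen_report", "data.frame")
  out
}

#' Significant feature ids of a screen report
#' @param report a `screen_report`.
#' @return character vector of significant feature ids.
#' @export
significant_features <- function(report) {
  report$feature_id[report$significant]
}

#' Intersect significant feature sets across datasets
#'
#' @param sets named list (one per dataset) of character vectors of
#'   significant feature ids; at least two datasets.
#' @return list with `intersection` (features significant in every
#'   dataset) and `pairwise` (named list of all pairwise intersections).
#' @export
intersect_significant <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 datasets to intersect")
  if (is.null(names(sets)))
    names(sets) <- paste0("dataset", seq_along(sets))
  inter <- Reduce(intersect, sets)
  pairs <- utils::combn(names(sets), 2L, simplify = FALSE)
  pairwise <- lapply(pairs, function(p) intersect(sets[[p[1L]]],
                                                  sets[[p[2L]]]))
  names(pairwise) <- vapply(pairs, paste, "", collapse = "&")
  list(intersection = inter, pairwise = pairwise)
}

#' Write a screen report as tab-delimited text
#' @param report a `screen_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
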