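#' Run the full multi-cohort analysis on in-memory data
#'
#' Per dataset: fit per-gene gamma-mixture state models, score pathways,
#' screen genes and pathway scores for survival stratification; then
#' intersect the significant sets across datasets (full and all pairwise),
#' scan CNV and methylation calls for pathway targeting, and characterize
#' every pathway in the full pathway-tier intersection.
#'
#' @param datasets named list; each element a list with `expression`,
#'   `clinical`, `cnv` (optional), `methylation` (optional).
#' @param ps a `pathway_set`.
#' @param alpha per-feature screen significance level (default 0.05, raw
#'   p-values).
#' @param family_alpha family-wise level of the targeting scan.
#' @param metric pathway metric screened for survival: `"activity"`
#'   (default) or `"consistency"`.
#' @param tol,max_iter,seed passed to [fit_all_genes()].
#' @return an object of class `pathstrat_run`: list with per-dataset
#'   results (`models`, `scores`, `gene_screen`, `pathway_screen`,
#'   `targeting_cnv`, `targeting_methylation`), cross-dataset
#'   `gene_intersection` and `pathway_intersection` (each with full and
#'   pairwise sets), and `characterization` of intersected pathways.
#' @export
run_cohort_analysis <- function(datasets, ps, alpha = 0.05,
                                family_alpha = 0.05,
                                metric = c("activity", "consistency"),
                                tol = 1e-6, max_iter = 500, seed = 1L) {
  metric <- match.arg(metric)
  if (length(datasets) < 1L) stop("need at least one dataset")
  per <- list()
  for (d in names(datasets)) {
    ds <- datasets[[d]]
    models <- fit_all_genes(ds$expression, tol = tol, max_iter = max_iter,
                            seed = seed)
    scores <- score_pathways(ps, models)
    gene_screen <- screen_features(ds$expression, ds$clinical, alpha = alpha,
                                   feature_kind = "gene")
    feat <- if (metric == "activity") scores$activity else scores$consistency
    pathway_screen <- screen_features(feat, ds$clinical, alpha = alpha,
                                      feature_kind =
                                        paste0("pathway_", metric))
    targeting_cnv <- if (!is.null(ds$cnv))
      targeting_scan(call_cnv(ds$cnv), ps, alpha = family_alpha) else NULL
    targeting_meth <- if (!is.null(ds$methylation))
      targeting_scan(call_methylation(ds$methylation), ps,
                     alpha = family_alpha) else NULL
    per[[d]] <- list(models = models, scores = scores,
                     gene_screen = gene_screen,
                     pathway_screen = pathway_screen,
                     targeting_cnv = targeting_cnv,
                     targeting_methylation = targeting_meth)
  }
  gene_sets <- lapply(per, function(p) significant_features(p$gene_screen))
  path_sets <- lapply(per, function(p)
    significant_features(p$pathway_screen))
  gene_int <- if (length(per) >= 2L) intersect_significant(gene_sets)
              else list(intersection = gene_sets[[1L]], pairwise = list())
  path_int <- if (length(per) >= 2L) intersect_significant(path_sets)
              else list(intersection = path_sets[[1L]], pairwise = list())

  characterization <- list()
  for (pid in path_int$intersection) {
    characterization[[pid]] <- lapply(names(datasets), function(d) {
      ds <- datasets[[d]]
      if (is.null(ds$cnv)) return(NULL)
      feat <- if (metric == "activity") per[[d]]$scores$activity
              else per[[d]]$scores$consistency
      if (!pid %in% rownames(feat)) return(NULL)
      al <- align_samples(feat[pid, , drop = FALSE], ds$clinical)
      grp <- stats::setNames(two_means_1d(al$m[1L, ]), colnames(al$m))
      characterize_pathway(pid, ps, ds$expression, call_cnv(ds$cnv),
                           ds$cnv, grp)
    })
    names(characterization[[pid]]) <- names(datasets)
  }
  structure(list(per_dataset = per,
                 gene_sets = gene_sets, pathway_sets = path_sets,
                 gene_intersection = gene_int,
                 pathway_intersection = path_int,
                 characterization = characterization,
                 alpha = alpha, family_alpha = family_alpha,
                 metric = metric, seed = seed),
            class = "pathstrat_run")
}

#' Run the full analysis from files on disk
#'
#' Reads every table named in `config`, runs [run_cohort_analysis()], and
#' writes per-stage TSV/JSON outputs plus a reproducibility manifest to
#' `config$out_dir`. Any stage failure aborts with a stage-named error and
#' leaves a `FAILED` marker file in the output directory.
#'
#' @param config list with elements `datasets` (named list; each with
#'   paths `expression`, `clinical`, and optionally `cnv`,
#'   `methylation`), `pathways` (path), `out_dir`, and optionally `alpha`,
#'   `family_alpha`, `metric`, `seed`.
#' @return the `pathstrat_run` result, invisibly.
#' @export
run_full_analysis <- function(config) {
  if (is.null(config$datasets) || length(config$datasets) < 1L)
    stop("config error: at least one dataset required")
  alpha <- config$alpha %||% 0.05
  if (alpha <= 0 || alpha >= 1) stop("config error: alpha must lie in (0,1)")
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste("stage:", name, "-", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  datasets <- stage("read_inputs", lapply(config$datasets, function(p) {
    list(expression = read_matrix(p$expression, "expression"),
         clinical = read_clinical(p$clinical),
         cnv = if (!is.null(p$cnv)) read_matrix(p$cnv, "cnv"),
         methylation = if (!is.null(p$methylation))
           read_matrix(p$methylation, "methylation"))
  }))
  ps <- stage("read_pathways", read_pathway_set(config$pathways))
  run <- stage("analysis", run_cohort_analysis(
    datasets, ps, alpha = alpha,
    family_alpha = config$family_alpha %||% 0.05,
    metric = config$metric %||% "activity",
    seed = config$seed %||% 1L))
  stage("write_outputs", {
    for (d in names(run$per_dataset)) {
      p <- run$per_dataset[[d]]
      write_screen_report(p$gene_screen,
                          file.path(out_dir, paste0(d, "_gene_screen.tsv")))
      write_screen_report(p$pathway_screen,
                          file.path(out_dir,
                                    paste0(d, "_pathway_screen.tsv")))
      if (!is.null(p$targeting_cnv))
        write_targeting_result(p$targeting_cnv,
                               file.path(out_dir,
                                         paste0(d, "_targeting_cnv.tsv")))
      if (!is.null(p$targeting_methylation))
        write_targeting_result(
          p$targeting_methylation,
          file.path(out_dir, paste0(d, "_targeting_methylation.tsv")))
    }
    jsonlite::write_json(
      list(gene_intersection = run$gene_intersection,
           pathway_intersection = run$pathway_intersection),
      file.path(out_dir, "intersections.json"), auto_unbox = TRUE)
    jsonlite::write_json(
      list(package_version = as.character(utils::packageVersion("pathstrat")),
           r_version = R.version.string,
           seed = run$seed, alpha = run$alpha,
           family_alpha = run$family_alpha, metric = run$metric,
           config = config[setdiff(names(config), "out_dir")],
           timestamp = format(Sys.time(), tz = "UTC")),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  })
  invisible(run)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pathstrat_run <- function(x, ...) {
  cat("pathstrat_run over", length(x$per_dataset), "dataset(s)\n")
  for (d in names(x$per_dataset)) {
    cat(sprintf("  %s: %d significant genes, %d significant pathways\n", d,
                length(x$gene_sets[[d]]), length(x$pathway_sets[[d]])))
  }
  cat("  gene-tier intersection:",
      if (length(x$gene_intersection$intersection) == 0L) "(empty)"
      else paste(x$gene_intersection$intersection, collapse = ", "), "\n")
  cat("  pathway-tier intersection:",
      if (length(x$pathway_intersection$intersection) == 0L) "(empty)"
      else paste(x$pathway_intersection$intersection, collapse = ", "),
      "\n")
  invisible(x)
}
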