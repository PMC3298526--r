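#' Configuration for a synthetic multi-cohort study
#'
#' The generator plants one driver pathway whose latent per-sample activity
#' state is coupled both to its member genes' expression states and to the
#' survival hazard. All remaining genes follow per-gene random two-state
#' mixtures independent of survival. Per dataset, a fraction of driver
#' genes is decoupled (their expression severed from the latent state),
#' which is the mechanism that makes single genes unstable across cohorts
#' while the pathway aggregate stays detectable.
#'
#' Defaults describe the reference study conditions: three cohorts of 200,
#' 120 and 50 patients; expression on an RMA-like scale with a suppressed
#' state Gamma(shape 8, scale 0.55) (mean 4.4) and a promoted state
#' Gamma(shape 17, scale 0.36) (mean 6.12), deliberately overlapping so a
#' single gene is a noisy readout of the latent state; exponential survival
#' with baseline hazard 2.5e-3 per day tripled under high driver activity;
#' uniform right-censoring on (0, 9125) days (25-year horizon, keeping
#' censoring light so the smallest cohort retains near-maximal log-rank
#' information); background alteration rate 5% per gene per patient versus
#' 25% for driver genes.
#'
#' @param n_genes total number of genes.
#' @param n_samples_per_dataset integer vector of cohort sizes.
#' @param n_pathways number of pathways (the first is the driver).
#' @param pathway_size_range (min, max) genes per pathway; the driver
#'   pathway takes the maximum.
#' @param driver_pathway_id identifier of the driver pathway.
#' @param down_shape,down_scale,up_shape,up_scale gamma parameters of the
#'   two expression states; the up-state mean must exceed the down-state
#'   mean.
#' @param state_coupling probability that a (non-decoupled) driver gene
#'   follows the latent driver state in a high-activity sample.
#' @param decouple_fraction per-dataset fraction of driver genes whose
#'   coupling is severed (`floor(decouple_fraction * n_driver)` genes,
#'   drawn independently per dataset).
#' @param hazard_base baseline exponential hazard (per day).
#' @param hazard_ratio multiplicative hazard under high driver activity
#'   (> 0).
#' @param censor_max horizon of the uniform censoring distribution (days).
#' @param alt_rate_background,alt_rate_driver per-gene-per-patient
#'   alteration probabilities (CNV spikes / methylation) for background and
#'   driver genes.
#' @param inhibitor_prob probability that a non-driver interaction input is
#'   an inhibitor rather than a promoter.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 250,
                          n_samples_per_dataset = c(200, 120, 50),
                          n_pathways = 10,
                          pathway_size_range = c(8, 40),
                          driver_pathway_id = "PW_DRIVER",
                          down_shape = 8, down_scale = 0.55,
                          up_shape = 17, up_scale = 0.36,
                          state_coupling = 0.9,
                          decouple_fraction = 0.3,
                          hazard_base = 2.5e-3,
                          hazard_ratio = 3,
                          censor_max = 9125,
                          alt_rate_background = 0.05,
                          alt_rate_driver = 0.25,
                          inhibitor_prob = 0.25,
                          seed = 1L) {
  cfg <- list(n_genes = n_genes,
              n_samples_per_dataset = as.integer(n_samples_per_dataset),
              n_pathways = n_pathways,
              pathway_size_range = pathway_size_range,
              driver_pathway_id = driver_pathway_id,
              down_shape = down_shape, down_scale = down_scale,
              up_shape = up_shape, up_scale = up_scale,
              state_coupling = state_coupling,
              decouple_fraction = decouple_fraction,
              hazard_base = hazard_base, hazard_ratio = hazard_ratio,
              censor_max = censor_max,
              alt_rate_background = alt_rate_background,
              alt_rate_driver = alt_rate_driver,
              inhibitor_prob = inhibitor_prob,
              seed = as.integer(seed))
  if (cfg$up_shape * cfg$up_scale <= cfg$down_shape * cfg$down_scale)
    stop("config error: up-state mean must exceed down-state mean")
  if (cfg$state_coupling < 0 || cfg$state_coupling > 1)
    stop("config error: state_coupling must lie in [0,1]")
  if (cfg$hazard_ratio <= 0) stop("config error: hazard_ratio must be > 0")
  rates <- c(cfg$decouple_fraction, cfg$alt_rate_background,
             cfg$alt_rate_driver, cfg$inhibitor_prob)
  if (any(rates < 0 | rates > 1)) stop("config error: rates must lie in [0,1]")
  if (max(cfg$pathway_size_range) > cfg$n_genes)
    stop("config error: pathway_size_range exceeds n_genes")
  if (cfg$pathway_size_range[1L] < 2L)
    stop("config error: pathways need at least 2 genes")
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic multi-cohort study
#'
#' Per dataset: a latent driver state `L ~ Bernoulli(0.5)` per sample;
#' driver-pathway genes outside that dataset's decoupled subset are drawn
#' from the up-state gamma with probability `state_coupling` when `L = 1`
#' and from the down-state gamma otherwise; decoupled driver genes and all
#' non-driver genes follow per-gene random mixtures (mixing weight uniform
#' on (0.25, 0.75)) independent of `L` and of survival. Survival is
#' exponential with hazard `hazard_base * hazard_ratio^L`, right-censored
#' at `Uniform(0, censor_max)`. CNV log ratios are N(0, 0.1) background
#' with +-0.8 spikes at the alteration rate (driver genes use
#' `alt_rate_driver`); methylation betas are Beta(2, 8) background with
#' Beta(8, 2) draws at the same alteration rates. Pathways are linear
#' cascades: each member gene is the single input of one interaction whose
#' output is the next member (ring closure); driver interactions are all
#' promoting, non-driver inputs are inhibitors with probability
#' `inhibitor_prob`.
#'
#' @param config a `cohort_config`.
#' @return an object of class `synthetic_cohort`: list with `datasets` (a
#'   named list, each with `expression`, `clinical`, `cnv`, `methylation`),
#'   `pathways` (a `pathway_set`), `truth` (driver pathway id, per-dataset
#'   latent states and decoupled gene lists, driver gene list), and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_driver <- max(config$pathway_size_range)
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  driver_genes <- genes[seq_len(n_driver)]
  other_pool <- setdiff(genes, driver_genes)

  # pathway topology: ring cascades
  pw_ids <- c(config$driver_pathway_id,
              sprintf("PW%02d", seq_len(config$n_pathways - 1L)))
  members <- vector("list", config$n_pathways)
  members[[1L]] <- driver_genes
  for (k in seq_len(config$n_pathways - 1L)) {
    sz <- sample(config$pathway_size_range[1L]:config$pathway_size_range[2L],
                 1L)
    members[[k + 1L]] <- sample(other_pool, min(sz, length(other_pool)))
  }
  names(members) <- pw_ids
  rec <- do.call(rbind, lapply(seq_along(pw_ids), function(k) {
    g <- members[[k]]
    nk <- length(g)
    nxt <- g[c(2:nk, 1L)]
    role_in <- if (k == 1L) rep("promoter", nk)
               else ifelse(stats::runif(nk) < config$inhibitor_prob,
                           "inhibitor", "promoter")
    iid <- sprintf("%s_I%02d", pw_ids[k], seq_len(nk))
    rbind(data.frame(pathway_id = pw_ids[k], interaction_id = iid,
                     gene = g, role = role_in, stringsAsFactors = FALSE),
          data.frame(pathway_id = pw_ids[k], interaction_id = iid,
                     gene = nxt, role = "output", stringsAsFactors = FALSE))
  }))
  ps <- pathway_set(rec)

  # per-gene background mixing weights, shared across datasets
  bg_weight <- stats::setNames(stats::runif(config$n_genes, 0.25, 0.75),
                               genes)

  n_dec <- floor(config$decouple_fraction * n_driver)
  datasets <- list()
  truth_latent <- list()
  truth_dec <- list()
  for (d in seq_along(config$n_samples_per_dataset)) {
    n <- config$n_samples_per_dataset[d]
    sid <- sprintf("D%dS%03d", d, seq_len(n))
    L <- stats::rbinom(n, 1L, 0.5)
    dec <- sort(sample(driver_genes, n_dec))
    state <- matrix(0L, config$n_genes, n, dimnames = list(genes, sid))
    for (g in genes) {
      state[g, ] <- if (g %in% driver_genes && !(g %in% dec))
        L * stats::rbinom(n, 1L, config$state_coupling)
      else stats::rbinom(n, 1L, bg_weight[g])
    }
    expr <- matrix(0, config$n_genes, n, dimnames = list(genes, sid))
    up_idx <- state == 1L
    expr[up_idx] <- stats::rgamma(sum(up_idx), config$up_shape,
                                  scale = config$up_scale)
    expr[!up_idx] <- stats::rgamma(sum(!up_idx), config$down_shape,
                                   scale = config$down_scale)

    t_event <- stats::rexp(n, config$hazard_base * config$hazard_ratio^L)
    t_cens <- stats::runif(n, 0, config$censor_max)
    clinical <- validate_clinical(data.frame(
      sample_id = sid,
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      stringsAsFactors = FALSE))

    rate <- ifelse(genes %in% driver_genes, config$alt_rate_driver,
                   config$alt_rate_background)
    spike <- matrix(stats::rbinom(config$n_genes * n, 1L, rep(rate, n)),
                    config$n_genes, n, dimnames = list(genes, sid))
    sign <- matrix(sample(c(-1, 1), config$n_genes * n, replace = TRUE),
                   config$n_genes, n)
    cnv <- ifelse(spike == 1L, sign * 0.8,
                  matrix(stats::rnorm(config$n_genes * n, 0, 0.1),
                         config$n_genes, n))
    dimnames(cnv) <- list(genes, sid)
    spike_m <- matrix(stats::rbinom(config$n_genes * n, 1L, rep(rate, n)),
                      config$n_genes, n)
    meth <- ifelse(spike_m == 1L,
                   matrix(stats::rbeta(config$n_genes * n, 8, 2),
                          config$n_genes, n),
                   matrix(stats::rbeta(config$n_genes * n, 2, 8),
                          config$n_genes, n))
    dimnames(meth) <- list(genes, sid)

    datasets[[paste0("dataset", d)]] <- list(
      expression = structure(expr, kind = "expression"),
      clinical = clinical,
      cnv = structure(cnv, kind = "cnv"),
      methylation = structure(meth, kind = "methylation"))
    truth_latent[[paste0("dataset", d)]] <- stats::setNames(L, sid)
    truth_dec[[paste0("dataset", d)]] <- dec
  }
  structure(list(datasets = datasets, pathways = ps,
                 truth = list(driver_pathway = config$driver_pathway_id,
                              driver_genes = driver_genes,
                              latent = truth_latent,
                              decoupled = truth_dec),
                 config = config),
            class = "synthetic_cohort")
}

#' Truth summary of a synthetic cohort
#'
#' @param cohort a `synthetic_cohort`.
#' @return a `data.frame` with one row per sample (`dataset`, `sample_id`,
#'   `latent_state`); the per-dataset decoupled gene lists are attached as
#'   the `"decoupled"` attribute and the driver pathway id as
#'   `"driver_pathway"`.
#' @export
truth_report <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  tab <- do.call(rbind, lapply(names(cohort$truth$latent), function(d) {
    L <- cohort$truth$latent[[d]]
    data.frame(dataset = d, sample_id = names(L),
               latent_state = as.integer(L), stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  attr(tab, "decoupled") <- cohort$truth$decoupled
  attr(tab, "driver_pathway") <- cohort$truth$driver_pathway
  tab
}

#' Write a synthetic cohort to a directory in the pipeline's file dialects
#'
#' Per dataset, writes `expression.tsv`, `clinical.tsv`, `cnv.tsv`,
#' `methylation.tsv`; plus `pathways.tsv` and `truth.json` at the top
#' level.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in names(cohort$datasets)) {
    dd <- file.path(dir, d)
    dir.create(dd, showWarnings = FALSE)
    ds <- cohort$datasets[[d]]
    write_matrix(ds$expression, file.path(dd, "expression.tsv"))
    write_clinical(ds$clinical, file.path(dd, "clinical.tsv"))
    write_matrix(ds$cnv, file.path(dd, "cnv.tsv"))
    write_matrix(ds$methylation, file.path(dd, "methylation.tsv"))
  }
  write_pathway_set(cohort$pathways, file.path(dir, "pathways.tsv"))
  jsonlite::write_json(list(driver_pathway = cohort$truth$driver_pathway,
                            driver_genes = cohort$truth$driver_genes,
                            # named lists so sample names survive the
                            # JSON round-trip
                            latent = lapply(cohort$truth$latent, as.list),
                            decoupled = cohort$truth$decoupled),
                       file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", length(x$datasets), "datasets (",
      paste(vapply(x$datasets, function(d) ncol(d$expression), 1L),
            collapse = ", "),
      "samples),", x$config$n_genes, "genes,",
      length(pathway_ids(x$pathways)), "pathways; driver:",
      x$truth$driver_pathway, "\n")
  invisible(x)
}
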