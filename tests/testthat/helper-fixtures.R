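# Shared fixtures: small cohort configurations and hand-built objects used
# across test files. Everything is generated in code; no stored data.

small_config <- function(seed = 1L, ...) {
  args <- list(n_genes = 60, n_samples_per_dataset = c(60, 40),
               n_pathways = 4, pathway_size_range = c(4, 10), seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(cohort_config, args)
}

# a model collection with prescribed posterior matrix (genes x samples)
make_models <- function(P) {
  models <- lapply(rownames(P), function(g) {
    structure(list(gene_id = g, down_shape = 2, down_scale = 1,
                   up_shape = 20, up_scale = 1, weight_up = 0.5,
                   degenerate = FALSE,
                   posteriors = stats::setNames(P[g, ], colnames(P)),
                   loglik = NA_real_, loglik_trace = numeric(0),
                   n_iter = 1L),
              class = "gene_state_model")
  })
  names(models) <- rownames(P)
  structure(models, class = "gene_state_models", n_degenerate = 0L)
}

make_interaction <- function(promoters = character(0),
                             inhibitors = character(0),
                             outputs = character(0), id = "I1") {
  list(id = id, promoters = promoters, inhibitors = inhibitors,
       outputs = outputs)
}

# random right-censored survival data with two groups
random_surv_data <- function(n, p_censor = 0.3, ties = TRUE) {
  time <- if (ties) sample(1:10, n, replace = TRUE) +
            sample(c(0, 0.5), n, replace = TRUE)
          else stats::rexp(n, 0.1)
  list(time = time,
       event = stats::rbinom(n, 1, 1 - p_censor),
       group = sample(rep(1:2, length.out = n)))
}

write_tsv_fixture <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
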