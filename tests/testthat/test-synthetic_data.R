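test_that("identical seeds give bit-identical cohorts", {
  a <- generate_cohort(small_config(seed = 7))
  b <- generate_cohort(small_config(seed = 7))
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- generate_cohort(small_config(seed = 8))
  expect_false(identical(a$datasets$dataset1$expression,
                         c2$datasets$dataset1$expression))
})

test_that("cohort invariants hold: shapes, sample alignment, value ranges", {
  co <- generate_cohort(small_config(seed = 2))
  for (ds in co$datasets) {
    sid <- colnames(ds$expression)
    expect_identical(colnames(ds$cnv), sid)
    expect_identical(colnames(ds$methylation), sid)
    expect_identical(ds$clinical$sample_id, sid)
    expect_true(all(ds$expression > 0))
    expect_true(all(ds$methylation >= 0 & ds$methylation <= 1))
    expect_true(all(ds$clinical$time > 0))
    expect_true(all(ds$clinical$event %in% 0:1))
  }
  expect_true(co$truth$driver_pathway %in% pathway_ids(co$pathways))
  expect_setequal(pathway_genes(co$pathways, co$truth$driver_pathway),
                  co$truth$driver_genes)
})

test_that("config validation rejects impossible settings", {
  expect_error(cohort_config(pathway_size_range = c(4, 500), n_genes = 100),
               "config error")
  expect_error(cohort_config(up_shape = 1, up_scale = 1,
                             down_shape = 8, down_scale = 1),
               "up-state mean")
  expect_error(cohort_config(state_coupling = 1.2), "config error")
  expect_error(cohort_config(hazard_ratio = -1), "config error")
})

test_that("truth_report has one row per sample and floor-rule decoupling", {
  cfg <- small_config(seed = 5, pathway_size_range = c(4, 20),
                      decouple_fraction = 0.3)
  co <- generate_cohort(cfg)
  tr <- truth_report(co)
  expect_equal(nrow(tr), sum(cfg$n_samples_per_dataset))
  expect_true(all(tr$latent_state %in% 0:1))
  # 20 driver genes at fraction 0.3 -> floor(6) decoupled per dataset
  dec <- attr(tr, "decoupled")
  expect_true(all(vapply(dec, length, 1L) == 6L))
  expect_true(all(unlist(dec) %in% co$truth$driver_genes))
  expect_equal(attr(tr, "driver_pathway"), co$truth$driver_pathway)
})

test_that("driver-gene group marginals match the configured gamma components", {
  cfg <- cohort_config(n_genes = 12, n_samples_per_dataset = 1000,
                       n_pathways = 2, pathway_size_range = c(4, 8),
                       state_coupling = 1, decouple_fraction = 0, seed = 9)
  co <- generate_cohort(cfg)
  L <- co$truth$latent$dataset1
  g <- co$truth$driver_genes[1L]
  x <- co$datasets$dataset1$expression[g, ]
  ks_up <- ks.test(x[L == 1], pgamma, shape = cfg$up_shape,
                   scale = cfg$up_scale)
  ks_dn <- ks.test(x[L == 0], pgamma, shape = cfg$down_shape,
                   scale = cfg$down_scale)
  expect_gt(ks_up$p.value, 0.01)
  expect_gt(ks_dn$p.value, 0.01)
})

test_that("censoring fraction decreases as the censoring horizon grows", {
  frac <- vapply(c(1000, 5000, 20000), function(cm) {
    co <- generate_cohort(small_config(seed = 4, censor_max = cm,
                                       n_samples_per_dataset = 400))
    1 - mean(co$datasets$dataset1$clinical$event)
  }, 1)
  expect_true(all(diff(frac) < 0))
})

test_that("decouple-free driver genes shrink geometrically across datasets", {
  frac <- vapply(1:30, function(s) {
    cfg <- small_config(seed = 100 + s, pathway_size_range = c(4, 20),
                        decouple_fraction = 0.3,
                        n_samples_per_dataset = c(20, 20, 20))
    co <- generate_cohort(cfg)
    dec <- co$truth$decoupled
    free <- Reduce(setdiff, dec, co$truth$driver_genes)
    length(free) / length(co$truth$driver_genes)
  }, 1)
  # expectation (14/20)^3 ~ 0.343; mean of 30 draws of 20 genes
  expect_lt(abs(mean(frac) - (14 / 20)^3), 0.08)
})

test_that("driver activity separates latent groups at full coupling", {
  cfg <- cohort_config(n_genes = 40, n_samples_per_dataset = 120,
                       n_pathways = 3, pathway_size_range = c(4, 12),
                       state_coupling = 1, decouple_fraction = 0,
                       hazard_ratio = 4, seed = 21)
  co <- generate_cohort(cfg)
  models <- suppressMessages(
    fit_all_genes(co$datasets$dataset1$expression, seed = 1))
  sc <- suppressMessages(score_pathways(co$pathways, models))
  act <- sc$activity[co$truth$driver_pathway, ]
  L <- co$truth$latent$dataset1
  # rank-based AUC of activity against the latent truth
  r <- rank(act)
  n1 <- sum(L == 1); n0 <- sum(L == 0)
  auc <- (sum(r[L == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  expect_gt(auc, 0.9)
})

test_that("write_cohort emits the documented file layout", {
  co <- generate_cohort(small_config(seed = 12))
  d <- tempfile("cohort")
  write_cohort(co, d)
  expect_true(file.exists(file.path(d, "pathways.tsv")))
  expect_true(file.exists(file.path(d, "truth.json")))
  expect_true(file.exists(file.path(d, "dataset1", "expression.tsv")))
  m <- read_matrix(file.path(d, "dataset2", "cnv.tsv"), "cnv")
  expect_identical(unname(m[, ]), unname(co$datasets$dataset2$cnv[, ]))
  cl <- read_clinical(file.path(d, "dataset1", "clinical.tsv"))
  expect_equal(cl$sample_id, co$datasets$dataset1$clinical$sample_id)
  unlink(d, recursive = TRUE)
})
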