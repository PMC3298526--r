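# brute-force two-means oracle: evaluate every sorted split
brute_two_means_wss <- function(v) {
  s <- sort(v)
  n <- length(s)
  min(vapply(1:(n - 1), function(k) {
    sum((s[1:k] - mean(s[1:k]))^2) + sum((s[(k + 1):n] - mean(s[(k + 1):n]))^2)
  }, 1))
}

cluster_wss <- function(v, g) {
  sum((v[g == 1] - mean(v[g == 1]))^2) + sum((v[g == 2] - mean(v[g == 2]))^2)
}

test_that("two_means_1d finds the exact optimum, labels and symmetry", {
  expect_equal(two_means_1d(c(1, 1, 1, 10, 10)), c(1L, 1L, 1L, 2L, 2L))
  g <- two_means_1d(c(0, 0, 5, 5))
  expect_equal(g, c(1L, 1L, 2L, 2L))
  expect_equal(two_means_1d(-c(0, 0, 5, 5)), c(2L, 2L, 1L, 1L))
  expect_error(two_means_1d(rep(3, 10)), "unclusterable")
  expect_error(two_means_1d(c(1, 2, 3)), "at least 4")
})

test_that("two_means_1d matches the brute-force best sorted split", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    v <- switch(sample(3, 1),
                rnorm(n), rexp(n), round(runif(n, 0, 5), 1))
    g <- two_means_1d(v)
    expect_equal(cluster_wss(v, g), brute_two_means_wss(v),
                 tolerance = 1e-9)
    expect_lt(mean(v[g == 1]), mean(v[g == 2]))
  }
})

test_that("km_estimate matches closed forms and handles no-event input", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  all_cens <- km_estimate(c(5, 6, 7), c(0, 0, 0))
  expect_equal(km_surv_at(all_cens, c(0, 10)), c(1, 1))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("km_estimate agrees with the survival package, ties included", {
  skip_if_not_installed("survival")
  set.seed(99)
  for (i in 1:100) {
    d <- random_surv_data(sample(10:60, 1))
    km <- km_estimate(d$time, d$event)
    sf <- survival::survfit(survival::Surv(d$time, d$event) ~ 1)
    if (nrow(km) == 0L) next
    expect_equal(km_surv_at(km, sf$time), sf$surv, tolerance = 1e-12)
  }
})

test_that("log-rank null identity and label symmetry", {
  t <- c(1, 3, 4, 7, 9)
  e <- c(1, 0, 1, 1, 0)
  lr <- logrank_test(c(t, t), c(e, e), rep(1:2, each = 5))
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)
  d <- random_surv_data(40)
  a <- logrank_test(d$time, d$event, d$group)
  b <- logrank_test(d$time, d$event, 3 - d$group)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
  expect_error(logrank_test(d$time, d$event, rep(1, 40)), "two non-empty")
})

test_that("log-rank agrees with survival::survdiff to 1e-8", {
  skip_if_not_installed("survival")
  set.seed(123)
  for (i in 1:100) {
    d <- random_surv_data(sample(12:80, 1), ties = (i %% 2 == 0))
    if (sum(d$event) == 0) next
    lr <- logrank_test(d$time, d$event, d$group)
    sd <- survival::survdiff(survival::Surv(d$time, d$event) ~ d$group)
    expect_equal(lr$statistic, unname(sd$chisq), tolerance = 1e-8)
  }
})

test_that("screen flags a strong synthetic pathway and skips constants", {
  cfg <- cohort_config(n_genes = 30, n_samples_per_dataset = 120,
                       n_pathways = 2, pathway_size_range = c(4, 10),
                       state_coupling = 1, decouple_fraction = 0,
                       hazard_ratio = 4, seed = 55)
  co <- generate_cohort(cfg)
  ds <- co$datasets$dataset1
  models <- suppressMessages(fit_all_genes(ds$expression, seed = 1))
  sc <- suppressMessages(score_pathways(co$pathways, models))
  rep1 <- screen_features(sc$activity, ds$clinical, alpha = 0.05,
                          feature_kind = "pathway_activity")
  expect_true(co$truth$driver_pathway %in% significant_features(rep1))
  expect_true(all(rep1$p_value > 0 & rep1$p_value <= 1))
  expect_equal(rep1$n1 + rep1$n2, rep(ncol(sc$activity), nrow(rep1)))

  feat <- rbind(sc$activity, CONST = rep(1, ncol(sc$activity)))
  expect_message(rep2 <- screen_features(feat, ds$clinical), "skipped")
  expect_false("CONST" %in% rep2$feature_id)
  expect_equal(attr(rep2, "skipped"), "CONST")
})

test_that("screen statistics are invariant to affine feature rescaling", {
  cfg <- small_config(seed = 61)
  co <- generate_cohort(cfg)
  ds <- co$datasets$dataset1
  feat <- ds$expression[1:5, , drop = FALSE]
  r1 <- screen_features(feat, ds$clinical)
  r2 <- screen_features(feat * 3.7 + 11, ds$clinical)
  expect_equal(r2$statistic, r1$statistic)
  expect_equal(r2$p_value, r1$p_value)
})

test_that("samples absent from the clinical table are excluded", {
  co <- generate_cohort(small_config(seed = 62))
  ds <- co$datasets$dataset1
  cl <- ds$clinical[1:50, ]
  expect_message(rep1 <- screen_features(ds$expression[1:3, , drop = FALSE],
                                         cl),
                 "excluded")
  expect_equal(rep1$n1 + rep1$n2, rep(50L, 3L))
})

test_that("intersection logic matches set algebra", {
  res <- intersect_significant(list(d1 = c("A", "B"), d2 = c("B", "C"),
                                    d3 = "B"))
  expect_equal(res$intersection, "B")
  expect_equal(res$pairwise[["d1&d2"]], "B")
  expect_equal(res$pairwise[["d1&d3"]], "B")
  res2 <- intersect_significant(list(c("A"), c("B"), c("C")))
  expect_length(res2$intersection, 0L)
  expect_error(intersect_significant(list(c("A"))), "at least 2")
  # intersection is contained in every per-dataset set
  set.seed(8)
  sets <- lapply(1:3, function(i) sample(LETTERS, 10))
  res3 <- intersect_significant(sets)
  for (s in sets) expect_true(all(res3$intersection %in% s))
})
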