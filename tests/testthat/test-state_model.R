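test_that("well-separated mixture parameters are recovered", {
  set.seed(101)
  z <- rbinom(500, 1, 0.5)
  x <- ifelse(z == 1, rgamma(500, 30, scale = 1), rgamma(500, 1.5, scale = 1))
  m <- fit_gamma_mixture(x, seed = 1)
  expect_false(m$degenerate)
  expect_lt(abs(m$weight_up - 0.5), 0.05)
  expect_lt(abs(m$up_shape * m$up_scale - 30) / 30, 0.10)
  expect_lt(abs(m$down_shape * m$down_scale - 1.5) / 1.5, 0.10)
  # the larger-mean component is labelled "up"
  expect_gt(m$up_shape * m$up_scale, m$down_shape * m$down_scale)
})

test_that("EM log-likelihood is non-decreasing at every iteration", {
  set.seed(202)
  for (rep in 1:20) {
    z <- rbinom(80, 1, runif(1, 0.3, 0.7))
    x <- ifelse(z == 1, rgamma(80, 12, scale = 0.5),
                rgamma(80, 3, scale = 0.6))
    m <- fit_gamma_mixture(x, seed = rep)
    if (m$degenerate) next
    d <- diff(m$loglik_trace)
    expect_true(all(d > -1e-7 * pmax(abs(m$loglik_trace[-1]), 1)))
  }
})

test_that("mixture log-likelihood dominates the single-gamma fit", {
  skip_if_not_installed("MASS")
  set.seed(303)
  z <- rbinom(300, 1, 0.5)
  x <- ifelse(z == 1, rgamma(300, 25, scale = 1), rgamma(300, 2, scale = 1))
  m <- fit_gamma_mixture(x)
  single <- suppressWarnings(MASS::fitdistr(x, "gamma"))
  expect_gte(m$loglik, as.numeric(stats::logLik(single)) - 1e-6)
})

test_that("degenerate inputs yield the 0.5-posterior fallback", {
  m <- fit_gamma_mixture(rep(7, 50))
  expect_true(m$degenerate)
  expect_true(all(m$posteriors == 0.5))
  m2 <- fit_gamma_mixture(rgamma(10, 5))      # too few values
  expect_true(m2$degenerate)
  expect_warning(p <- posterior_up(m, 3), "degenerate")
  expect_equal(p, 0.5)
  expect_error(fit_gamma_mixture(c(1, 2, -1)), "domain error")
})

test_that("posterior_up is a proper, monotone, clipped probability", {
  set.seed(404)
  z <- rbinom(400, 1, 0.5)
  x <- ifelse(z == 1, rgamma(400, 30, scale = 1), rgamma(400, 1.5, scale = 1))
  m <- fit_gamma_mixture(x)
  grid <- seq(min(x), max(x), length.out = 200)
  p <- posterior_up(m, grid)
  expect_true(all(p >= 1e-12 & p <= 1 - 1e-12))
  expect_true(all(diff(p) >= -1e-12))          # up component dominates right tail
  expect_gt(posterior_up(m, 80), 1 - 1e-6)     # tail limit
  # crossing point of the weighted densities gives exactly 0.5
  f <- function(v) {
    dgamma(v, m$up_shape, scale = m$up_scale) * m$weight_up -
      dgamma(v, m$down_shape, scale = m$down_scale) * (1 - m$weight_up)
  }
  x0 <- uniroot(f, c(2, 25), tol = 1e-12)$root
  expect_equal(posterior_up(m, x0), 0.5, tolerance = 1e-6)
  expect_error(posterior_up(m, -1), "domain error")
})

test_that("fit_all_genes is deterministic, labels degenerates, permutes cleanly", {
  set.seed(505)
  n <- 60
  mat <- rbind(
    BIMODAL = ifelse(rbinom(n, 1, 0.5) == 1, rgamma(n, 20, scale = 0.5),
                     rgamma(n, 3, scale = 0.5)),
    FLAT = rep(2.5, n))
  colnames(mat) <- paste0("S", 1:n)
  expect_message(models <- fit_all_genes(mat, seed = 2), "1 degenerate")
  expect_equal(attr(models, "n_degenerate"), 1L)
  expect_true(models$FLAT$degenerate)
  expect_false(models$BIMODAL$degenerate)

  models2 <- suppressMessages(fit_all_genes(mat, seed = 2))
  expect_identical(models$BIMODAL[c("up_shape", "up_scale", "weight_up")],
                   models2$BIMODAL[c("up_shape", "up_scale", "weight_up")])

  perm <- sample(n)
  models3 <- suppressMessages(fit_all_genes(mat[, perm], seed = 2))
  expect_equal(models3$BIMODAL$up_shape, models$BIMODAL$up_shape)
  expect_equal(unname(models3$BIMODAL$posteriors),
               unname(models$BIMODAL$posteriors[perm]))
})

test_that("driver genes recover the Bernoulli mixing truth on synthetic data", {
  cfg <- cohort_config(n_genes = 20, n_samples_per_dataset = 200,
                       n_pathways = 2, pathway_size_range = c(4, 8),
                       state_coupling = 1, decouple_fraction = 0,
                       down_shape = 1.5, down_scale = 1,
                       up_shape = 30, up_scale = 1, seed = 31)
  co <- generate_cohort(cfg)
  L <- co$truth$latent$dataset1
  models <- suppressMessages(
    fit_all_genes(co$datasets$dataset1$expression, seed = 1))
  for (g in co$truth$driver_genes) {
    expect_false(models[[g]]$degenerate)
    expect_lt(abs(models[[g]]$weight_up - mean(L)), 0.1)
  }
})

test_that("state models serialize to a JSON parameter table", {
  set.seed(606)
  n <- 50
  mat <- rbind(A = ifelse(rbinom(n, 1, 0.5) == 1,
                          rgamma(n, 20, scale = 0.5),
                          rgamma(n, 3, scale = 0.5)),
               B = rep(1, n))
  colnames(mat) <- paste0("S", 1:n)
  models <- suppressMessages(fit_all_genes(mat))
  f <- tempfile(fileext = ".json")
  write_state_models(models, f)
  tab <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(tab$gene_id, c("A", "B"))
  expect_equal(tab$degenerate, c(FALSE, TRUE))
  expect_equal(tab$weight_up[1], models$A$weight_up)
})
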