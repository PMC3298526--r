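#' Fit a two-component gamma mixture to one gene's expression values
#'
#' Models a gene's expression across samples as a mixture of a low
#' ("down", suppressed) and a high ("up", promoted) gamma component and
#' returns per-sample posterior probabilities of the up state. The down
#' state in expression data is typically exponential-like and the up state
#' near-normal; both are special cases of the gamma family, which is why the
#' mixture is parameterised as two gammas.
#'
#' Estimation is by expectation-maximisation with an exact weighted
#' maximum-likelihood M-step for each gamma component (Newton iterations on
#' the shape), so the observed-data log-likelihood is non-decreasing across
#' iterations. Initialisation is deterministic: values are split at the
#' median and each half fitted by the method of moments. The `seed` is used
#' only for jittered restarts when the EM collapses.
#'
#' Degenerate inputs (fewer than 20 values, essentially zero variance, or a
#' collapsed fit: mixing weight outside \[0.01, 0.99\] or a vanishing
#' component variance) yield a degenerate model whose posteriors are all
#' 0.5 — maximal uncertainty — rather than an error, so downstream pathway
#' scores stay defined.
#'
#' @param values vector of positive expression values (one gene, all
#'   samples).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param seed integer used for a jittered restart if the EM collapses;
#'   `NULL` disables restarts.
#' @param gene_id optional identifier stored in the model.
#' @return an object of class `gene_state_model` with elements
#'   `down_shape`, `down_scale`, `up_shape`, `up_scale`, `weight_up`,
#'   `degenerate`, `posteriors`, `loglik`, `loglik_trace`, `n_iter`.
#' @export
fit_gamma_mixture <- function(values, tol = 1e-6, max_iter = 500, seed = NULL,
                              gene_id = NA_character_) {
  if (any(!is.finite(values)) || any(values <= 0))
    stop("domain error: gamma mixture requires finite positive values")
  n <- length(values)
  if (n < 20L || stats::var(values) < 1e-8)
    return(degenerate_model(gene_id, values))

  fit <- em_gamma_mixture(values, init_posteriors_median(values), tol, max_iter)
  if (is.null(fit) && !is.null(seed)) {
    # one jittered restart: perturb the deterministic initial posteriors
    set.seed(as.integer(seed))
    r0 <- pmin(pmax(init_posteriors_median(values) +
                      stats::runif(n, -0.25, 0.25), 0.01), 0.99)
    fit <- em_gamma_mixture(values, r0, tol, max_iter)
  }
  if (is.null(fit)) return(degenerate_model(gene_id, values))

  # relabel so the larger-mean component is "up"
  mean_d <- fit$pd[1L] * fit$pd[2L]
  mean_u <- fit$pu[1L] * fit$pu[2L]
  if (mean_d > mean_u) {
    tmp <- fit$pd; fit$pd <- fit$pu; fit$pu <- tmp
    fit$w <- 1 - fit$w
    fit$post <- 1 - fit$post
  }
  structure(list(gene_id = gene_id,
                 down_shape = unname(fit$pd[1L]),
                 down_scale = unname(fit$pd[2L]),
                 up_shape = unname(fit$pu[1L]),
                 up_scale = unname(fit$pu[2L]),
                 weight_up = fit$w,
                 degenerate = FALSE,
                 posteriors = stats::setNames(fit$post, names(values)),
                 loglik = fit$ll,
                 loglik_trace = fit$trace,
                 n_iter = fit$iter),
            class = "gene_state_model")
}

degenerate_model <- function(gene_id, values) {
  structure(list(gene_id = gene_id,
                 down_shape = NA_real_, down_scale = NA_real_,
                 up_shape = NA_real_, up_scale = NA_real_,
                 weight_up = NA_real_, degenerate = TRUE,
                 posteriors = stats::setNames(rep(0.5, length(values)),
                                              names(values)),
                 loglik = NA_real_, loglik_trace = numeric(0), n_iter = 0L),
            class = "gene_state_model")
}

# deterministic initial responsibilities: above-median values start in "up"
init_posteriors_median <- function(values) {
  as.numeric(values > stats::median(values)) * 0.98 + 0.01
}

# EM core. Returns NULL on collapse (weight outside [eps, 1-eps] or a
# component variance underflow).
em_gamma_mixture <- function(x, r, tol, max_iter, eps = 0.01) {
  pu <- weighted_gamma_mle(x, r)
  pd <- weighted_gamma_mle(x, 1 - r)
  if (is.null(pu) || is.null(pd)) return(NULL)
  w <- mean(r)
  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    ld <- stats::dgamma(x, pd[1L], scale = pd[2L], log = TRUE) + log1p(-w)
    lu <- stats::dgamma(x, pu[1L], scale = pu[2L], log = TRUE) + log(w)
    mx <- pmax(ld, lu)
    s <- exp(ld - mx) + exp(lu - mx)
    ll <- sum(mx + log(s))
    if (!is.finite(ll)) return(NULL)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol * abs(ll_old)) break
    ll_old <- ll
    r <- exp(lu - mx) / s
    w <- mean(r)
    if (w < eps || w > 1 - eps) return(NULL)
    pu <- weighted_gamma_mle(x, r)
    pd <- weighted_gamma_mle(x, 1 - r)
    if (is.null(pu) || is.null(pd)) return(NULL)
  }
  list(pd = pd, pu = pu, w = w, post = r, ll = ll, trace = trace, iter = it)
}

# Weighted gamma MLE: Newton on log(k) - digamma(k) = log(wmean) - wmeanlog,
# initialised at the standard closed-form approximation. Returns NULL if the
# component collapses (negligible weight or vanishing variance).
weighted_gamma_mle <- function(x, w) {
  sw <- sum(w)
  if (sw < 1e-10) return(NULL)
  m <- sum(w * x) / sw
  ml <- sum(w * log(x)) / sw
  s <- log(m) - ml                      # >= 0 by Jensen's inequality
  if (!is.finite(s)) return(NULL)
  if (s < 1e-10) return(NULL)           # variance underflow: near-degenerate
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:30) {
    step <- (log(k) - digamma(k) - s) / (1 / k - trigamma(k))
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-12 * k) { k <- k_new; break }
    k <- k_new
  }
  c(shape = k, scale = m / k)
}

#' Posterior probability of the up state at a new value
#'
#' @param model a `gene_state_model`.
#' @param x positive expression value(s).
#' @return posterior P(up | x), clipped to \[1e-12, 1 - 1e-12\]. A
#'   degenerate model returns 0.5 with a warning.
#' @export
posterior_up <- function(model, x) {
  if (model$degenerate) {
    warning("degenerate model: returning posterior 0.5")
    return(rep(0.5, length(x)))
  }
  if (any(x <= 0)) stop("domain error: gamma support requires x > 0")
  lu <- stats::dgamma(x, model$up_shape, scale = model$up_scale, log = TRUE) +
    log(model$weight_up)
  ld <- stats::dgamma(x, model$down_shape, scale = model$down_scale,
                      log = TRUE) + log1p(-model$weight_up)
  mx <- pmax(lu, ld)
  p <- exp(lu - mx) / (exp(lu - mx) + exp(ld - mx))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Fit gamma-mixture state models for every gene of an expression matrix
#'
#' @param m expression matrix (genes x samples, positive values).
#' @param tol,max_iter,seed passed to [fit_gamma_mixture()]; each gene gets
#'   a distinct restart seed derived from `seed`.
#' @return a named list of `gene_state_model` objects (class
#'   `gene_state_models`); the number of degenerate fits is reported with a
#'   message and stored in the `"n_degenerate"` attribute.
#' @export
fit_all_genes <- function(m, tol = 1e-6, max_iter = 500, seed = 1L) {
  genes <- rownames(m)
  models <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    models[[i]] <- fit_gamma_mixture(m[i, ], tol = tol, max_iter = max_iter,
                                     seed = if (is.null(seed)) NULL
                                            else as.integer(seed) + i,
                                     gene_id = genes[i])
  }
  names(models) <- genes
  n_deg <- sum(vapply(models, function(mm) mm$degenerate, TRUE))
  if (n_deg > 0L) message(n_deg, " degenerate gene fit(s)")
  structure(models, class = "gene_state_models", n_degenerate = n_deg)
}

#' Matrix of per-sample up-state posteriors for a model collection
#' @param models a `gene_state_models` collection.
#' @return numeric matrix, genes x samples, entries in \[0, 1\].
#' @export
posterior_matrix <- function(models) {
  do.call(rbind, lapply(models, function(m) m$posteriors))
}

#' Serialize state models to a JSON parameter table
#' @param models a `gene_state_models` collection.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_state_models <- function(models, path) {
  tab <- do.call(rbind, lapply(models, function(m)
    data.frame(gene_id = m$gene_id, down_shape = m$down_shape,
               down_scale = m$down_scale, up_shape = m$up_shape,
               up_scale = m$up_scale, weight_up = m$weight_up,
               degenerate = m$degenerate, loglik = m$loglik,
               stringsAsFactors = FALSE)))
  jsonlite::write_json(tab, path, digits = NA, na = "null")
  invisible(path)
}

#' @export
print.gene_state_model <- function(x, ...) {
  if (x$degenerate) {
    cat("gene_state_model", x$gene_id, "(degenerate)\n")
  } else {
    cat(sprintf(
      "gene_state_model %s: down Gamma(%.3g, scale %.3g), up Gamma(%.3g, scale %.3g), w_up %.3f\n",
      x$gene_id, x$down_shape, x$down_scale, x$up_shape, x$up_scale,
      x$weight_up))
  }
  invisible(x)
}
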