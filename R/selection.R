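## Model comparison under path imputation. The deviance information
## criterion is the complete-data variant for missing-data models:
##   DIC = -4 E_{theta,mu}[log f(v | theta, mu)]
##         + 2 E_{mu}[log f(v | theta_bar, mu)],
## both expectations estimated from the stored joint draws of parameters and
## imputed paths; the plug-in theta_bar is the per-time posterior mean
## beta(t) (well-defined under a variable partition) together with the
## posterior mean sigma^2. The mean and plug-in deviances are exposed so
## alternative weightings can be recomputed.

## complete-data log-likelihood of one design context under a time-varying
## coefficient matrix beta_t (S x p) and variance sigma2
loglik_time_varying <- function(ctx, beta_t, sigma2) {
  mu <- rowSums(ctx$X * beta_t[ctx$step, , drop = FALSE])
  r <- ctx$y - mu
  n <- length(r)
  -0.5 * n * log(2 * pi * sigma2) - sum(r * r) / (2 * sigma2)
}

#' Data-augmented deviance information criterion
#'
#' @param object a `velm` fit (its stored per-iteration complete-data
#'   log-likelihoods and path bookkeeping are reused).
#' @return object of class `velm_dic`: list with `dic`, `mean_deviance`
#'   (`-2 E[log f]`), `plugin_deviance` (`-2 E_mu[log f at theta_bar]`) and
#'   `p_d` (= mean_deviance - plugin_deviance).
#' @export
dic <- function(object) {
  stopifnot(inherits(object, "velm"))
  mean_dev <- -2 * mean(object$loglik_draws)
  sigma2_bar <- mean(object$sigma2_draws)
  beta_bar <- object$beta_mean
  ## E_mu[.] weights each pooled path by how often the chain used it
  w <- tabulate(object$path_draws, nbins = length(object$contexts))
  used <- which(w > 0)
  plug <- vapply(used, function(m)
    loglik_time_varying(object$contexts[[m]], beta_bar, sigma2_bar), 0)
  plugin_dev <- -2 * sum(w[used] * plug) / sum(w)
  out <- list(dic = 2 * mean_dev - plugin_dev,
              mean_deviance = mean_dev, plugin_deviance = plugin_dev,
              p_d = mean_dev - plugin_dev)
  class(out) <- "velm_dic"
  out
}

#' @export
print.velm_dic <- function(x, ...) {
  cat(sprintf("DIC %.2f  (mean deviance %.2f, plug-in deviance %.2f, p_D %.2f)\n",
              x$dic, x$mean_deviance, x$plugin_deviance, x$p_d))
  invisible(x)
}

## free-parameter count of a K-segment model with p covariates: K coefficient
## vectors + (K-1) interior change points + one shared variance
k_free_params <- function(K, p) K * p + (K - 1L) + 1L

#' Fixed-K Bayesian information criterion
#'
#' `BIC = -2 log Lhat + k(K) log n` with `k(K) = K p + (K - 1) + 1` (segment
#' coefficient vectors, interior change points, shared variance) and
#' `n = 2 (T - 1)` stacked velocity components.
#'
#' @param loglik_hat maximized (complete-data) log-likelihood, or a `velm`
#'   fit, in which case the largest stored log-likelihood is used and `K`,
#'   `p`, `S` are taken from the fit.
#' @param K number of segments.
#' @param p number of covariates.
#' @param S number of velocity steps (`T - 1`).
#' @return scalar BIC (lower is better), with components as attributes.
#' @export
bic <- function(loglik_hat, K = NULL, p = NULL, S = NULL) {
  if (inherits(loglik_hat, "velm")) {
    fit <- loglik_hat
    if (is.null(K)) K <- if (fit$fixed_k) fit$K else
      as.integer(names(which.max(table(fit$K_draws))))
    p <- fit$p; S <- fit$S
    loglik_hat <- max(fit$loglik_draws)
  }
  k <- k_free_params(K, p)
  n <- 2L * S
  structure(-2 * loglik_hat + k * log(n),
            k = k, n = n, loglik = loglik_hat)
}

#' All-subsets covariate comparison by DIC
#'
#' Fits the (variable-K) velocity model once per nonempty covariate subset
#' and ranks the models by the data-augmented DIC, mirroring an all-subsets
#' table with inclusion indicators.
#'
#' @param track a [telemetry_track()], or `NULL` when `paths` is given.
#' @param fields named list of [gradient_field()]s (at most ~6: `2^p - 1`
#'   fits are run).
#' @param paths optional shared `imputed_paths` pool (recommended: all
#'   subsets then see identical path uncertainty).
#' @param prior,control,drift,seed passed to [velm()].
#' @param K passed to [velm()] (default `NULL`: variable K).
#' @return data.frame with one row per model: inclusion indicators, `dic`,
#'   `p_d`, ordered by DIC; attribute `fits` holds the fitted models.
#' @export
all_subsets <- function(track = NULL, fields, paths = NULL,
                        prior = velm_prior(), control = velm_control(),
                        drift = FALSE, K = NULL, seed = NULL) {
  p <- length(fields)
  if (p < 1L || p > 6L) stop("all_subsets supports 1..6 covariates, got ", p)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(paths)) {
    if (is.null(track)) stop("supply a track or an imputed path pool")
    cfit <- fit_ctcrw(track, fix_obs_sd = control$fix_obs_sd)
    paths <- draw_paths(track, cfit, dt = control$dt, M = control$M)
  }
  subsets <- lapply(seq_len(2^p - 1L), function(b) which(bitwAnd(b, 2^(seq_len(p) - 1L)) > 0))
  nm <- names(fields)
  rows <- vector("list", length(subsets))
  fits <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    sel <- subsets[[i]]
    fit <- velm(fields = fields[sel], K = K, paths = paths, prior = prior,
                control = control, drift = drift)
    d <- dic(fit)
    ind <- as.integer(seq_len(p) %in% sel)
    rows[[i]] <- data.frame(model = i, t(ind), dic = d$dic, p_d = d$p_d)
    fits[[i]] <- fit
  }
  out <- do.call(rbind, rows)
  names(out)[1L + seq_len(p)] <- nm
  o <- order(out$dic)
  out <- out[o, ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits[o]
  out
}
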