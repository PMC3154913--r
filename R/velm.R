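#' Sampler controls for [velm()]
#'
#' @param dt imputation grid spacing, hours.
#' @param M number of imputed path realizations in the composition pool.
#' @param iters total MCMC iterations.
#' @param burn burn-in iterations discarded (`iters > burn >= 0`).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param min_seg minimum segment length in grid steps (>= 2).
#' @param tau_window half-width (steps) of the change-point random-walk
#'   proposal.
#' @param c birth-distribution covariance tuning scalar.
#' @param lambda_b BDMCMC birth rate; defaults to the Poisson prior mean
#'   `lambda` (the standard convention).
#' @param T0 virtual time simulated per BDMCMC sweep.
#' @param K_max cap on the number of segments.
#' @param prelim_K fixed segment count of the preliminary fit that seeds the
#'   birth distribution.
#' @param prelim_iters,prelim_burn iterations for the preliminary fit.
#' @param fix_sigma2 optional: hold sigma^2 at this value (no Gibbs update).
#' @param fix_obs_sd optional: hold the CTCRW observation sd at this value
#'   when the track is imputed internally.
#' @return list of class `velm_control`.
#' @export
velm_control <- function(dt = 1, M = 30, iters = 3000, burn = 500, thin = 1,
                         min_seg = 5L, tau_window = 10L, c = 1,
                         lambda_b = NULL, T0 = 1, K_max = 50L,
                         prelim_K = 3L, prelim_iters = 800, prelim_burn = 200,
                         fix_sigma2 = NULL, fix_obs_sd = NULL) {
  if (dt <= 0) stop("dt must be > 0")
  if (iters <= burn || burn < 0) stop("need iters > burn >= 0")
  if (min_seg < 2L) stop("min_seg must be >= 2")
  structure(as.list(environment()), class = "velm_control")
}

#' Velocity-based movement model with behavioural change points
#'
#' Fits the gradient-driven velocity regression
#' \deqn{v_t \sim N(X(\mu_t)\,\beta_{k(t)},\ \sigma^2 I)}
#' where `v_t` is the animal's velocity at regular grid times, `X(mu_t)` the
#' 2 x p matrix of local covariate gradients (potential drivers of movement),
#' and the coefficients `beta` are piecewise constant over an unknown
#' partition of the trip. Uncertainty in the path itself is integrated out by
#' composition sampling over a pool of CTCRW path imputations. With `K`
#' supplied the partition size is fixed and the sampler is Gibbs
#' (beta, sigma^2) + Metropolis (tau); with `K = NULL` the number of segments
#' is random with a Poisson prior and is sampled by birth-death MCMC, the
#' birth distribution being built from a preliminary fixed-K fit.
#'
#' @param track a [telemetry_track()]; may be omitted when `paths` is given.
#' @param fields named list of [gradient_field()] covariates.
#' @param K fixed number of segments, or `NULL` (default) for variable K.
#' @param paths optional `imputed_paths` (or T x 2 matrix for a single known
#'   path); when omitted, a CTCRW is fitted to `track` and `control$M` paths
#'   are drawn at spacing `control$dt`.
#' @param prior a [velm_prior()].
#' @param control a [velm_control()].
#' @param drift add constant drift columns to the design?
#' @param birth optional pre-built [build_birth_distribution()]; skips the
#'   preliminary fit.
#' @param seed optional RNG seed (makes the whole fit reproducible).
#' @return object of class `velm`; see [summary.velm()], [coef.velm()],
#'   [plot.velm()], [dic()], [bic()].
#' @export
velm <- function(track = NULL, fields, K = NULL, paths = NULL,
                 prior = velm_prior(), control = velm_control(),
                 drift = FALSE, birth = NULL, seed = NULL) {
  cl <- match.call()
  if (!is.null(seed)) set.seed(seed)
  ## ---- path pool --------------------------------------------------------
  if (is.null(paths)) {
    if (is.null(track)) stop("supply a telemetry track or an imputed path set")
    cfit <- fit_ctcrw(track, fix_obs_sd = control$fix_obs_sd)
    paths <- draw_paths(track, cfit, dt = control$dt, M = control$M)
  } else if (is.matrix(paths) || is.data.frame(paths)) {
    paths <- structure(list(times = seq(0, by = control$dt,
                                        length.out = nrow(paths)),
                            dt = control$dt,
                            paths = array(as.matrix(paths),
                                          c(nrow(paths), 2L, 1L)),
                            M = 1L, params = NULL, seed = NULL,
                            track_id = NA_character_),
                       class = "imputed_paths")
  }
  stopifnot(inherits(paths, "imputed_paths"))
  M <- paths$M
  dt <- paths$dt
  ## ---- designs, one per pooled path -------------------------------------
  ctxs <- lapply(seq_len(M), function(m)
    build_design(paths$paths[, , m], dt, fields, drift = drift))
  S <- ctxs[[1L]]$S
  p <- ctxs[[1L]]$p
  covariates <- ctxs[[1L]]$covariates
  n_dropped <- vapply(ctxs, `[[`, 0L, "n_dropped")
  min_seg <- as.integer(control$min_seg)
  fixed_k <- !is.null(K)
  if (fixed_k) {
    K <- as.integer(K)
    if (K * min_seg > S)
      stop("infeasible K: ", K, " segments of >= ", min_seg,
           " steps do not fit in ", S, " steps")
  }
  lambda_b <- if (is.null(control$lambda_b)) prior$lambda else control$lambda_b
  ## ---- birth distribution (variable K only) -----------------------------
  if (!fixed_k && is.null(birth)) {
    pk <- min(control$prelim_K, S %/% min_seg)
    pc <- control
    pc$iters <- control$prelim_iters
    pc$burn <- control$prelim_burn
    prelim <- velm(fields = fields, K = max(pk, 1L), paths = paths,
                   prior = prior, control = pc, drift = drift)
    birth <- build_birth_distribution(prelim, c = control$c)
  }
  ## ---- initial state ----------------------------------------------------
  K0 <- if (fixed_k) K else 1L
  tau0 <- if (K0 == 1L) 1L else as.integer(round(seq(1, S + 1, length.out = K0 + 1L)))[-(K0 + 1L)]
  sigma2_0 <- if (!is.null(control$fix_sigma2)) control$fix_sigma2
              else sigma2_prior_mean(prior)
  state <- new_state(tau0, matrix(rep_len(prior_beta_mean(prior, p), p * K0),
                                  K0, p, byrow = TRUE), sigma2_0)
  if (!state_valid(state, S, min_seg))
    stop("infeasible initial partition (check K and min_seg)")
  ## ---- main loop --------------------------------------------------------
  iters <- control$iters; burn <- control$burn; thin <- max(1L, control$thin)
  save_idx <- seq(burn + 1L, iters, by = thin)
  n_save <- length(save_idx)
  K_draws <- integer(n_save)
  sigma2_draws <- numeric(n_save)
  loglik_draws <- numeric(n_save)
  path_draws <- integer(n_save)
  tau_draws <- vector("list", n_save)
  beta_seg_draws <- vector("list", n_save)
  beta_draws <- array(NA_real_, c(n_save, S, p))
  fitted_sum <- matrix(0, S, 2L); fitted_n <- numeric(S)
  vel_sum <- matrix(0, S, 2L)
  si <- 0L
  for (it in seq_len(iters)) {
    m <- if (M > 1L) sample.int(M, 1L) else 1L
    ctx <- ctxs[[m]]
    if (!fixed_k)
      state <- bdmcmc_sweep(state, ctx, birth, prior, lambda_b,
                            T0 = control$T0, min_seg = min_seg,
                            K_max = control$K_max)
    if (is.null(control$fix_sigma2))
      state <- gibbs_update_sigma2(state, ctx, prior)
    state <- gibbs_update_beta(state, ctx, prior)
    state <- mh_update_tau(state, ctx, min_seg, window = control$tau_window)
    if (it > burn && ((it - burn - 1L) %% thin == 0L)) {
      si <- si + 1L
      K_draws[si] <- length(state$tau)
      sigma2_draws[si] <- state$sigma2
      loglik_draws[si] <- state_loglik(state, ctx)
      path_draws[si] <- m
      tau_draws[[si]] <- state$tau
      beta_seg_draws[[si]] <- state$beta
      seg <- seg_of_step(state$tau, S)
      bt <- state$beta[seg, , drop = FALSE]
      beta_draws[si, , ] <- bt
      ks <- which(ctx$keep)
      nk <- length(ks)
      mu_x <- rowSums(ctx$X[seq_len(nk), , drop = FALSE] * bt[ks, , drop = FALSE])
      mu_y <- rowSums(ctx$X[nk + seq_len(nk), , drop = FALSE] * bt[ks, , drop = FALSE])
      fitted_sum[ks, 1L] <- fitted_sum[ks, 1L] + mu_x
      fitted_sum[ks, 2L] <- fitted_sum[ks, 2L] + mu_y
      vel_sum[ks, 1L] <- vel_sum[ks, 1L] + ctx$y[seq_len(nk)]
      vel_sum[ks, 2L] <- vel_sum[ks, 2L] + ctx$y[nk + seq_len(nk)]
      fitted_n[ks] <- fitted_n[ks] + 1
    }
  }
  beta_mean <- apply(beta_draws, c(2L, 3L), mean)
  beta_sd <- apply(beta_draws, c(2L, 3L), stats::sd)
  beta_lo <- apply(beta_draws, c(2L, 3L), stats::quantile, probs = 0.025, names = FALSE)
  beta_hi <- apply(beta_draws, c(2L, 3L), stats::quantile, probs = 0.975, names = FALSE)
  colnames(beta_mean) <- colnames(beta_sd) <- colnames(beta_lo) <-
    colnames(beta_hi) <- covariates
  fn <- pmax(fitted_n, 1)
  structure(list(
    call = cl, fixed_k = fixed_k, K = if (fixed_k) K else NA_integer_,
    covariates = covariates, p = p, S = S, dt = dt,
    times = paths$times[-length(paths$times)],
    K_draws = K_draws, sigma2_draws = sigma2_draws,
    loglik_draws = loglik_draws, path_draws = path_draws,
    tau_draws = tau_draws, beta_seg_draws = beta_seg_draws,
    beta_draws = beta_draws,
    beta_mean = beta_mean, beta_sd = beta_sd,
    beta_lo = beta_lo, beta_hi = beta_hi,
    fitted_vel = fitted_sum / fn, obs_vel = vel_sum / fn,
    fitted_n = fitted_n,
    paths = paths, contexts = ctxs, n_dropped = n_dropped,
    prior = prior, control = control, drift = drift,
    birth = birth, lambda_b = lambda_b,
    track_id = paths$track_id), class = "velm")
}

#' @export
print.velm <- function(x, ...) {
  cat("Velocity-based movement model",
      if (x$fixed_k) paste0("(fixed K = ", x$K, ")") else "(variable K, BDMCMC)", "\n")
  cat("  ", x$S, " grid steps of ", x$dt, " h; covariates: ",
      paste(x$covariates, collapse = ", "), "\n", sep = "")
  cat("  ", length(x$K_draws), " stored draws over ", x$paths$M,
      " imputed paths\n", sep = "")
  if (!x$fixed_k) {
    tb <- table(x$K_draws)
    cat("  posterior mode of segment count: ", names(tb)[which.max(tb)], "\n", sep = "")
  }
  cat(sprintf("  posterior mean sigma^2: %.4g (km/h)^2\n", mean(x$sigma2_draws)))
  invisible(x)
}

#' Summary of a fitted velocity movement model
#' @param object a `velm` fit.
#' @param ... unused.
#' @export
summary.velm <- function(object, ...) {
  out <- list(
    fixed_k = object$fixed_k, K = object$K,
    K_table = table(object$K_draws) / length(object$K_draws),
    sigma2 = c(mean = mean(object$sigma2_draws),
               sd = stats::sd(object$sigma2_draws)),
    beta_range = apply(object$beta_mean, 2L, range),
    covariates = object$covariates,
    n_draws = length(object$K_draws),
    dropped = sum(object$n_dropped))
  class(out) <- "summary.velm"
  out
}

#' @export
print.summary.velm <- function(x, ...) {
  cat("Segment count posterior:\n")
  print(round(x$K_table, 3))
  cat(sprintf("sigma^2: %.4g (sd %.3g)\n", x$sigma2["mean"], x$sigma2["sd"]))
  cat("Range of posterior-mean beta(t) per covariate:\n")
  print(round(x$beta_range, 4))
  if (x$dropped > 0)
    cat(x$dropped, "step evaluations dropped outside raster extent\n")
  invisible(x)
}

#' Posterior mean time-varying coefficients
#'
#' @param object a `velm` fit.
#' @param ... unused.
#' @return S x p matrix: posterior mean of `beta(t)` per grid step.
#' @export
coef.velm <- function(object, ...) object$beta_mean

#' @export
fitted.velm <- function(object, ...) object$fitted_vel

#' Velocity residuals at the posterior mean
#'
#' Observed (imputation-averaged) minus fitted mean velocity, per grid step
#' and axis, in km/h.
#' @param object a `velm` fit.
#' @param ... unused.
#' @export
residuals.velm <- function(object, ...) object$obs_vel - object$fitted_vel

#' @export
logLik.velm <- function(object, ...) {
  Kmode <- if (object$fixed_k) object$K else
    as.integer(names(which.max(table(object$K_draws))))
  df <- Kmode * object$p + (Kmode - 1L) + 1L
  structure(max(object$loglik_draws), df = df, nobs = 2L * object$S,
            class = "logLik")
}

#' Plot posterior time-varying coefficients
#'
#' One panel per covariate: posterior mean of `beta(t)` with the 95%
#' credible band.
#' @param x a `velm` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.velm <- function(x, ...) {
  p <- x$p
  old <- graphics::par(mfrow = c(p, 1L), mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  tt <- x$times
  for (j in seq_len(p)) {
    ylim <- range(x$beta_lo[, j], x$beta_hi[, j])
    graphics::plot(tt, x$beta_mean[, j], type = "l", ylim = ylim,
                   xlab = "time (h)", ylab = x$covariates[j], ...)
    graphics::polygon(c(tt, rev(tt)), c(x$beta_lo[, j], rev(x$beta_hi[, j])),
                      col = grDevices::adjustcolor("steelblue", 0.25), border = NA)
    graphics::lines(tt, x$beta_mean[, j], lwd = 1.5)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}

## Monte-Carlo standard error by batch means
mcse <- function(x, n_batch = 25L) {
  n <- length(x)
  n_batch <- max(2L, min(n_batch, n %/% 2L))
  bs <- n %/% n_batch
  bm <- colMeans(matrix(x[seq_len(bs * n_batch)], bs, n_batch))
  stats::sd(bm) / sqrt(n_batch)
}

#' Monte-Carlo standard errors of the posterior-mean beta(t)
#'
#' Batch-means standard error of the chain mean, per grid step and covariate.
#' @param object a `velm` fit.
#' @param n_batch number of batches.
#' @return S x p matrix of MC standard errors.
#' @export
velm_mcse <- function(object, n_batch = 25L) {
  S <- object$S; p <- object$p
  out <- matrix(0, S, p, dimnames = list(NULL, object$covariates))
  for (j in seq_len(p))
    out[, j] <- apply(object$beta_draws[, , j, drop = FALSE], 2L, mcse,
                      n_batch = n_batch)
  out
}

#' Write MCMC chains as a long-format table
#'
#' One row per (iteration, segment): columns `iteration`, `segment`, `tau`,
#' `beta_<covariate>` ..., `sigma2`, `K`. Round-trips through
#' [read_chains()].
#' @param object a `velm` fit.
#' @param path output CSV path.
#' @export
write_chains <- function(object, path) {
  stopifnot(inherits(object, "velm"))
  n <- length(object$K_draws)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    B <- object$beta_seg_draws[[i]]
    rows[[i]] <- data.frame(iteration = i,
                            segment = seq_along(object$tau_draws[[i]]),
                            tau = object$tau_draws[[i]],
                            B,
                            sigma2 = object$sigma2_draws[i],
                            K = object$K_draws[i])
  }
  df <- do.call(rbind, rows)
  names(df)[4:(3 + object$p)] <- paste0("beta_", object$covariates)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a chain table written by [write_chains()]
#' @param path CSV path.
#' @return data.frame in the long chain format.
#' @export
read_chains <- function(path) utils::read.csv(path)
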