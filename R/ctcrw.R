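## Continuous-time correlated random walk (integrated Ornstein-Uhlenbeck
## velocity) for irregular telemetry. Per axis the state is (position,
## velocity); the velocity is OU with decay ou_decay (1/h) and volatility
## ou_scale; position integrates velocity. The two axes are independent and
## share parameters; location error is isotropic Gaussian with sd obs_sd (km),
## optionally scaled per error class. Transitions between arbitrary time gaps
## use the exact discretization, never Euler steps.

#' CTCRW parameter set
#'
#' @param ou_decay velocity autocorrelation decay, 1/h (> 0).
#' @param ou_scale velocity volatility (km/h per sqrt h, > 0).
#' @param obs_sd isotropic location-error standard deviation, km (>= 0).
#' @param class_scale optional named vector of per-error-class multipliers of
#'   `obs_sd`.
#' @return object of class `ctcrw_params`.
#' @export
ctcrw_params <- function(ou_decay, ou_scale, obs_sd, class_scale = NULL) {
  if (!is.finite(ou_decay) || ou_decay <= 0) stop("ou_decay must be finite and > 0")
  if (!is.finite(ou_scale) || ou_scale <= 0) stop("ou_scale must be finite and > 0")
  if (!is.finite(obs_sd) || obs_sd < 0) stop("obs_sd must be finite and >= 0")
  structure(list(ou_decay = ou_decay, ou_scale = ou_scale, obs_sd = obs_sd,
                 class_scale = class_scale), class = "ctcrw_params")
}

## Exact integrated-OU transition over gap dt: returns 2x2 Phi and Q.
ctcrw_transition <- function(theta, sigma, dt) {
  phi <- exp(-theta * dt)
  a <- -expm1(-theta * dt) / theta       # (1 - e^{-theta dt}) / theta
  Phi <- matrix(c(1, 0, a, phi), 2, 2)
  s2 <- sigma^2
  q11 <- (s2 / theta^2) * (dt - 2 * a + (1 - phi^2) / (2 * theta))
  q12 <- (s2 / (2 * theta^2)) * (1 - phi)^2
  q22 <- (s2 / (2 * theta)) * (1 - phi^2)
  Q <- matrix(c(q11, q12, q12, q22), 2, 2)
  list(Phi = Phi, Q = Q)
}

## diffuse initial position variance (km^2); velocity starts at its
## stationary distribution N(0, sigma^2 / (2 theta))
.ctcrw_pos_var0 <- 1e4

ctcrw_init <- function(theta, sigma, pos0) {
  list(m = c(pos0, 0), P = diag(c(.ctcrw_pos_var0, sigma^2 / (2 * theta))))
}

ctcrw_obs_var <- function(params, track) {
  n <- length(track$times)
  mult <- rep(1, n)
  if (!is.null(params$class_scale) && !is.null(track$error_class)) {
    m <- params$class_scale[track$error_class]
    mult[!is.na(m)] <- m[!is.na(m)]
  }
  (params$obs_sd * mult)^2
}

## Kalman filter for one axis over the fix times only; returns loglik and,
## if keep = TRUE, the filtered moments needed by the smoother/sampler.
ctcrw_filter_axis <- function(obs, times, theta, sigma, rvec, keep = FALSE) {
  n <- length(obs)
  init <- ctcrw_init(theta, sigma, obs[1L])
  m <- init$m; P <- init$P
  ll <- 0
  if (keep) {
    mf <- matrix(0, 2, n); Pf <- array(0, c(2, 2, n))
  }
  for (i in seq_len(n)) {
    if (i > 1L) {
      tr <- ctcrw_transition(theta, sigma, times[i] - times[i - 1L])
      m <- drop(tr$Phi %*% m)
      P <- tr$Phi %*% P %*% t(tr$Phi) + tr$Q
    }
    S <- P[1, 1] + rvec[i]
    if (!is.finite(S) || S <= 0)       # numerically infeasible parameters
      return(list(loglik = -Inf))
    innov <- obs[i] - m[1L]
    ll <- ll + stats::dnorm(innov, 0, sqrt(S), log = TRUE)
    K <- P[, 1] / S
    m <- m + K * innov
    P <- P - tcrossprod(K, P[1, ])
    P <- (P + t(P)) / 2
    if (keep) { mf[, i] <- m; Pf[, , i] <- P }
  }
  if (keep) list(loglik = ll, mf = mf, Pf = Pf) else list(loglik = ll)
}

#' Exact CTCRW marginal log-likelihood of a telemetry track
#'
#' Gaussian marginal log-likelihood of the observed fixes under the integrated
#' Ornstein-Uhlenbeck state-space model, computed by Kalman filtering with the
#' exact transition moments between the (irregular) fix times. The two
#' coordinate axes are independent with shared parameters. The initial state
#' is a diffuse position prior centred on the first fix and the stationary
#' zero-mean velocity distribution.
#'
#' @param track a [telemetry_track()].
#' @param params a [ctcrw_params()].
#' @return scalar log-likelihood.
#' @export
ctcrw_loglik <- function(track, params) {
  stopifnot(inherits(track, "telemetry_track"), inherits(params, "ctcrw_params"))
  if (length(track$times) < 2L) stop("need at least 2 fixes")
  rvec <- ctcrw_obs_var(params, track)
  ctcrw_filter_axis(track$x, track$times, params$ou_decay, params$ou_scale, rvec)$loglik +
    ctcrw_filter_axis(track$y, track$times, params$ou_decay, params$ou_scale, rvec)$loglik
}

#' Fit the CTCRW to a telemetry track by maximum likelihood
#'
#' Maximizes [ctcrw_loglik()] over log-transformed parameters from a fixed set
#' of five starting points (the likelihood can be multimodal in decay/scale),
#' using L-BFGS-B on the log scale. Asymptotic standard errors on the log
#' scale are taken from the numerical Hessian at the optimum.
#'
#' @param track a [telemetry_track()] with at least 4 fixes (>= 10 recommended).
#' @param fix_obs_sd optional: if supplied, the observation-error sd is held
#'   at this value instead of being estimated.
#' @return object of class `ctcrw_fit` with elements `params`, `loglik`,
#'   `log_se` (named se's of the log-parameters), `convergence`.
#' @export
fit_ctcrw <- function(track, fix_obs_sd = NULL) {
  stopifnot(inherits(track, "telemetry_track"))
  n <- length(track$times)
  if (n < 4L) stop("need at least 4 fixes to fit the CTCRW, got ", n)
  est_obs <- is.null(fix_obs_sd)
  ## crude data scales to seed the starts
  dt_med <- stats::median(diff(track$times))
  sp <- sqrt(diff(track$x)^2 + diff(track$y)^2) / diff(track$times)
  v_scale <- max(stats::median(sp), 1e-3)
  starts <- list(
    c(log(1 / (4 * dt_med)), log(v_scale), log(0.1 * v_scale * dt_med)),
    c(log(1), log(1), log(0.1)),
    c(log(0.1), log(v_scale), log(v_scale * dt_med)),
    c(log(2), log(0.3 * v_scale), log(0.02 * v_scale * dt_med)),
    c(log(0.02), log(3 * v_scale), log(0.5)))
  nll <- function(p) {
    theta <- exp(p[1L]); sigma <- exp(p[2L])
    os <- if (est_obs) exp(p[3L]) else fix_obs_sd
    pr <- ctcrw_params(theta, sigma, os)
    rvec <- ctcrw_obs_var(pr, track)
    ll <- ctcrw_filter_axis(track$x, track$times, theta, sigma, rvec)$loglik +
      ctcrw_filter_axis(track$y, track$times, theta, sigma, rvec)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  np <- if (est_obs) 3L else 2L
  best <- NULL
  for (s in starts) {
    p0 <- s[seq_len(np)]
    fit <- tryCatch(
      stats::optim(p0, nll, method = "L-BFGS-B",
                   lower = rep(-12, np), upper = rep(8, np),
                   control = list(maxit = 400)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("CTCRW fit failed from all starts")
  p <- best$par
  H <- tryCatch(stats::optimHess(p, nll), error = function(e) NULL)
  log_se <- rep(NA_real_, np)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)
      log_se <- ifelse(dv > 0, sqrt(dv), NA_real_)
    }
  }
  names(log_se) <- c("log_ou_decay", "log_ou_scale", "log_obs_sd")[seq_len(np)]
  params <- ctcrw_params(exp(p[1L]), exp(p[2L]),
                         if (est_obs) exp(p[3L]) else fix_obs_sd)
  structure(list(params = params, loglik = -best$value, log_se = log_se,
                 convergence = best$convergence, n_fixes = n, track_id = track$id),
            class = "ctcrw_fit")
}

#' @export
print.ctcrw_fit <- function(x, ...) {
  cat("CTCRW fit (", x$n_fixes, " fixes, track '", x$track_id, "')\n", sep = "")
  cat(sprintf("  ou_decay = %.4g /h, ou_scale = %.4g, obs_sd = %.4g km\n",
              x$params$ou_decay, x$params$ou_scale, x$params$obs_sd))
  cat(sprintf("  log-likelihood %.3f, convergence code %d\n", x$loglik, x$convergence))
  invisible(x)
}

#' @export
coef.ctcrw_fit <- function(object, ...) {
  c(ou_decay = object$params$ou_decay, ou_scale = object$params$ou_scale,
    obs_sd = object$params$obs_sd)
}

#' @export
logLik.ctcrw_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$log_se), class = "logLik")
}

## union of grid and fix times for smoothing/sampling; obs_idx[i] = fix index
## observed at union time i, or NA
ctcrw_union_times <- function(track, grid) {
  tt <- sort(unique(c(grid, track$times)))
  ## merge near-duplicates (grid times numerically equal to fix times)
  keep <- c(TRUE, diff(tt) > 1e-9)
  tt <- tt[keep]
  obs_idx <- rep(NA_integer_, length(tt))
  fi <- findInterval(track$times, tt + 1e-9) + 1L
  fi <- pmin(pmax(fi, 1L), length(tt))
  for (k in seq_along(track$times)) {
    j <- which.min(abs(tt - track$times[k]))
    if (abs(tt[j] - track$times[k]) < 1e-8) obs_idx[j] <- k
  }
  grid_idx <- vapply(grid, function(g) which.min(abs(tt - g)), integer(1))
  list(times = tt, obs_idx = obs_idx, grid_idx = grid_idx)
}

## filter over union times for one axis, keeping filtered moments and
## transitions; obs contributes an update only where obs_idx is set
ctcrw_filter_union <- function(obs, rvec, un, theta, sigma) {
  tt <- un$times; n <- length(tt)
  init <- ctcrw_init(theta, sigma, obs[1L])
  m <- init$m; P <- init$P
  mf <- matrix(0, 2, n); Pf <- array(0, c(2, 2, n))
  Phis <- array(0, c(2, 2, n)); Qs <- array(0, c(2, 2, n))
  for (i in seq_len(n)) {
    if (i > 1L) {
      tr <- ctcrw_transition(theta, sigma, tt[i] - tt[i - 1L])
      Phis[, , i] <- tr$Phi; Qs[, , i] <- tr$Q
      m <- drop(tr$Phi %*% m)
      P <- tr$Phi %*% P %*% t(tr$Phi) + tr$Q
    }
    k <- un$obs_idx[i]
    if (!is.na(k)) {
      S <- P[1, 1] + rvec[k]
      K <- P[, 1] / S
      m <- m + K * (obs[k] - m[1L])
      P <- P - tcrossprod(K, P[1, ])
      P <- (P + t(P)) / 2
    }
    mf[, i] <- m; Pf[, , i] <- P
  }
  list(mf = mf, Pf = Pf, Phis = Phis, Qs = Qs)
}

## square root of a symmetric 2x2 PSD matrix, tolerant of tiny negative
## eigenvalues from degenerate (noiseless) updates
psd_sqrt2 <- function(C) {
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}

## backward sampling of M joint state draws for one axis
ctcrw_ffbs_axis <- function(flt, M) {
  n <- dim(flt$mf)[2L]
  Z <- array(0, c(2, M, n))
  A <- psd_sqrt2(flt$Pf[, , n])
  Z[, , n] <- flt$mf[, n] + A %*% matrix(stats::rnorm(2 * M), 2, M)
  for (i in seq(n - 1L, 1L)) {
    Phi <- flt$Phis[, , i + 1L]; Q <- flt$Qs[, , i + 1L]
    P <- flt$Pf[, , i]; m <- flt$mf[, i]
    S <- Phi %*% P %*% t(Phi) + Q
    J <- tryCatch(t(solve(S, Phi %*% P)), error = function(e) P %*% t(Phi) %*% MASS_ginv2(S))
    C <- P - J %*% Phi %*% P
    A <- psd_sqrt2(C)
    pm <- drop(Phi %*% m)
    Z[, , i] <- (m - drop(J %*% pm)) + J %*% Z[, , i + 1L] +
      A %*% matrix(stats::rnorm(2 * M), 2, M)
  }
  Z
}

## tiny pseudo-inverse fallback for degenerate 2x2 systems
MASS_ginv2 <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- ifelse(e$values > 1e-12 * max(abs(e$values), 1e-300), 1 / e$values, 0)
  e$vectors %*% (lam * t(e$vectors))
}

#' Draw posterior-predictive path realizations on a regular grid
#'
#' Composition-sampling workhorse: draws `M` independent joint realizations of
#' the location process at regular grid times, conditional on the telemetry
#' fixes, by forward filtering over the union of fix and grid times followed
#' by backward sampling. With `obs_sd = 0` every draw interpolates the fixes
#' exactly at fix times.
#'
#' @param track a [telemetry_track()].
#' @param params a [ctcrw_params()] or `ctcrw_fit`.
#' @param dt grid spacing in hours (> 0, smaller than the track span).
#' @param M number of path realizations (>= 1).
#' @param seed optional RNG seed.
#' @return object of class `imputed_paths`: list with `times` (grid),
#'   `paths` (array T x 2 x M of locations, km), `params`, `seed`.
#' @export
draw_paths <- function(track, params, dt, M, seed = NULL) {
  stopifnot(inherits(track, "telemetry_track"))
  if (inherits(params, "ctcrw_fit")) params <- params$params
  stopifnot(inherits(params, "ctcrw_params"))
  if (dt <= 0) stop("dt must be > 0")
  if (M < 1) stop("M must be >= 1")
  span <- diff(range(track$times))
  if (dt > span) stop("grid spacing dt (", dt, ") exceeds the track span (", span, " h)")
  if (!is.null(seed)) set.seed(seed)
  ngrid <- floor(span / dt + 1e-9)
  grid <- track$times[1L] + dt * (0:ngrid)
  un <- ctcrw_union_times(track, grid)
  rvec <- ctcrw_obs_var(params, track)
  out <- array(0, c(length(grid), 2L, M))
  for (ax in 1:2) {
    obs <- if (ax == 1L) track$x else track$y
    flt <- ctcrw_filter_union(obs, rvec, un, params$ou_decay, params$ou_scale)
    Z <- ctcrw_ffbs_axis(flt, M)
    out[, ax, ] <- t(Z[1L, , un$grid_idx])
  }
  if (!all(is.finite(out))) stop("non-finite draw in path imputation")
  structure(list(times = grid, dt = dt, paths = out, M = M,
                 params = params, seed = seed, track_id = track$id),
            class = "imputed_paths")
}

#' @export
print.imputed_paths <- function(x, ...) {
  cat("Imputed path set: ", x$M, " realizations on ", length(x$times),
      " grid times (dt = ", x$dt, " h)\n", sep = "")
  invisible(x)
}

#' Kalman smoother moments of the CTCRW at given times
#'
#' Rauch-Tung-Striebel smoother means and variances of position (per axis) at
#' the supplied times, conditional on the fixes. Used for uncertainty bands
#' and as the analytic reference for the path-sampler moments.
#'
#' @inheritParams draw_paths
#' @param at numeric vector of times at which moments are wanted.
#' @return data.frame with columns time, mean_x, mean_y, var_x, var_y.
#' @export
ctcrw_smoother <- function(track, params, at) {
  if (inherits(params, "ctcrw_fit")) params <- params$params
  un <- ctcrw_union_times(track, at)
  rvec <- ctcrw_obs_var(params, track)
  res <- list()
  for (ax in 1:2) {
    obs <- if (ax == 1L) track$x else track$y
    flt <- ctcrw_filter_union(obs, rvec, un, params$ou_decay, params$ou_scale)
    n <- length(un$times)
    ms <- flt$mf; Ps <- flt$Pf
    for (i in seq(n - 1L, 1L)) {
      Phi <- flt$Phis[, , i + 1L]; Q <- flt$Qs[, , i + 1L]
      P <- flt$Pf[, , i]; m <- flt$mf[, i]
      S <- Phi %*% P %*% t(Phi) + Q
      J <- tryCatch(t(solve(S, Phi %*% P)), error = function(e) P %*% t(Phi) %*% MASS_ginv2(S))
      ms[, i] <- m + drop(J %*% (ms[, i + 1L] - Phi %*% m))
      Ps[, , i] <- P + J %*% (Ps[, , i + 1L] - S) %*% t(J)
    }
    res[[ax]] <- list(mean = ms[1L, un$grid_idx], var = pmax(Ps[1L, 1L, un$grid_idx], 0))
  }
  data.frame(time = un$times[un$grid_idx],
             mean_x = res[[1]]$mean, mean_y = res[[2]]$mean,
             var_x = res[[1]]$var, var_y = res[[2]]$var)
}

#' Write imputed paths as a long-format CSV
#'
#' Columns: realization, time, x, y.
#' @param paths an `imputed_paths` object.
#' @param path output file.
#' @export
write_paths <- function(paths, path) {
  stopifnot(inherits(paths, "imputed_paths"))
  Tn <- length(paths$times)
  df <- data.frame(
    realization = rep(seq_len(paths$M), each = Tn),
    time = rep(paths$times, paths$M),
    x = as.vector(paths$paths[, 1L, ]),
    y = as.vector(paths$paths[, 2L, ]))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read imputed paths written by [write_paths()]
#' @param path input CSV.
#' @param dt grid spacing (recovered from the file if omitted).
#' @return an `imputed_paths` object (without provenance parameters).
#' @export
read_paths <- function(path, dt = NULL) {
  df <- utils::read.csv(path)
  reals <- sort(unique(df$realization))
  tt <- sort(unique(df$time))
  if (is.null(dt)) dt <- stats::median(diff(tt))
  arr <- array(0, c(length(tt), 2L, length(reals)))
  for (m in seq_along(reals)) {
    sub <- df[df$realization == reals[m], ]
    sub <- sub[order(sub$time), ]
    arr[, 1L, m] <- sub$x; arr[, 2L, m] <- sub$y
  }
  structure(list(times = tt, dt = dt, paths = arr, M = length(reals),
                 params = NULL, seed = NULL, track_id = NA_character_),
            class = "imputed_paths")
}
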