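## Core change-point velocity regression machinery: velocity transform,
## stacked univariate design, partition states, Gaussian likelihood, and the
## conjugate Gibbs / Metropolis-Hastings updates. The bivariate velocity
## model v_t ~ N(X(mu_t) beta_seg(t), sigma^2 I) is rewritten in univariate
## form by stacking the x-components of all steps above the y-components;
## both components of a step always share one segment.

#' Velocity series from a regular-grid path
#'
#' First-differences a path on a regular grid into velocity vectors in km/h:
#' `v_t = (mu_{t+1} - mu_t) / dt`. The transform is invertible given the
#' start location, so no information is lost.
#'
#' @param path T x 2 matrix of locations (km) at regular times.
#' @param dt grid spacing in hours.
#' @return (T-1) x 2 matrix of velocities.
#' @export
path_to_velocity <- function(path, dt) {
  path <- as.matrix(path)
  if (nrow(path) < 2L) stop("need at least 2 path locations")
  if (dt <= 0) stop("dt must be > 0")
  diff(path) / dt
}

#' Invert [path_to_velocity()]
#' @param start length-2 start location.
#' @param vel (T-1) x 2 velocity matrix (km/h).
#' @param dt grid spacing (hours).
#' @return T x 2 path matrix.
#' @export
velocity_to_path <- function(start, vel, dt) {
  rbind(matrix(start, 1L), matrix(start, nrow(vel), 2L, byrow = TRUE) +
          apply(vel * dt, 2L, cumsum))
}

#' Stacked univariate regression for one path realization
#'
#' Evaluates the covariate gradient fields along the path (at the start
#' location of each step), first-differences the path into velocities, and
#' stacks the x-components of all steps above the y-components into a single
#' univariate regression: response length `2 S`, design `2 S x p` whose rows
#' carry the matching gradient components. With `drift = TRUE` two extra
#' columns model a constant drift: `(1, 0)` on x-rows and `(0, 1)` on y-rows.
#' Steps whose location falls outside any gradient field's extent are dropped
#' (both components) and counted.
#'
#' @param path T x 2 location matrix on a regular grid.
#' @param dt grid spacing, hours.
#' @param fields named list of [gradient_field()]s (the covariates).
#' @param drift add constant drift columns?
#' @return list with `y` (2 S' vector), `X` (2 S' x p design), `step`
#'   (step index of each row), `axis` (1 = x row, 2 = y row), `S` (total grid
#'   steps), `keep` (logical over the S steps), `n_dropped`, `covariates`.
#' @export
build_design <- function(path, dt, fields, drift = FALSE) {
  path <- as.matrix(path)
  S <- nrow(path) - 1L
  if (S < 1L) stop("path too short")
  vel <- path_to_velocity(path, dt)
  loc <- path[seq_len(S), , drop = FALSE]
  p <- length(fields)
  if (p < 1L) stop("at least one covariate gradient field is required")
  nm <- names(fields)
  if (is.null(nm) || any(nm == "")) nm <- paste0("cov", seq_len(p))
  Gx <- matrix(NA_real_, S, p); Gy <- matrix(NA_real_, S, p)
  for (j in seq_len(p)) {
    g <- eval_gradient(fields[[j]], loc, na_outside = TRUE)
    Gx[, j] <- g[, 1L]; Gy[, j] <- g[, 2L]
  }
  keep <- stats::complete.cases(Gx) & stats::complete.cases(Gy) &
    stats::complete.cases(vel)
  n_dropped <- sum(!keep)
  ks <- which(keep)
  Xx <- Gx[ks, , drop = FALSE]; Xy <- Gy[ks, , drop = FALSE]
  if (drift) {
    Xx <- cbind(Xx, 1, 0); Xy <- cbind(Xy, 0, 1)
    nm <- c(nm, "drift_x", "drift_y")
  }
  list(y = c(vel[ks, 1L], vel[ks, 2L]),
       X = rbind(Xx, Xy),
       step = c(ks, ks),
       axis = rep(1:2, each = length(ks)),
       S = S, keep = keep, n_dropped = n_dropped,
       covariates = nm, p = ncol(Xx))
}

## ---- partition states -------------------------------------------------

## A partition state is list(tau, beta, sigma2): tau = integer segment start
## steps with tau[1] == 1, strictly increasing on 1..S; beta = K x p matrix;
## sigma2 > 0 shared by all segments and both axes.

new_state <- function(tau, beta, sigma2) {
  list(tau = as.integer(tau), beta = rbind(beta), sigma2 = sigma2)
}

## segment id per step 1..S
seg_of_step <- function(tau, S) {
  K <- length(tau)
  rep.int(seq_len(K), diff(c(tau, S + 1L)))
}

state_valid <- function(state, S, min_seg) {
  tau <- state$tau
  K <- length(tau)
  if (tau[1L] != 1L) return(FALSE)
  if (K > 1L && any(diff(tau) < min_seg)) return(FALSE)
  if (S + 1L - tau[K] < min_seg) return(FALSE)
  if (nrow(state$beta) != K) return(FALSE)
  is.finite(state$sigma2) && state$sigma2 > 0
}

## number of admissible change-point sets with m interior points, min gap g,
## on S steps (log scale); the discrete-uniform tau prior normalizer
log_n_tau_configs <- function(m, S, g) {
  if (m == 0L) return(0)
  lchoose(S + 1L - 2L * g - (m - 1L) * (g - 1L), m)
}

#' Log-likelihood of a partition state
#'
#' Sum over stacked rows of the Normal(X_row beta_seg(row), sigma^2) log
#' density. Both components of a step share one segment by construction.
#'
#' @param state list with `tau` (segment start steps, first = 1), `beta`
#'   (K x p), `sigma2`.
#' @param ctx a design context from [build_design()].
#' @return scalar log-likelihood.
#' @export
state_loglik <- function(state, ctx) {
  seg <- seg_of_step(state$tau, ctx$S)[ctx$step]
  mu <- rowSums(ctx$X * state$beta[seg, , drop = FALSE])
  r <- ctx$y - mu
  n <- length(r)
  -0.5 * n * log(2 * pi * state$sigma2) - sum(r * r) / (2 * state$sigma2)
}

## residual sum of squares under the current betas
state_sse <- function(state, ctx) {
  seg <- seg_of_step(state$tau, ctx$S)[ctx$step]
  r <- ctx$y - rowSums(ctx$X * state$beta[seg, , drop = FALSE])
  sum(r * r)
}

## ---- priors ------------------------------------------------------------

#' Prior configuration for the velocity change-point model
#'
#' Gaussian prior N(`mu_beta`, `Sigma_beta`) on each segment's coefficient
#' vector, inverse-gamma (shape `q`, scale `r`) on the shared noise variance
#' sigma^2, discrete-uniform on change-point locations, and Poisson(`lambda`)
#' on the number of interior change points. The defaults are deliberately
#' diffuse: `Sigma_beta = 100 I`, and `q = 3`, `r = 20` give a sigma^2 prior
#' with mean 10 and variance 100.
#'
#' @param mu_beta prior mean vector (recycled to length p at fit time).
#' @param sigma_beta prior variance scale: `Sigma_beta = sigma_beta * I`.
#' @param q,r inverse-gamma shape (> 1) and scale (> 0) for sigma^2.
#' @param lambda Poisson prior mean for the number of interior change points.
#' @return object of class `velm_prior`.
#' @export
velm_prior <- function(mu_beta = 0, sigma_beta = 100, q = 3, r = 20, lambda = 1) {
  if (q <= 1) stop("q must exceed 1 (finite prior mean for sigma^2)")
  if (r <= 0 || sigma_beta <= 0 || lambda <= 0) stop("variances and lambda must be > 0")
  structure(list(mu_beta = mu_beta, sigma_beta = sigma_beta, q = q, r = r,
                 lambda = lambda), class = "velm_prior")
}

#' Prior mean of sigma^2 under a [velm_prior()]
#' @param prior a `velm_prior`.
#' @return `r / (q - 1)`.
#' @export
sigma2_prior_mean <- function(prior) prior$r / (prior$q - 1)

prior_beta_mean <- function(prior, p) rep_len(prior$mu_beta, p)

## log N(beta; mu_beta, sigma_beta I), independent components
log_prior_beta <- function(beta, prior) {
  p <- length(beta)
  mu <- prior_beta_mean(prior, p)
  sum(stats::dnorm(beta, mu, sqrt(prior$sigma_beta), log = TRUE))
}

## log posterior kernel of a partition state (sigma^2 prior omitted: it is
## common to all states compared within a sweep)
log_post_kernel <- function(state, ctx, prior, min_seg) {
  m <- length(state$tau) - 1L
  state_loglik(state, ctx) +
    stats::dpois(m, prior$lambda, log = TRUE) -
    log_n_tau_configs(m, ctx$S, min_seg) +
    sum(vapply(seq_len(nrow(state$beta)),
               function(k) log_prior_beta(state$beta[k, ], prior), 0))
}

## ---- Gibbs / MH updates -----------------------------------------------

## conjugate Gaussian full-conditional draw of beta for every segment
gibbs_update_beta <- function(state, ctx, prior) {
  K <- length(state$tau)
  p <- ctx$p
  seg <- seg_of_step(state$tau, ctx$S)[ctx$step]
  prec0 <- diag(1 / prior$sigma_beta, p)
  pm0 <- drop(prec0 %*% prior_beta_mean(prior, p))
  beta <- state$beta
  for (k in seq_len(K)) {
    rows <- seg == k
    Xk <- ctx$X[rows, , drop = FALSE]
    yk <- ctx$y[rows]
    A <- crossprod(Xk) / state$sigma2 + prec0
    b <- drop(crossprod(Xk, yk)) / state$sigma2 + pm0
    U <- chol(A)
    mean_k <- backsolve(U, backsolve(U, b, transpose = TRUE))
    beta[k, ] <- mean_k + backsolve(U, stats::rnorm(p))
  }
  state$beta <- beta
  state
}

## conjugate inverse-gamma full-conditional draw of sigma^2:
## InvGamma(q + N/2, r + SSE/2)
gibbs_update_sigma2 <- function(state, ctx, prior) {
  N <- length(ctx$y)
  sse <- state_sse(state, ctx)
  state$sigma2 <- 1 / stats::rgamma(1L, shape = prior$q + N / 2,
                                    rate = prior$r + sse / 2)
  state
}

## symmetric discrete random-walk Metropolis update of each interior change
## point; proposals violating ordering / min-segment constraints are rejected
## outright (the uniform tau prior cancels within fixed m)
mh_update_tau <- function(state, ctx, min_seg, window = 10L) {
  K <- length(state$tau)
  if (K < 2L || window < 1L) return(state)
  S <- ctx$S
  cur_ll <- state_loglik(state, ctx)
  for (j in 2:K) {
    shift <- sample.int(2L * window + 1L, 1L) - window - 1L
    if (shift == 0L) next
    tau_new <- state$tau
    tau_new[j] <- tau_new[j] + shift
    lo <- tau_new[j - 1L] + min_seg
    hi <- if (j < K) tau_new[j + 1L] - min_seg else S + 1L - min_seg
    if (tau_new[j] < lo || tau_new[j] > hi) next
    cand <- state; cand$tau <- tau_new
    cand_ll <- state_loglik(cand, ctx)
    if (log(stats::runif(1L)) < cand_ll - cur_ll) {
      state <- cand
      cur_ll <- cand_ll
    }
  }
  state
}
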