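## Birth-death MCMC over the change-point partition. The partition is viewed
## as a point process: each removable point is a (tau_k, beta_k) pair (the
## anchor segment starting at the grid start is never born or dies). Births
## arrive at rate lambda_b with the new change point drawn uniformly from the
## feasible free times and the new coefficients from an empirical Gaussian
## birth distribution built from a preliminary fixed-K fit; each point dies
## at the rate that makes the process reverse the birth, so the stationary
## law is the posterior (Stephens-style detailed balance). A death merges the
## segment into its left neighbour, whose coefficients survive; a birth
## splits a segment at tau*, the right part receiving the newborn
## coefficients.

#' Empirical birth distribution from a preliminary fit
#'
#' Per grid step `t`, the birth distribution for a newborn segment's
#' coefficients is Gaussian with mean the preliminary posterior mean of
#' `beta(t)` and covariance `c` times the preliminary posterior covariance of
#' `beta(t)`; `c > 0` is a mixing tuning constant that does not affect the
#' stationary posterior.
#'
#' @param prelim a `velm` fit (typically fixed-K) whose stored `beta(t)`
#'   draws supply the moments, or a list with elements `mean` (S x p) and
#'   `cov` (p x p x S).
#' @param c tuning scalar (> 0).
#' @return object of class `birth_distribution`.
#' @export
build_birth_distribution <- function(prelim, c = 1) {
  if (c <= 0) stop("birth tuning constant c must be > 0")
  if (inherits(prelim, "velm")) {
    draws <- prelim$beta_draws              # n_save x S x p
    if (is.null(draws) || dim(draws)[1L] < 2L)
      stop("preliminary fit must carry at least 2 stored beta(t) draws")
    S <- dim(draws)[2L]; p <- dim(draws)[3L]
    mean_t <- apply(draws, c(2L, 3L), mean)
    cov_t <- array(0, c(p, p, S))
    for (t in seq_len(S)) {
      B <- draws[, t, , drop = FALSE]
      dim(B) <- dim(draws)[c(1L, 3L)]
      cov_t[, , t] <- stats::cov(B)
    }
  } else {
    mean_t <- prelim$mean
    cov_t <- prelim$cov
    S <- nrow(mean_t); p <- ncol(mean_t)
    if (is.matrix(cov_t)) cov_t <- array(cov_t, c(p, p, S))
  }
  ## pre-factor the scaled covariances (ridge keeps degenerate posteriors PSD)
  p <- ncol(mean_t)
  chol_t <- array(0, c(p, p, nrow(mean_t)))
  for (t in seq_len(nrow(mean_t))) {
    Sg <- c * cov_t[, , t]
    Sg <- (Sg + t(Sg)) / 2 + diag(1e-8, p)
    chol_t[, , t] <- chol(Sg)
  }
  structure(list(mean = mean_t, cov = cov_t, chol = chol_t, c = c,
                 S = nrow(mean_t), p = p),
            class = "birth_distribution")
}

## log Gaussian birth density of beta at step t
birth_beta_logdens <- function(birth, t, beta) {
  p <- birth$p
  U <- matrix(birth$chol[, , t], p, p)
  z <- backsolve(U, beta - birth$mean[t, ], transpose = TRUE)
  -0.5 * sum(z * z) - sum(log(diag(U))) - 0.5 * p * log(2 * pi)
}

birth_beta_draw <- function(birth, t) {
  p <- birth$p
  drop(birth$mean[t, ] + crossprod(matrix(birth$chol[, , t], p, p),
                                   stats::rnorm(p)))
}

## feasible birth times for a state: inserting s must leave both the split
## segment's parts with >= min_seg steps
free_birth_times <- function(tau, S, min_seg) {
  K <- length(tau)
  ends <- c(tau[-1L] - 1L, S)
  out <- integer(0)
  for (k in seq_len(K)) {
    a <- tau[k]; b <- ends[k]
    if (b - a + 1L >= 2L * min_seg)
      out <- c(out, (a + min_seg):(b - min_seg + 1L))
  }
  out
}

#' Propose a birth
#'
#' Draws a candidate change point uniformly from the feasible free times and
#' candidate coefficients from the birth distribution at that time; returns
#' the pair together with its log birth density. Returns `NULL` when no
#' feasible time exists or the segment cap is reached (birth skipped).
#'
#' @param state partition state.
#' @param birth a [build_birth_distribution()].
#' @param S number of grid steps.
#' @param min_seg minimum segment length (steps).
#' @param K_max segment-count cap.
#' @return list(tau_star, beta_star, log_dens) or `NULL`.
#' @export
birth_propose <- function(state, birth, S, min_seg, K_max = 50L) {
  if (length(state$tau) >= K_max) return(NULL)
  free <- free_birth_times(state$tau, S, min_seg)
  if (!length(free)) return(NULL)
  t_star <- free[sample.int(length(free), 1L)]
  b_star <- birth_beta_draw(birth, t_star)
  list(tau_star = t_star, beta_star = b_star,
       log_dens = -log(length(free)) + birth_beta_logdens(birth, t_star, b_star))
}

## insert a newborn (tau*, beta*): the containing segment splits, its right
## part takes beta*
birth_apply <- function(state, tau_star, beta_star) {
  pos <- findInterval(tau_star, state$tau)
  tau <- append(state$tau, as.integer(tau_star), after = pos)
  beta <- rbind(state$beta[seq_len(pos), , drop = FALSE],
                beta_star,
                if (pos < nrow(state$beta))
                  state$beta[(pos + 1L):nrow(state$beta), , drop = FALSE])
  new_state(tau, beta, state$sigma2)
}

## remove point j (j >= 2): the segment merges into its left neighbour
death_apply <- function(state, j) {
  new_state(state$tau[-j], state$beta[-j, , drop = FALSE], state$sigma2)
}

#' Death rate of a removable segment
#'
#' The Stephens detailed-balance rate: `lambda_b` times the posterior-kernel
#' ratio of the state without the point to the state with it, times the birth
#' density of the removed point evaluated in the reduced state. Computed in
#' log space.
#'
#' @param state partition state with `K >= 2`.
#' @param j index of the removable segment (2..K).
#' @param ctx design context.
#' @param birth birth distribution.
#' @param prior a [velm_prior()].
#' @param lambda_b birth rate.
#' @param min_seg minimum segment length.
#' @return nonnegative death rate.
#' @export
death_rate <- function(state, j, ctx, birth, prior, lambda_b, min_seg) {
  reduced <- death_apply(state, j)
  lr <- log_post_kernel(reduced, ctx, prior, min_seg) -
    log_post_kernel(state, ctx, prior, min_seg)
  free <- free_birth_times(reduced$tau, ctx$S, min_seg)
  lb <- -log(length(free)) +
    birth_beta_logdens(birth, state$tau[j], state$beta[j, ])
  exp(min(log(lambda_b) + lr + lb, 700))
}

#' One birth-death sweep of virtual time T0
#'
#' Simulates the continuous-time birth-death process: repeatedly computes the
#' total event rate (birth rate, if feasible, plus all death rates), draws an
#' exponential waiting time, and executes a birth or a
#' probability-proportional death, until virtual time `T0` elapses.
#'
#' @param state partition state.
#' @param ctx design context.
#' @param birth birth distribution.
#' @param prior a [velm_prior()].
#' @param lambda_b birth rate (> 0, or 0 to disable births).
#' @param T0 virtual time per sweep.
#' @param min_seg minimum segment length.
#' @param K_max segment-count cap.
#' @param max_events guard on events per sweep.
#' @return updated partition state.
#' @export
bdmcmc_sweep <- function(state, ctx, birth, prior, lambda_b, T0 = 1,
                         min_seg = 5L, K_max = 50L, max_events = 1000L) {
  vt <- 0
  ev <- 0L
  repeat {
    K <- length(state$tau)
    can_birth <- lambda_b > 0 && K < K_max &&
      length(free_birth_times(state$tau, ctx$S, min_seg)) > 0L
    br <- if (can_birth) lambda_b else 0
    dr <- if (K >= 2L)
      vapply(2:K, function(j)
        death_rate(state, j, ctx, birth, prior, lambda_b, min_seg), 0)
    else numeric(0)
    total <- br + sum(dr)
    if (!is.finite(total) || total <= 0) break
    vt <- vt + stats::rexp(1L, total)
    if (vt > T0) break
    if (stats::runif(1L) * total < br) {
      prop <- birth_propose(state, birth, ctx$S, min_seg, K_max)
      if (!is.null(prop))
        state <- birth_apply(state, prop$tau_star, prop$beta_star)
    } else {
      j <- 1L + sample.int(length(dr), 1L, prob = dr)
      state <- death_apply(state, j)
    }
    ev <- ev + 1L
    if (ev >= max_events) break
  }
  state
}
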