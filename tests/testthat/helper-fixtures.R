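# shared fixtures and independent oracles, all generated in code

# dense joint-Gaussian log-density of one axis of the integrated-OU
# state-space model: the brute-force oracle for the Kalman likelihood
dense_ctcrw_loglik_axis <- function(obs, times, theta, sigma, obs_sd) {
  n <- length(times)
  mean_state <- matrix(0, 2, n)
  mean_state[, 1] <- c(obs[1], 0)
  covs <- array(0, c(2, 2, n, n))
  covs[, , 1, 1] <- diag(c(veloseg:::.ctcrw_pos_var0, sigma^2 / (2 * theta)))
  for (i in 2:n) {
    tr <- veloseg:::ctcrw_transition(theta, sigma, times[i] - times[i - 1])
    mean_state[, i] <- tr$Phi %*% mean_state[, i - 1]
    for (j in 1:(i - 1)) {
      covs[, , j, i] <- covs[, , j, i - 1] %*% t(tr$Phi)
      covs[, , i, j] <- t(covs[, , j, i])
    }
    covs[, , i, i] <- tr$Phi %*% covs[, , i - 1, i - 1] %*% t(tr$Phi) + tr$Q
  }
  mu <- mean_state[1, ]
  V <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) V[i, j] <- covs[1, 1, i, j]
  V <- V + diag(obs_sd^2, n)
  d <- obs - mu
  as.numeric(-0.5 * (n * log(2 * pi) + determinant(V)$modulus +
                       t(d) %*% solve(V, d)))
}

dense_ctcrw_loglik <- function(track, params) {
  dense_ctcrw_loglik_axis(track$x, track$times, params$ou_decay,
                          params$ou_scale, params$obs_sd) +
    dense_ctcrw_loglik_axis(track$y, track$times, params$ou_decay,
                            params$ou_scale, params$obs_sd)
}

# hand-built design context for sampler-level tests: S steps, one covariate
# column made of the supplied x/y gradient components
make_toy_ctx <- function(gx, gy, vx, vy) {
  S <- length(gx)
  list(y = c(vx, vy), X = cbind(c(gx, gy)), step = c(1:S, 1:S),
       axis = rep(1:2, each = S), S = S, keep = rep(TRUE, S),
       n_dropped = 0L, covariates = "g", p = 1L)
}

# a small central-place scenario used by the faster recovery tests
small_scenario <- function(T = 120L, sigma2 = 0.5, obs_sd = 0.3) {
  sim_scenario(T = T, tau = c(1L, as.integer(T / 2 + 1)),
               beta = rbind(c(2, 0), c(-2, 0)), sigma2 = sigma2,
               grid = list(n = 61L, h = 9, x0 = -270, y0 = -270),
               start = c(10, 5), obs_sd = obs_sd)
}

# most frequent value
mode_int <- function(x) as.integer(names(which.max(table(x))))

# most frequent interior change point among K = 2 draws
cp_mode <- function(fit) {
  k2 <- which(fit$K_draws == 2L)
  if (!length(k2)) return(NA_integer_)
  taus <- vapply(fit$tau_draws[k2], function(t) t[2], integer(1))
  mode_int(taus)
}
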