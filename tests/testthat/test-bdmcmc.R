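test_that("birth distribution carries preliminary posterior moments and
           scales with the tuning constant", {
  sc <- small_scenario(T = 80L)
  st <- sim_study(sc, seed = 5)
  prelim <- velm(fields = st$fields, K = 2L, paths = st$path,
                 control = velm_control(iters = 400, burn = 100), seed = 6)
  b1 <- build_birth_distribution(prelim, c = 1)
  b2 <- build_birth_distribution(prelim, c = 2)
  t0 <- 20L
  expect_equal(b1$mean[t0, ], apply(prelim$beta_draws[, t0, ], 2, mean),
               ignore_attr = TRUE)
  expect_equal(b2$cov, b1$cov)                 # raw moments unchanged
  expect_equal(crossprod(matrix(b2$chol[, , t0], 2, 2)),
               2 * crossprod(matrix(b1$chol[, , t0], 2, 2)),
               tolerance = 1e-6)               # scaled covariance doubles
  expect_error(build_birth_distribution(
    structure(list(beta_draws = prelim$beta_draws[1, , , drop = FALSE]),
              class = "velm"), c = 1), "at least 2")
  expect_error(build_birth_distribution(prelim, c = 0), "c must be > 0")
})

flat_birth <- function(S, p = 1L, v = 4) {
  build_birth_distribution(list(mean = matrix(0, S, p),
                                cov = array(diag(v, p), c(p, p, S))), c = 1)
}

test_that("birth proposals respect the free-time support and the density
           integrates to one", {
  S <- 10L
  birth <- flat_birth(S)
  st <- veloseg:::new_state(c(1L, 5L), rbind(1, -1), 1)
  set.seed(31)
  free <- veloseg:::free_birth_times(st$tau, S, 2L)
  expect_false(5L %in% free)                   # existing change point excluded
  draws <- replicate(400, birth_propose(st, birth, S, 2L, K_max = 10L)$tau_star)
  expect_true(all(draws %in% free))
  expect_null(birth_propose(st, birth, S, 2L, K_max = 2L))   # cap reached
  # quadrature: sum over tau*, integral over beta* of the birth density = 1
  bgrid <- seq(-30, 30, by = 0.005)
  total <- 0
  for (ts in free) {
    ld <- vapply(bgrid, function(b)
      veloseg:::birth_beta_logdens(birth, ts, b), 0) - log(length(free))
    total <- total + sum(exp(ld)) * 0.005
  }
  expect_equal(total, 1, tolerance = 1e-3)
})

test_that("death rates cancel the likelihood for redundant segments and fall
           as a segment explains more variance", {
  set.seed(41)
  S <- 12L
  gx <- runif(S, 0.5, 1.5); gy <- runif(S, -0.5, 0.5)
  prior <- velm_prior(lambda = 1)
  birth <- flat_birth(S)
  st <- veloseg:::new_state(c(1L, 7L), rbind(0.8, 0.8), 0.5)
  # equal betas: the likelihood ratio is 1, so the rate cannot depend on the data
  ctx_a <- make_toy_ctx(gx, gy, rnorm(S), rnorm(S))
  ctx_b <- make_toy_ctx(gx, gy, rnorm(S, 5), rnorm(S, -3))
  r_a <- death_rate(st, 2L, ctx_a, birth, prior, 1, 2L)
  r_b <- death_rate(st, 2L, ctx_b, birth, prior, 1, 2L)
  expect_equal(r_a, r_b, tolerance = 1e-10)
  # data generated with segment-2 beta = 2: the closer the segment's beta is
  # to 2, the smaller its death rate
  seg <- rep(1:2, c(6, 6))
  btr <- c(0, 2)
  vx <- gx * btr[seg] + rnorm(S, 0, 0.3)
  vy <- gy * btr[seg] + rnorm(S, 0, 0.3)
  ctx <- make_toy_ctx(gx, gy, vx, vy)
  rates <- vapply(c(0, 0.5, 1, 1.5, 2), function(b2)
    death_rate(veloseg:::new_state(c(1L, 7L), rbind(0, b2), 0.09),
               2L, ctx, birth, prior, 1, 2L), 0)
  expect_true(all(diff(rates) < 0))
})

test_that("birth-death sweeps preserve partition invariants and are inert
           when no event is possible", {
  set.seed(51)
  S <- 30L
  ctx <- make_toy_ctx(runif(S), runif(S), rnorm(S), rnorm(S))
  prior <- velm_prior(lambda = 1)
  birth <- flat_birth(S)
  st <- veloseg:::new_state(1L, matrix(0, 1, 1), 1)
  expect_identical(bdmcmc_sweep(st, ctx, birth, prior, lambda_b = 0,
                                min_seg = 3L), st)   # no births, nothing to die
  for (i in 1:200) {
    st <- bdmcmc_sweep(st, ctx, birth, prior, lambda_b = 1, min_seg = 3L,
                       K_max = 6L)
    st <- veloseg:::gibbs_update_beta(st, ctx, prior)
    expect_true(veloseg:::state_valid(st, S, 3L))
    expect_lte(length(st$tau), 6L)
  }
})

test_that("the birth-death chain reproduces the enumerated posterior over K
           on a two-state toy", {
  # 8 steps, one covariate, sigma^2 known, K in {1, 2}: the posterior is
  # enumerable by discretizing beta (the likelihood factorizes by segment)
  set.seed(5)
  S <- 8L; sig2 <- 0.25
  gx <- seq(0.5, 1.2, length.out = S); gy <- rep(0.3, S)
  seg_true <- rep(1:2, c(4, 4)); btru <- c(0.8, -0.2)
  vx <- gx * btru[seg_true] + rnorm(S, 0, sqrt(sig2))
  vy <- gy * btru[seg_true] + rnorm(S, 0, sqrt(sig2))
  ctx <- make_toy_ctx(gx, gy, vx, vy)
  prior <- velm_prior(lambda = 1)
  bgrid <- seq(-10, 10, by = 0.01)
  seg_margin <- function(steps) {
    rows <- c(steps, steps + S)
    ll <- vapply(bgrid, function(b)
      sum(dnorm(ctx$y[rows], ctx$X[rows, 1] * b, sqrt(sig2), log = TRUE)), 0) +
      dnorm(bgrid, 0, 10, log = TRUE)
    mx <- max(ll); mx + log(sum(exp(ll - mx)) * 0.01)
  }
  lw1 <- dpois(0, 1, log = TRUE) + seg_margin(1:S)
  lw2 <- vapply(3:7, function(tau) dpois(1, 1, log = TRUE) - log(5) +
                  seg_margin(1:(tau - 1)) + seg_margin(tau:S), 0)
  m0 <- max(lw1, lw2)
  p2_enum <- sum(exp(lw2 - m0)) / (exp(lw1 - m0) + sum(exp(lw2 - m0)))
  birth <- flat_birth(S)
  st <- veloseg:::new_state(1L, matrix(0, 1, 1), sig2)
  nit <- 30000L
  Ks <- integer(nit)
  for (it in seq_len(nit)) {
    st <- bdmcmc_sweep(st, ctx, birth, prior, lambda_b = 1, min_seg = 2L,
                       K_max = 2L)
    st <- veloseg:::gibbs_update_beta(st, ctx, prior)
    st <- veloseg:::mh_update_tau(st, ctx, 2L, window = 3L)
    Ks[it] <- length(st$tau)
  }
  p2_chain <- mean(Ks[-seq_len(2000)] == 2L)
  expect_lt(abs(p2_chain - p2_enum), 0.02)
})
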