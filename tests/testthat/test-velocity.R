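test_that("velocity transform is the scaled first difference and inverts exactly", {
  path <- rbind(c(0, 0), c(1, 2), c(3, 5))
  v <- path_to_velocity(path, dt = 1)
  expect_equal(v, rbind(c(1, 2), c(2, 3)))
  expect_equal(path_to_velocity(path, dt = 0.5), 2 * v)
  expect_equal(path_to_velocity(matrix(1, 4, 2), 1), matrix(0, 3, 2))
  set.seed(8)
  p2 <- matrix(cumsum(rnorm(20)), 10, 2)
  expect_equal(velocity_to_path(p2[1, ], path_to_velocity(p2, 0.25), 0.25), p2,
               tolerance = 1e-12)
  expect_error(path_to_velocity(matrix(0, 1, 2), 1), "at least 2")
})

test_that("stacked design has the block shape, optional drift columns, and
           honours out-of-extent dropping", {
  f <- vraster(outer(0:9, 0:9, function(y, x) x + 0.5 * y), 0, 0, 1)
  gf <- list(slope = gradient_field(f))
  path <- cbind(seq(1, 4, length.out = 4), seq(1, 4, length.out = 4))
  ctx <- build_design(path, dt = 1, fields = gf)
  expect_equal(length(ctx$y), 6L)          # 2 (T - 1) rows
  expect_equal(dim(ctx$X), c(6L, 1L))
  expect_equal(ctx$X[, 1], c(rep(1, 3), rep(0.5, 3)))  # x-block then y-block
  ctx_d <- build_design(path, dt = 1, fields = gf, drift = TRUE)
  expect_equal(ctx_d$p, 3L)
  expect_equal(ctx_d$X[, 2], c(1, 1, 1, 0, 0, 0))      # drift_x
  expect_equal(ctx_d$X[, 3], c(0, 0, 0, 1, 1, 1))      # drift_y
  # a step whose location lies outside the raster extent is dropped (both
  # components); steps starting inside are kept
  path2 <- rbind(path, c(40, 40), c(41, 41))
  ctx2 <- build_design(path2, dt = 1, fields = gf)
  expect_equal(ctx2$n_dropped, 1L)
  expect_equal(sum(ctx2$keep), 4L)
  expect_equal(length(ctx2$y), 8L)
})

test_that("partition log-likelihood matches closed form and a brute-force
           per-observation oracle, and is invariant to idle splits", {
  set.seed(21)
  S <- 5
  ctx <- make_toy_ctx(runif(S), runif(S), rnorm(S), rnorm(S))
  st0 <- veloseg:::new_state(1L, matrix(0, 1, 1), 1)
  expect_equal(state_loglik(st0, ctx),
               -0.5 * sum(ctx$y^2) - length(ctx$y) / 2 * log(2 * pi))
  st <- veloseg:::new_state(c(1L, 3L), rbind(0.7, -1.2), 0.63)
  seg <- rep(1:2, c(2, 3))
  brute <- sum(dnorm(c(ctx$y[1:S]), ctx$X[1:S, 1] * c(0.7, -1.2)[seg],
                     sqrt(0.63), log = TRUE)) +
    sum(dnorm(ctx$y[S + 1:S], ctx$X[S + 1:S, 1] * c(0.7, -1.2)[seg],
              sqrt(0.63), log = TRUE))
  expect_equal(state_loglik(st, ctx), brute, tolerance = 1e-10)
  # splitting a segment without changing beta leaves the likelihood unchanged
  st_split <- veloseg:::new_state(c(1L, 3L, 5L), rbind(0.7, -1.2, -1.2), 0.63)
  expect_equal(state_loglik(st_split, ctx), state_loglik(st, ctx), tolerance = 1e-12)
})

test_that("beta full conditional matches least squares in the diffuse limit
           and its draw moments match the conjugate Gaussian", {
  set.seed(31)
  S <- 40
  gx <- rnorm(S); gy <- rnorm(S)
  b_true <- 1.4
  vx <- gx * b_true + rnorm(S, 0, 0.3); vy <- gy * b_true + rnorm(S, 0, 0.3)
  ctx <- make_toy_ctx(gx, gy, vx, vy)
  prior_diffuse <- velm_prior(sigma_beta = 1e8)
  st <- veloseg:::new_state(1L, matrix(0, 1, 1), 0.09)
  draws <- replicate(10000, veloseg:::gibbs_update_beta(st, ctx, prior_diffuse)$beta[1, 1])
  ls_fit <- unname(coef(lm(ctx$y ~ ctx$X - 1)))      # independent LS oracle
  se <- sd(draws) / sqrt(10000)
  expect_lt(abs(mean(draws) - ls_fit), 3 * se + 1e-4 * abs(ls_fit))
  # analytic conjugate moments with an informative prior
  prior <- velm_prior(mu_beta = 0.5, sigma_beta = 0.2)
  V <- 1 / (crossprod(ctx$X)[1, 1] / 0.09 + 1 / 0.2)
  mth <- V * (crossprod(ctx$X, ctx$y)[1, 1] / 0.09 + 0.5 / 0.2)
  draws2 <- replicate(10000, veloseg:::gibbs_update_beta(st, ctx, prior)$beta[1, 1])
  expect_lt(abs(mean(draws2) - mth), 3 * sd(draws2) / sqrt(10000))
  expect_lt(abs(var(draws2) - V), 3 * V * sqrt(2 / 9999))
  # zero-gradient design: draws come from the prior
  ctx0 <- make_toy_ctx(rep(0, S), rep(0, S), vx, vy)
  draws3 <- replicate(5000, veloseg:::gibbs_update_beta(st, ctx0, prior)$beta[1, 1])
  expect_lt(abs(mean(draws3) - 0.5), 3 * sqrt(0.2 / 5000))
  expect_lt(abs(var(draws3) - 0.2), 4 * 0.2 * sqrt(2 / 4999))
})

test_that("sigma^2 full conditional is InvGamma(q + N/2, r + SSE/2)", {
  # residuals (1, -1, 2, -2) with q = 3, r = 20: target InvGamma(5, 25)
  ctx <- make_toy_ctx(c(0, 0), c(0, 0), c(1, -1), c(2, -2))
  st <- veloseg:::new_state(1L, matrix(0, 1, 1), 1)
  prior <- velm_prior(q = 3, r = 20)
  set.seed(99)
  draws <- replicate(20000, veloseg:::gibbs_update_sigma2(st, ctx, prior)$sigma2)
  # InvGamma(5, 25): mean 25/4, var 25^2/(16 * 3)
  se <- sqrt(625 / 48 / 20000)
  expect_lt(abs(mean(draws) - 6.25), 3 * se)
  # all residuals zero: conditional is InvGamma(q + N/2, r)
  ctx0 <- make_toy_ctx(c(0, 0), c(0, 0), c(0, 0), c(0, 0))
  d0 <- replicate(20000, veloseg:::gibbs_update_sigma2(st, ctx0, prior)$sigma2)
  expect_lt(abs(mean(d0) - 20 / (3 + 2 - 1)), 3 * sd(d0) / sqrt(20000))
})

test_that("change-point Metropolis respects constraints and is uniform under a
           flat likelihood", {
  set.seed(55)
  S <- 20L
  ctx <- make_toy_ctx(rnorm(S), rnorm(S), rnorm(S), rnorm(S))
  # identical beta across segments makes the likelihood flat in tau
  st <- veloseg:::new_state(c(1L, 10L), rbind(0.3, 0.3), 1)
  expect_identical(veloseg:::mh_update_tau(st, ctx, min_seg = 2L, window = 0L)$tau,
                   st$tau)
  taus <- integer(60000)
  for (i in seq_along(taus)) {
    st <- veloseg:::mh_update_tau(st, ctx, min_seg = 2L, window = 4L)
    taus[i] <- st$tau[2]
  }
  allowed <- 3:19          # min gap 2 on both sides
  expect_true(all(taus %in% allowed))
  # thin the walk so the chi-square multinomial assumption is honest
  thinned <- taus[seq(20, length(taus), by = 20)]
  chi <- chisq.test(table(factor(thinned, levels = allowed)))
  expect_gt(chi$p.value, 0.01)
})

test_that("fixed-K fit recovers a planted change point from the true path", {
  sc <- small_scenario(T = 200L)
  st <- sim_study(sc, seed = 77)
  fit <- velm(fields = st$fields, K = 2L, paths = st$path,
              control = velm_control(iters = 1200, burn = 300, min_seg = 5),
              seed = 78)
  taus <- vapply(fit$tau_draws, function(t) t[2], integer(1))
  expect_lt(abs(mode_int(taus) - st$truth$tau[2]), 10)
  expect_error(velm(fields = st$fields, K = 50L, paths = st$path,
                    control = velm_control(iters = 200, burn = 50)),
               "infeasible K")
  expect_error(velm_control(iters = 100, burn = 100), "iters > burn")
})
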