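test_that("synthetic covariate surfaces have the advertised analytic shape", {
  sc <- sim_scenario(covariates = list(
    list(name = "bump", type = "bump", center = c(45, -18), height = 50, width = 60),
    list(name = "plane", type = "plane", a = 2, b = 0, c0 = 1)),
    grid = list(n = 41L, h = 9, x0 = -180, y0 = -180))
  covs <- sim_covariates(sc)
  # bump maximum sits at the cell nearest the centre
  idx <- arrayInd(which.max(covs$bump$values), dim(covs$bump$values))
  xs <- veloseg:::raster_xcoords(covs$bump); ys <- veloseg:::raster_ycoords(covs$bump)
  expect_lte(abs(xs[idx[2]] - 45), 9 / 2 + 1e-9)
  expect_lte(abs(ys[idx[1]] - (-18)), 9 / 2 + 1e-9)
  # plane gradient is exact in the interior
  gp <- gradient_field(covs$plane)
  expect_equal(gp$gx$values[5, 5], 2, tolerance = 1e-12)
  expect_equal(gp$gy$values[5, 5], 0, tolerance = 1e-12)
  # numeric bump gradient matches the closed form within the Taylor bound
  gb <- gradient_field(covs$bump)
  cx <- 45; cy <- -18; w <- 60; hgt <- 50
  at <- c(90, 36)
  g_true <- -hgt * exp(-sum((at - c(cx, cy))^2) / (2 * w^2)) *
    (at - c(cx, cy)) / w^2
  # third derivatives of the bump are O(h/w) smaller than the gradient itself;
  # a generous h^2-scaled bound suffices
  expect_lt(max(abs(drop(eval_gradient(gb, at)) - g_true)), 9^2 * 1e-3)
})

test_that("the forward velocity process follows its mean drift", {
  # constant-gradient plane: mean per-step displacement must be dt * g * b
  sc <- sim_scenario(T = 2000L, tau = 1L, beta = rbind(0.05), sigma2 = 0.04,
                     covariates = list(list(name = "plane", type = "plane",
                                            a = 1, b = 0.5, c0 = 0)),
                     start = c(0, 0), grid = list(n = 131L, h = 9, x0 = -585,
                                                  y0 = -585))
  tr <- sim_track(sc, seed = 3)
  steps <- diff(tr$path)
  g <- c(1, 0.5)
  mc_se <- sqrt(0.04 / nrow(steps))
  expect_lt(abs(mean(steps[, 1]) - 0.05 * g[1]), 3 * mc_se)
  expect_lt(abs(mean(steps[, 2]) - 0.05 * g[2]), 3 * mc_se)
  # beta = 0 and vanishing noise: the path stays put
  sc0 <- sim_scenario(T = 50L, tau = 1L, beta = rbind(0), sigma2 = 1e-12,
                      covariates = list(list(name = "plane", type = "plane",
                                             a = 1, b = 0, c0 = 0)),
                      start = c(3, 3), grid = list(n = 21L, h = 9, x0 = -90,
                                                   y0 = -90))
  tr0 <- sim_track(sc0, seed = 4)
  expect_lt(max(abs(sweep(tr0$path, 2, c(3, 3)))), 1e-4)
  # sign-flipped beta reverses the mean drift direction at the change point
  scf <- sim_scenario(T = 400L, tau = c(1L, 201L), beta = rbind(0.05, -0.05),
                      sigma2 = 0.04,
                      covariates = list(list(name = "plane", type = "plane",
                                             a = 1, b = 0, c0 = 0)),
                      start = c(0, 0), grid = list(n = 131L, h = 9, x0 = -585,
                                                   y0 = -585))
  trf <- sim_track(scf, seed = 5)
  d <- diff(trf$path[, 1])
  expect_gt(mean(d[1:200]), 0)
  expect_lt(mean(d[201:399]), 0)
})

test_that("telemetry degradation has the advertised sampling and error laws", {
  sc <- small_scenario(T = 100L, obs_sd = 0)
  sc$gap_dist <- "fixed"; sc$mean_gap <- sc$dt
  st <- sim_track(sc, seed = 6)
  trk <- sim_telemetry(st$path, st$times, sc, seed = 7)
  # noiseless fixed-gap sampling reproduces the path exactly
  at <- match(round(trk$times, 9), round(st$times, 9))
  expect_true(!anyNA(at))
  expect_equal(trk$x, st$path[at, 1], tolerance = 1e-9)
  expect_equal(trk$y, st$path[at, 2], tolerance = 1e-9)
  # empirical location-error sd within 5% of obs_sd at 10^4 fixes
  sc2 <- sim_scenario(T = 12001L, tau = 1L, beta = rbind(0), sigma2 = 1e-6,
                      covariates = list(list(name = "plane", type = "plane",
                                             a = 0, b = 0, c0 = 0)),
                      start = c(0, 0), mean_gap = 1, obs_sd = 0.5,
                      grid = list(n = 21L, h = 9, x0 = -90, y0 = -90))
  st2 <- sim_track(sc2, seed = 8)
  trk2 <- sim_telemetry(st2$path, st2$times, sc2, seed = 9)
  expect_gt(length(trk2$times), 1e4)
  ex <- trk2$x - approx(st2$times, st2$path[, 1], xout = trk2$times)$y
  ey <- trk2$y - approx(st2$times, st2$path[, 2], xout = trk2$times)$y
  expect_lt(abs(sd(c(ex, ey)) - 0.5) / 0.5, 0.05)
  # fix times strictly increasing and inside the path span
  expect_true(all(diff(trk2$times) > 0))
  expect_true(min(trk2$times) >= min(st2$times) &&
                max(trk2$times) <= max(st2$times))
})

test_that("the whole synthetic study is reproducible from its seed", {
  a <- sim_study(small_scenario(T = 60L), seed = 123)
  b <- sim_study(small_scenario(T = 60L), seed = 123)
  expect_identical(a$path, b$path)
  expect_identical(a$track$times, b$track$times)
  expect_identical(a$track$x, b$track$x)
})
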