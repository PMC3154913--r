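## Synthetic-data generator: smooth covariate surfaces with closed-form
## gradients, gradient-driven piecewise-coefficient tracks simulated forward
## at the analysis resolution, and Argos-like degradation to irregular noisy
## fixes. This is the test bed for the whole pipeline: every recovery test
## and the population workflow run on data from here.

#' Default simulation scenario
#'
#' A central-place-forager scenario: the animal starts near a home site,
#' moves away from it at ~2 km/h for the first half of the trip (positive
#' coefficient on the home-distance gradient) and returns in the second half
#' (sign-flipped coefficient), with velocity noise `sigma2 = 0.5` (km/h)^2.
#' A second, inactive bump-shaped covariate ("prey") is included so that
#' covariate selection has something to reject. The grid uses 9 km cells,
#' matching the resolution of typical monthly ocean covariates.
#'
#' @param T number of regular path locations (T - 1 velocity steps).
#' @param dt grid spacing, hours.
#' @param tau segment start steps (first = 1).
#' @param beta K x p coefficient matrix (columns follow `covariates`).
#' @param sigma2 velocity noise variance, (km/h)^2.
#' @param start start location (km).
#' @param home home-site location (km) for the distance covariate.
#' @param covariates list of covariate surface specs; each is a list with
#'   `type` in `"distance"` (field `target`), `"bump"` (`center`, `height`,
#'   `width`) or `"plane"` (`a`, `b`, `c0`), plus a `name`.
#' @param grid list with `n` (cells per side), `h` (cell km), `x0`, `y0`
#'   (centre of cell \[1,1\]).
#' @param mean_gap mean telemetry sampling gap, hours (>= dt).
#' @param gap_dist `"exponential"` (Argos-like renewal) or `"fixed"`.
#' @param obs_sd telemetry location-error sd, km.
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(T = 500L, dt = 1, tau = c(1L, 251L),
                         beta = rbind(c(2, 0), c(-2, 0)), sigma2 = 0.5,
                         start = c(20, 10), home = c(0, 0),
                         covariates = list(
                           list(name = "dist_home", type = "distance", target = c(0, 0)),
                           list(name = "prey", type = "bump",
                                center = c(200, 150), height = 100, width = 150)),
                         grid = list(n = 131L, h = 9, x0 = -585, y0 = -585),
                         mean_gap = 2, gap_dist = "exponential", obs_sd = 0.3) {
  beta <- rbind(beta)
  if (length(tau) != nrow(beta)) stop("tau and beta disagree on segment count")
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  if (mean_gap < dt) stop("mean sampling gap must be >= the grid spacing dt")
  if (any(tau > T - 1L) || tau[1L] != 1L) stop("tau must start at 1 and lie on the step grid")
  structure(as.list(environment()), class = "sim_scenario")
}

#' Synthesize covariate rasters for a scenario
#'
#' Builds each covariate surface on the scenario grid. Bump surfaces are
#' isotropic Gaussians with closed-form values (and hence closed-form
#' gradients, used as oracles in tests); planes are affine; distance surfaces
#' come from [distance_covariate()].
#'
#' @param scenario a [sim_scenario()].
#' @return named list of [vraster()] layers.
#' @export
sim_covariates <- function(scenario) {
  g <- scenario$grid
  geom <- vraster(matrix(0, g$n, g$n), g$x0, g$y0, g$h)
  xs <- raster_xcoords(geom); ys <- raster_ycoords(geom)
  X <- matrix(xs, g$n, g$n, byrow = TRUE)
  Y <- matrix(ys, g$n, g$n)
  out <- list()
  for (spec in scenario$covariates) {
    v <- switch(spec$type,
      distance = distance_covariate(geom, spec$target, name = spec$name),
      bump = vraster(spec$height *
                       exp(-((X - spec$center[1L])^2 + (Y - spec$center[2L])^2) /
                             (2 * spec$width^2)),
                     g$x0, g$y0, g$h, name = spec$name),
      plane = vraster(spec$a * X + spec$b * Y + spec$c0,
                      g$x0, g$y0, g$h, name = spec$name),
      stop("unknown covariate spec type: ", spec$type))
    out[[spec$name]] <- v
  }
  out
}

#' Simulate a gradient-driven track on the regular grid
#'
#' Forward simulation of the velocity model at the analysis resolution:
#' `mu_{t+1} = mu_t + dt (X(mu_t) beta_seg(t) + eps_t)`,
#' `eps_t ~ N(0, sigma2 I)`. Steps that would leave the raster extent are
#' re-drawn (then noise-shrunk) a bounded number of times; the count is
#' recorded.
#'
#' @param scenario a [sim_scenario()].
#' @param fields named list of [gradient_field()]s (defaults to gradients of
#'   [sim_covariates()]).
#' @param seed optional RNG seed.
#' @return list: `path` (T x 2), `times`, `truth` (tau, beta, sigma2),
#'   `fields`, `n_retries`.
#' @export
sim_track <- function(scenario, fields = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fields))
    fields <- lapply(sim_covariates(scenario), gradient_field)
  Tn <- scenario$T
  dt <- scenario$dt
  seg <- seg_of_step(scenario$tau, Tn - 1L)
  p <- length(fields)
  if (ncol(scenario$beta) != p) stop("beta has ", ncol(scenario$beta),
                                     " columns but there are ", p, " covariates")
  sd_eps <- sqrt(scenario$sigma2)
  path <- matrix(0, Tn, 2L)
  path[1L, ] <- scenario$start
  g1 <- fields[[1L]]$gx
  xr <- range(raster_xcoords(g1)); yr <- range(raster_ycoords(g1))
  n_retries <- 0L
  for (t in seq_len(Tn - 1L)) {
    G <- t(eval_gradient_list(fields, path[t, ]))
    drift_v <- drop(G %*% scenario$beta[seg[t], ])
    ok <- FALSE
    shrink <- 1
    for (try in seq_len(60L)) {
      eps <- stats::rnorm(2L, 0, sd_eps * shrink)
      cand <- path[t, ] + dt * (drift_v + eps)
      if (cand[1L] >= xr[1L] && cand[1L] <= xr[2L] &&
          cand[2L] >= yr[1L] && cand[2L] <= yr[2L]) { ok <- TRUE; break }
      n_retries <- n_retries + 1L
      if (try > 20L) shrink <- shrink / 2
    }
    if (!ok) stop("simulated track escaped the grid at step ", t,
                  " despite retries; enlarge the grid or shrink beta")
    path[t + 1L, ] <- cand
  }
  list(path = path, times = dt * (seq_len(Tn) - 1L),
       truth = list(tau = scenario$tau, beta = scenario$beta,
                    sigma2 = scenario$sigma2),
       fields = fields, n_retries = n_retries)
}

## evaluate all gradient fields at one location: p x 2 matrix
eval_gradient_list <- function(fields, xy) {
  t(vapply(fields, function(f) drop(eval_gradient(f, xy)), numeric(2L)))
}

#' Degrade a regular path to Argos-like telemetry
#'
#' Fix times come from a renewal process over the path span (exponential
#' gaps with the scenario's mean, or fixed gaps); locations are the true path
#' linearly interpolated at those times plus isotropic Gaussian error.
#'
#' @param path T x 2 matrix of true locations.
#' @param times length-T vector of path times (hours).
#' @param scenario a [sim_scenario()] (supplies `mean_gap`, `gap_dist`,
#'   `obs_sd`).
#' @param id animal id for the resulting track.
#' @param group optional subgroup label.
#' @param seed optional RNG seed.
#' @return a [telemetry_track()].
#' @export
sim_telemetry <- function(path, times, scenario, id = "sim", group = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  span <- range(times)
  tt <- span[1L]
  fix_times <- tt
  repeat {
    gap <- if (scenario$gap_dist == "fixed") scenario$mean_gap
           else stats::rexp(1L, 1 / scenario$mean_gap)
    tt <- tt + max(gap, 1e-6)
    if (tt > span[2L]) break
    fix_times <- c(fix_times, tt)
  }
  if (length(fix_times) < 2L) fix_times <- span
  fx <- stats::approx(times, path[, 1L], xout = fix_times)$y
  fy <- stats::approx(times, path[, 2L], xout = fix_times)$y
  n <- length(fix_times)
  telemetry_track(id, fix_times,
                  fx + stats::rnorm(n, 0, scenario$obs_sd),
                  fy + stats::rnorm(n, 0, scenario$obs_sd),
                  group = group)
}

#' One-call synthetic study
#'
#' Convenience wrapper: covariate surfaces, gradient fields, a true track
#' and its degraded telemetry, all reproducible from the seed.
#'
#' @param scenario a [sim_scenario()].
#' @param seed RNG seed.
#' @param id,group passed to [sim_telemetry()].
#' @return list: `scenario`, `covariates`, `fields`, `path`, `times`,
#'   `truth`, `track`.
#' @export
sim_study <- function(scenario = sim_scenario(), seed = 1, id = "sim",
                      group = NULL) {
  set.seed(seed)
  covs <- sim_covariates(scenario)
  fields <- lapply(covs, gradient_field)
  tr <- sim_track(scenario, fields)
  track <- sim_telemetry(tr$path, tr$times, scenario, id = id, group = group)
  list(scenario = scenario, covariates = covs, fields = fields,
       path = tr$path, times = tr$times, truth = tr$truth, track = track)
}

#' Planted-regime population of coefficient trajectories
#'
#' Emulates the population-level workflow's input: each animal's
#' posterior-mean `beta(t)` trajectory dwells in a few population regimes
#' (segments of consecutive time steps share a regime), with subgroups
#' differing in their regime-usage probabilities. Used to exercise pooling,
#' mixture clustering and the subgroup tree without re-fitting every animal.
#'
#' @param n_animals number of animals.
#' @param regime_means G x p matrix of regime centroids in coefficient space.
#' @param usage named list of per-subgroup regime-usage probability vectors
#'   (length G each); animals are split evenly between subgroups.
#' @param n_times time steps per animal.
#' @param seg_len mean dwell length (steps) in one regime.
#' @param within_sd coefficient noise sd around the regime centroid.
#' @param seed RNG seed.
#' @return list: `trajectories` (list of [beta_trajectory()]-shaped
#'   data.frames), `true_regime` (list of per-time regime labels).
#' @export
sim_population_betas <- function(n_animals = 20L,
                                 regime_means = rbind(c(2, 0), c(-2, 0), c(0, 2)),
                                 usage = list(A = c(0.45, 0.45, 0.10),
                                              B = c(0.25, 0.25, 0.50)),
                                 n_times = 2000L, seg_len = 100L,
                                 within_sd = 0.12, seed = 1) {
  set.seed(seed)
  G <- nrow(regime_means); p <- ncol(regime_means)
  groups <- rep(names(usage), length.out = n_animals)
  trajectories <- vector("list", n_animals)
  true_regime <- vector("list", n_animals)
  for (i in seq_len(n_animals)) {
    u <- usage[[groups[i]]]
    lab <- integer(0)
    while (length(lab) < n_times) {
      g <- sample.int(G, 1L, prob = u)
      len <- 1L + stats::rgeom(1L, 1 / seg_len)
      lab <- c(lab, rep.int(g, len))
    }
    lab <- lab[seq_len(n_times)]
    B <- regime_means[lab, , drop = FALSE] +
      matrix(stats::rnorm(n_times * p, 0, within_sd), n_times, p)
    df <- data.frame(animal = sprintf("a%02d", i), group = groups[i],
                     time = seq_len(n_times), B, check.names = FALSE)
    names(df)[3L + seq_len(p)] <- paste0("b", seq_len(p))
    trajectories[[i]] <- df
    true_regime[[i]] <- lab
  }
  list(trajectories = trajectories, true_regime = true_regime)
}
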