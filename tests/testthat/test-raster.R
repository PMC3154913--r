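test_that("thin-plate fill reproduces constants and affine surfaces", {
  m <- matrix(5, 12, 12)
  r <- vraster(m, 0, 0, 1, "const")
  expect_identical(fill_missing(r)$values, r$values)  # nothing missing: identity
  holes <- cbind(sample(2:11, 8), sample(2:11, 8))
  m2 <- m; m2[holes] <- NA
  filled <- fill_missing(vraster(m2, 0, 0, 1))
  expect_equal(filled$values, m, tolerance = 1e-8)
  # affine surface f = 2x + y is in the spline's null space: exact recovery
  set.seed(11)
  xs <- 0:11; ys <- 0:11
  plane <- outer(ys, xs, function(y, x) 2 * x + y)
  pm <- plane
  pm[sample(length(pm), round(0.2 * length(pm)))] <- NA
  got <- fill_missing(vraster(pm, 0, 0, 1))
  expect_equal(got$values, plane, tolerance = 1e-6)
  # observed cells are untouched
  obs <- !is.na(pm)
  expect_identical(got$values[obs], plane[obs])
  expect_error(fill_missing(vraster(matrix(NA_real_, 4, 4))), "all cells missing")
})

test_that("temporal blending weights are inverse to the time gaps", {
  a <- vraster(matrix(0, 3, 3)); b <- vraster(matrix(1, 3, 3))
  expect_equal(temporal_blend(a, b, 0, 10, 5)$values, matrix(0.5, 3, 3))
  expect_equal(temporal_blend(a, b, 0, 4, 1)$values, matrix(0.25, 3, 3))
  expect_equal(temporal_blend(a, b, 0, 4, 0)$values, a$values)  # endpoint weight 1
  expect_equal(temporal_blend(a, b, 0, 4, 4)$values, b$values)
  bad <- vraster(matrix(1, 4, 3))
  expect_error(temporal_blend(a, bad, 0, 1, 0.5), "mismatched grids")
  expect_error(temporal_blend(a, b, 0, 1, 2), "outside")
})

test_that("distance covariate matches the exhaustive oracle and its gradient
           points away from the target", {
  geom <- vraster(matrix(0, 10, 10), 0, 0, 1)
  d <- distance_covariate(geom, c(3, 4))
  expect_equal(d$values[5, 4], 0)           # cell centre (3, 4) -> row 5, col 4
  expect_true(all(d$values >= 0))
  # mask distance vs brute-force min over mask cells
  mask <- matrix(FALSE, 10, 10); mask[2, 7] <- TRUE; mask[9, 3] <- TRUE
  dm <- distance_covariate(geom, mask)
  xs <- veloseg:::raster_xcoords(geom); ys <- veloseg:::raster_ycoords(geom)
  brute <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10)
    brute[i, j] <- min(sqrt((xs[j] - xs[7])^2 + (ys[i] - ys[2])^2),
                       sqrt((xs[j] - xs[3])^2 + (ys[i] - ys[9])^2))
  expect_equal(dm$values, brute, tolerance = 1e-12)
  expect_true(all(dm$values[mask] == 0))
  expect_error(distance_covariate(geom, matrix(FALSE, 10, 10)), "empty mask")
  # gradient approximates the unit vector (x - p)/|x - p| away from the target
  gf <- gradient_field(distance_covariate(vraster(matrix(0, 40, 40), 0, 0, 0.5),
                                          c(9.75, 9.75)))
  at <- c(14, 6)
  g <- drop(eval_gradient(gf, at))
  u <- (at - c(9.75, 9.75)) / sqrt(sum((at - c(9.75, 9.75))^2))
  expect_equal(g, u, tolerance = 0.01, ignore_attr = TRUE)
  # gradient at the singular (zero-distance) cell is the zero vector
  d0 <- distance_covariate(geom, c(3, 4))
  g0 <- gradient_field(d0)
  expect_equal(g0$gx$values[5, 4], 0)
  expect_equal(g0$gy$values[5, 4], 0)
})

test_that("finite-difference gradients are exact for affine and Taylor-bounded
           for smooth surfaces, and linear in the surface", {
  const <- gradient_field(vraster(matrix(3.3, 6, 8)))
  expect_true(all(const$gx$values == 0) && all(const$gy$values == 0))
  xs <- seq(0, 7); ys <- seq(0, 5)
  plane <- vraster(outer(ys, xs, function(y, x) 2 * x), 0, 0, 1)
  gp <- gradient_field(plane)
  expect_equal(gp$gx$values, matrix(2, 6, 8))
  expect_equal(gp$gy$values, matrix(0, 6, 8))
  # f = sin(x) cos(y), h = 0.1: central-difference error <= h^2/6 * max|f'''|
  h <- 0.1
  xs <- seq(0, 3, by = h); ys <- seq(0, 2, by = h)
  f <- vraster(outer(ys, xs, function(y, x) sin(x) * cos(y)), 0, 0, h)
  gf <- gradient_field(f)
  true_gx <- outer(ys, xs, function(y, x) cos(x) * cos(y))
  true_gy <- outer(ys, xs, function(y, x) -sin(x) * sin(y))
  interior_r <- 2:(length(ys) - 1); interior_c <- 2:(length(xs) - 1)
  expect_lt(max(abs((gf$gx$values - true_gx)[interior_r, interior_c])), h^2 / 6 * 1.01)
  expect_lt(max(abs((gf$gy$values - true_gy)[interior_r, interior_c])), h^2 / 6 * 1.01)
  # linearity: grad(a f + b g) = a grad(f) + b grad(g)
  set.seed(2)
  A <- vraster(matrix(rnorm(48), 6, 8)); B <- vraster(matrix(rnorm(48), 6, 8))
  comb <- vraster(1.5 * A$values - 2 * B$values)
  gc <- gradient_field(comb)
  ga <- gradient_field(A); gb <- gradient_field(B)
  expect_equal(gc$gx$values, 1.5 * ga$gx$values - 2 * gb$gx$values, tolerance = 1e-12)
  expect_equal(gc$gy$values, 1.5 * ga$gy$values - 2 * gb$gy$values, tolerance = 1e-12)
  expect_error(gradient_field(vraster(matrix(c(1, NA, 2, 3), 2, 2))), "unfilled")
})

test_that("bilinear gradient evaluation interpolates and guards the extent", {
  xs <- 0:5; ys <- 0:4
  f <- vraster(outer(ys, xs, function(y, x) x^2 + 3 * y), 0, 0, 1)
  gf <- gradient_field(f)
  # at a cell centre: exactly the cell's stored gradient
  expect_equal(drop(eval_gradient(gf, c(2, 2))),
               c(gf$gx$values[3, 3], gf$gy$values[3, 3]), ignore_attr = TRUE)
  # midway between two horizontally adjacent centres: component-wise average
  expect_equal(drop(eval_gradient(gf, c(2.5, 2)))[1],
               (gf$gx$values[3, 3] + gf$gx$values[3, 4]) / 2, ignore_attr = TRUE)
  expect_error(eval_gradient(gf, c(6.5, 2)), "outside the extent")
  expect_true(all(is.na(eval_gradient(gf, c(6.5, 2), na_outside = TRUE))))
})

test_that("ESRI ASCII grids round-trip exactly, including missing cells", {
  set.seed(5)
  m <- matrix(rnorm(30), 5, 6)
  m[2, 3] <- NA
  r <- vraster(m, x0 = -10, y0 = 4, h = 2.5, name = "sst")
  f <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(r, f)
  back <- read_esri_ascii(f, name = "sst")
  expect_equal(back$values, r$values, tolerance = 1e-12)
  expect_equal(c(back$x0, back$y0, back$h), c(-10, 4, 2.5))
})
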