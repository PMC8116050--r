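test_that("geometry construction matches analytic volumes", {
  # sphere-only control: ellipsoid width equal to neck joins without
  # constriction; test the sphere volume with a generous ellipsoid offset
  geom <- frap_geometry(voxel = 0.1, sphere_diam = 6, ellipsoid_length = 6,
                        ellipsoid_width = 3, neck_diam = 2)
  expect_s3_class(geom, "frap_geometry")
  expect_equal(sort(unique(geom$compartment[geom$mask])),
               c("daughter", "mother"))
  # analytic union volume: sphere + ellipsoid - lens overlap, bounded checks
  vol_sphere <- 4 / 3 * pi * 27
  vol_ellip <- 4 / 3 * pi * 3 * 1.5 * 1.5
  expect_gt(geom$volume, vol_sphere * 0.98)
  expect_lt(geom$volume, (vol_sphere + vol_ellip) * 1.02)
  # discrete neck diameter close to the requested one
  expect_equal(geom$neck_diam_discrete, 2, tolerance = 0.15)
  # mother volume close to the full sphere
  vol_mother <- sum(geom$compartment[geom$mask] == "mother") * geom$voxel^3
  expect_equal(vol_mother, vol_sphere, tolerance = 0.05)
  expect_error(frap_geometry(voxel = 0.5), "at most")
  expect_error(frap_geometry(neck_diam = 8), "impossible")
})

test_that("neck-diameter estimate converges under grid refinement", {
  est <- vapply(c(0.3, 0.2, 0.1), function(v)
    frap_geometry(voxel = v)$neck_diam_discrete, numeric(1))
  expect_true(all(diff(abs(est - 2)) <= 1e-9 + 0))
  expect_lt(abs(est[3] - 2), abs(est[1] - 2) + 1e-9)
})

test_that("free diffusion conserves intensity and equilibrates", {
  geom <- frap_geometry(voxel = 0.25, neck_diam = 2, ellipsoid_width = 3)
  sim <- simulate_frap(geom, D = 10, times = c(0.5, 2, 30), dt = 0.05)
  expect_lt(sim$conservation_drift, 1e-8)
  expect_true(all(sim$fields >= -1e-12))
  expect_true(all(sim$fields <= 1 + 1e-9))
  # t -> infinity: uniform at (initial total) / (number of voxels)
  expect_lt(diff(range(sim$fields[, 3])), 0.02)
  expect_equal(mean(sim$fields[, 3]), sim$initial_total / nrow(sim$fields),
               tolerance = 1e-8)
})

test_that("implicit Euler agrees with the exact semigroup of the operator", {
  # independent time integration: matrix exponential of the same masked
  # Laplacian (exact in time), versus the production implicit-Euler stepper
  geom <- frap_geometry(voxel = 0.3, neck_diam = 2, ellipsoid_width = 3)
  sim <- simulate_frap(geom, D = 2,
                       bleach = list(centre = c(0, 0), diameter = 1.2),
                       times = 0.2, dt = 0.001)
  L <- mcaspolarity:::mask_laplacian(geom)
  d <- dim(geom$mask)
  X <- array(rep(geom$xs, times = d[2] * d[3]), d)[geom$mask]
  Y <- array(rep(rep(geom$ys, each = d[1]), times = d[3]), d)[geom$mask]
  u0 <- rep(1, sum(geom$mask))
  u0[X^2 + Y^2 <= 0.6^2] <- 0
  exact <- as.numeric(Matrix::expm(0.2 * 2 * L) %*% u0)
  expect_lt(sqrt(mean((sim$fields[, 1] - exact)^2)), 1e-3)
})

test_that("cylinder-bleach spreading matches the analytic 2D solution", {
  # near the mother centre, far from walls and cylinder ends, the bleach
  # recovers like an infinite cylinder in free 2D diffusion:
  # u(r,t) = 1 - int_0^R s/(2Dt) I0(rs/(2Dt)) exp(-(r-s)^2/(4Dt)) ... ds
  geom <- frap_geometry(voxel = 0.15)
  sim <- simulate_frap(geom, D = 1,
                       bleach = list(centre = c(0, 0), diameter = 1),
                       times = 0.15, dt = 0.0025)
  d <- dim(geom$mask)
  X <- array(rep(geom$xs, times = d[2] * d[3]), d)[geom$mask]
  Y <- array(rep(rep(geom$ys, each = d[1]), times = d[3]), d)[geom$mask]
  Z <- array(rep(geom$zs, each = d[1] * d[2]), d)[geom$mask]
  sel <- X^2 + Y^2 < 1.6^2 & abs(Z) < 1
  r <- sqrt(X^2 + Y^2)[sel]
  D <- 1; t <- 0.15; R <- 0.5
  ss <- seq(1e-6, R, length.out = 400)
  exact <- vapply(r, function(ri) {
    ig <- ss / (2 * D * t) *
      besselI(ri * ss / (2 * D * t), 0, expon.scaled = TRUE) *
      exp(-(ri - ss)^2 / (4 * D * t))
    1 - sum(ig) * (ss[2] - ss[1])
  }, numeric(1))
  expect_lt(sqrt(mean((sim$fields[sel, 1] - exact)^2)), 0.01)
})

test_that("ROI measurement averages the z-summed image", {
  geom <- frap_geometry(voxel = 0.25)
  sim <- simulate_frap(geom, D = 10, times = c(50), dt = 0.1)
  # at equilibrium the field is uniform c: ROI value = c * mean column depth
  c_eq <- mean(sim$fields[, 1])
  roi <- measure_roi(sim, centre = c(0, 0), diameter = 3)
  d <- dim(geom$mask)
  depth <- apply(geom$mask, c(1, 2), sum) * geom$voxel
  px <- which(depth > 0, arr.ind = TRUE)
  inroi <- (geom$xs[px[, 1]])^2 + (geom$ys[px[, 2]])^2 <= 1.5^2
  expect_equal(roi$intensity[1], c_eq * mean(depth[px][inroi]),
               tolerance = 1e-6)
  expect_error(measure_roi(sim, centre = c(50, 0)), "intersect")
})

test_that("doubling the diffusion constant halves the recovery half-time", {
  geom <- frap_geometry(voxel = 0.25)
  half <- vapply(c(5, 10), function(D) {
    # sample over a window scaled to the dynamics (t ~ 1/D), so both runs
    # observe the same recovery phase
    sim <- simulate_frap(geom, D = D, times = seq(0.02, 1.2, 0.02) * 10 / D,
                         dt = 0.005)
    roi <- measure_roi(sim, centre = c(0, 0), diameter = 3)
    fit <- fit_frap(roi$times, roi$intensity, "recovery")
    expect_true(fit$converged)
    expect_gt(fit$r_squared, 0.98)
    fit$half_time
  }, numeric(1))
  expect_equal(half[1] / half[2], 2, tolerance = 0.05)
})

test_that("the neck constriction slows inter-compartment flux", {
  times <- seq(0.05, 4, 0.05)
  geom <- frap_geometry(voxel = 0.25)
  ns <- neck_slowdown(geom, D = 10, method = "flux", times = times, dt = 0.02)
  expect_gt(ns$slowing, 0)
  expect_lt(ns$slowing, 1)
  # the equilibration mode is a clean single exponential in both geometries
  expect_gt(ns$fits$constricted$r_squared, 0.999)
  expect_gt(ns$fits$control$r_squared, 0.999)
  # no-constriction geometry: slowing exactly zero (control equals itself)
  g0 <- frap_geometry(voxel = 0.25, ellipsoid_width = 2, neck_diam = 2)
  ns0 <- neck_slowdown(g0, D = 10, method = "flux",
                       times = seq(0.05, 3, 0.05), dt = 0.02)
  expect_equal(ns0$slowing, 0)
  # slowing grows monotonically as the neck narrows
  slow <- vapply(c(2.5, 2, 1.5), function(nd) {
    g <- frap_geometry(voxel = 0.25, ellipsoid_width = 3, neck_diam = nd)
    neck_slowdown(g, D = 10, method = "flux", times = times, dt = 0.02)$slowing
  }, numeric(1))
  expect_true(all(diff(slow) > 0))
  # the ROI protocol reports the daughter site as slower than the mother site
  nsr <- neck_slowdown(geom, D = 10, method = "roi", times = times, dt = 0.02)
  expect_gt(nsr$slowing, 0)
  expect_gt(nsr$fits$daughter$r_squared, 0.9)
})
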