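test_that("diffusion-only evolution matches the periodic heat kernel", {
  m <- diffusion_only(minimal_model(Dm = 0.05, Dc = 1))
  L <- 10; n <- 400
  g <- mcas_grid(n, L)
  x <- grid_coords(g)$x
  sigma0 <- 0.15
  st <- uniform_state(m, g, c(u = 0, v = 0))
  # narrow Gaussians evolve into heat kernels of widened variance
  for (s in c("u", "v"))
    st$fields[, s] <- exp(-(x - L / 2)^2 / (2 * sigma0^2))
  tr <- integrate_model(m, g, st, t_end = 1,
                        controls = solver_controls(dt_max = 1e-3))
  mass <- sum(st$fields[, 1]) * g$h[1]
  for (si in 1:2) {
    D <- m$species$D[si]
    # exact solution: convolution of the initial Gaussian with the kernel
    # = Gaussian of variance sigma0^2 + 2 D t (image sums for periodicity)
    exact <- mass * heat_kernel_circle(x, L / 2, D, 1 + sigma0^2 / (2 * D), L)
    rms <- sqrt(mean((tr$final$fields[, si] - exact)^2))
    expect_lt(rms, 1e-4)
  }
})

test_that("solver agrees with an independent stiff integrator", {
  skip_if_not_installed("deSolve")
  m <- minimal_model()
  L <- 10; n <- 64
  g <- mcas_grid(n, L)
  x <- grid_coords(g)$x
  st <- uniform_state(m, g, c(u = 1, v = 1))
  st$fields[, "u"] <- 1 + 0.2 * cos(2 * pi * x / L)
  st$fields[, "v"] <- 1 - 0.2 * cos(2 * pi * x / L)
  tr <- integrate_model(m, g, st, t_end = 3,
                        controls = solver_controls(rtol = 1e-6,
                                                   dt_max = 2e-3))
  # independent route: method-of-lines with deSolve's implicit lsoda
  h <- g$h[1]
  rhs <- function(t, y, parms) {
    u <- y[1:n]; v <- y[(n + 1):(2 * n)]
    lap <- function(f) (f[c(2:n, 1)] - 2 * f + f[c(n, 1:(n - 1))]) / h^2
    f <- u^2 * v - u
    list(c(f + 0.01 * lap(u), -f + lap(v)))
  }
  sol <- deSolve::ode(c(st$fields[, "u"], st$fields[, "v"]), c(0, 3), rhs,
                      NULL, method = "lsoda", rtol = 1e-10, atol = 1e-10)
  ref <- matrix(sol[2, -1], n, 2)
  expect_lt(max(abs(tr$final$fields - ref)), 2e-3)
})

test_that("a linearly stable homogeneous steady state stays put", {
  # total 12: the large-u root (u ~ 11.92) lies beyond the instability
  # window u^2 < b Dc / (a Dm), so no mode grows
  m <- minimal_model()
  g <- small_grid(128)
  u0 <- (12 + sqrt(144 - 4)) / 2
  st <- uniform_state(m, g, c(u = u0, v = 12 - u0))
  # keep the explicit reaction step within the stability bound of the
  # fast local relaxation rate (~140) so round-off is not churned
  tr <- integrate_model(m, g, st, t_end = 100,
                        controls = solver_controls(dt_max = 5e-3))
  expect_lt(max(abs(tr$final$fields[, "u"] - u0)), 1e-10 * u0)
})

test_that("run_to_steady_state returns immediately on an already-steady state", {
  m <- minimal_model()
  g <- small_grid(64)
  st <- uniform_state(m, g, c(u = 0.5, v = 2))
  res <- run_to_steady_state(m, g, st, max_time = 1000)
  expect_true(res$converged)
  expect_lt(res$state$time, 1)
})

test_that("conserved totals are computed and preserved on every model", {
  # uniform u=0, v=2 on L=10 -> total 20
  m <- minimal_model()
  g <- mcas_grid(100, 10)
  expect_equal(conserved_totals(m, g, uniform_state(m, g, c(u = 0, v = 2))),
               c(total = 20))
  # mechanistic: cytosolic fields weigh in at 1/eta
  mm <- mechanistic_model(FALSE)
  gm <- mcas_grid(c(20, 20), c(5, 5))
  stm <- uniform_state(mm, gm, c(Cdc42T = 1, Cdc42Dc = 2, BemGEFc = 0.01))
  expect_equal(conserved_totals(mm, gm, stm),
               c(Cdc42 = 25 * (1 + 200), BemGEF = 25 * 1))
  # integration drifts conserved totals only at round-off level
  for (model in all_models()) {
    grid <- if (model$name %in% c("minimal", "indirect"))
      mcas_grid(200, 10) else mcas_grid(100, 8.86)
    st <- mcas_state(random_state(model, n_points(grid),
                                  scale = if (grepl("mech", model$name)) 1 else 2,
                                  seed = 7))
    tr <- integrate_model(model, grid, st, t_end = 20)
    expect_lt(tr$conservation$rel_drift, 1e-8)
  }
})

test_that("insulated walls block flux exactly and removal restores mixing", {
  m <- diffusion_only(minimal_model())
  g <- mcas_grid(100, 10)
  wg <- insulate(g, c(50L, 100L))
  st <- uniform_state(m, g, c(u = 1, v = 1))
  st$fields[1:50, "v"] <- 3    # left half holds more substrate
  masks <- list(c(rep(TRUE, 50), rep(FALSE, 50)),
                c(rep(FALSE, 50), rep(TRUE, 50)))
  tr <- integrate_model(m, wg, st, t_end = 50)
  # per-half totals unchanged while insulated
  left_tot <- sum(tr$final$fields[1:50, "v"]) * 0.1
  expect_equal(left_tot, 3 * 50 * 0.1, tolerance = 1e-10)
  # after removing the walls the halves equilibrate to the global mean
  g2 <- remove_insulation(wg)
  expect_identical(g2$walls, integer(0))
  tr2 <- integrate_model(m, g2, tr$final, t_end = tr$final$time + 200)
  expect_lt(max(abs(tr2$final$fields[, "v"] - 2)), 1e-6)
})

test_that("mirror-symmetric initial conditions stay mirror-symmetric", {
  m <- minimal_model()
  n <- 128
  g <- mcas_grid(n, 10)
  x <- grid_coords(g)$x
  st <- uniform_state(m, g, c(u = 0.5, v = 1.5))
  bump <- exp(-(x - 5)^2)
  st$fields[, "u"] <- st$fields[, "u"] + bump
  tr <- integrate_model(m, g, st, t_end = 5)
  f <- tr$final$fields
  mirror <- function(v) v[n:1]
  # mirror axis through x = 5 maps point i to n + 1 - i
  expect_lt(max(abs(f[, "u"] - mirror(f[, "u"]))), 1e-9)
  expect_lt(max(abs(f[, "v"] - mirror(f[, "v"]))), 1e-9)
})

test_that("halving the grid spacing changes the peak amplitude by < 1%", {
  m <- minimal_model()
  amp <- vapply(c(500, 1000), function(n) {
    prep <- prepare_single_peak(m, mcas_grid(n, 10), 1, seed = 3)
    prep$peaks$amplitude[1]
  }, numeric(1))
  expect_lt(abs(amp[2] - amp[1]) / amp[1], 0.01)
})

test_that("negative states and invalid grids are rejected", {
  expect_error(mcas_grid(100, 10, walls = 200L), "within the domain")
  m <- minimal_model()
  g <- small_grid(32)
  st <- uniform_state(m, g, c(u = 1, v = 1))
  expect_error(integrate_model(m, g, st, t_end = 0), "exceed")
})
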