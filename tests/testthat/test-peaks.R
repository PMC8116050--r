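test_that("peak detection handles bumps, doublets and flat fields", {
  g <- mcas_grid(200, 10)
  x <- grid_coords(g)$x
  # single raised cosine: one peak at its centre, mass fraction 1
  f <- ifelse(abs(x - 5) < 1, 1 + cos(pi * (x - 5)), 0)
  ps <- detect_peaks(f, g)
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$position, 5, tolerance = g$h[1])
  expect_equal(ps$fraction, 1)
  # two Gaussians with 3:1 mass on a flat background
  f2 <- 0.1 + 3 * exp(-(x - 2.5)^2 / 0.08) + exp(-(x - 7.5)^2 / 0.08)
  ps2 <- detect_peaks(f2, g)
  expect_equal(nrow(ps2), 2L)
  masses <- ps2$mass / sum(ps2$mass)
  bg <- 0.1 * 5            # background splits evenly between the regions
  gm <- 3 * sqrt(0.08 * pi) # Gaussian masses
  expect_equal(sort(ps2$fraction),
               sort(c(gm / 3 + bg, gm + bg) / (gm / 3 + gm + 2 * bg)),
               tolerance = 1e-3)
  # watershed boundary at the inter-peak minimum: regions tile the domain
  regs <- attr(ps2, "regions")
  expect_equal(sort(unlist(regs)), seq_len(200))
  expect_equal(sum(ps2$mass), sum(f2) * g$h[1], tolerance = 1e-12)
  # constant field: no peaks
  expect_equal(nrow(detect_peaks(rep(2, 200), g)), 0L)
})

test_that("2D peak detection assigns basins and fractions", {
  g <- mcas_grid(c(40, 40), c(10, 10))
  co <- grid_coords(g)
  X <- matrix(rep(co$x, 40), 40, 40)
  Y <- matrix(rep(co$y, each = 40), 40, 40)
  f <- as.vector(3 * exp(-((X - 2.5)^2 + (Y - 5)^2) / 0.5) +
                 exp(-((X - 7.5)^2 + (Y - 5)^2) / 0.5)) + 0.05
  ps <- detect_peaks(f, g)
  expect_equal(nrow(ps), 2L)
  expect_equal(sum(ps$fraction), 1)
  expect_equal(sort(unlist(attr(ps, "regions"))), seq_len(1600))
  expect_gt(max(ps$fraction), 0.6)
})

test_that("basal level reads the substrate outside the dip", {
  g <- mcas_grid(200, 10)
  x <- grid_coords(g)$x
  act <- ifelse(abs(x - 5) < 1, 1 + cos(pi * (x - 5)), 0)
  sub <- 0.8 - 0.5 * exp(-(x - 5)^2 / 0.5)   # dip mirroring the peak
  ps <- detect_peaks(act, g)
  expect_equal(basal_level(sub, ps), 0.8, tolerance = 1e-6)
  # narrow region errors
  ps_narrow <- ps
  attr(ps_narrow, "regions") <- list(100:101)
  expect_error(basal_level(sub, ps_narrow), "3 grid points")
})

test_that("competition time interpolates the 70:30 and 99:1 crossings", {
  tt <- seq(0, 200, 5)
  f1 <- pmin(0.6 + 0.004 * tt, 1)   # crosses 0.70 at t=25, 0.99 at t=97.5
  tr <- synthetic_competition_trace(tt, cbind(f1, 1 - f1))
  ct <- competition_time(tr)
  expect_equal(as.numeric(ct), 97.5 - 25, tolerance = 1e-10)
  # frozen fractions: undefined with a reason
  tr2 <- synthetic_competition_trace(tt, cbind(rep(0.6, 41), rep(0.4, 41)))
  ct2 <- competition_time(tr2)
  expect_true(is.na(ct2))
  expect_match(attr(ct2, "reason"), "70:30")
  # reaching 70:30 but not 99:1 before the end is censored
  f3 <- pmin(0.6 + 0.001 * tt, 1)
  ct3 <- competition_time(synthetic_competition_trace(tt, cbind(f3, 1 - f3)))
  expect_true(is.na(ct3))
  expect_match(attr(ct3, "reason"), "99:1")
})

test_that("outcome classification implements the phase-diagram rules", {
  tt <- seq(0, 2000, 10)
  n <- length(tt)
  ramp <- function(to, from = 0.6, t_half = 300)
    from + (to - from) * pmin(tt / t_half, 1)
  lab <- function(trace) classify_outcome(trace)$label
  # -> (1, 0): competition
  f <- ramp(1)
  expect_equal(lab(synthetic_competition_trace(tt, cbind(f, 1 - f))),
               "competition")
  # -> (0.5, 0.5): equalization
  f <- ramp(0.5)
  expect_equal(lab(synthetic_competition_trace(tt, cbind(f, 1 - f))),
               "equalization")
  # frozen at (0.58, 0.42): coexistence
  f <- rep(0.58, n)
  expect_equal(lab(synthetic_competition_trace(tt, cbind(f, 1 - f))),
               "coexistence")
  # a third peak appearing: peaks_split
  f3 <- cbind(rep(0.5, n), rep(0.5, n), rep(NA, n))
  f3[tt >= 1000, ] <- rep(c(0.4, 0.4, 0.2), each = sum(tt >= 1000))
  expect_equal(lab(synthetic_competition_trace(tt, f3)), "peaks_split")
  # flat activator field: homogeneous
  f0 <- matrix(NA_real_, n, 1)
  expect_equal(lab(synthetic_competition_trace(tt, f0, final_range_rel = 1e-6)),
               "homogeneous")
  # still drifting at t_max: censored coexistence
  f <- 0.6 + 0.1 * tt / 2000
  out <- classify_outcome(synthetic_competition_trace(tt, cbind(f, 1 - f),
                                                      steady = FALSE))
  expect_equal(out$label, "coexistence")
  expect_true(out$censored)
})

test_that("peak tracking keeps identities across frames", {
  # build a small trajectory-like object: two bumps whose masses swap slowly
  g <- mcas_grid(120, 12)
  x <- grid_coords(g)$x
  times <- 0:10
  arr <- array(0, c(120, 2, length(times)),
               dimnames = list(NULL, c("u", "v"), NULL))
  for (i in seq_along(times)) {
    w <- 0.75 - 0.02 * times[i]
    arr[, 1, i] <- w * exp(-(x - 3)^2 / 0.3) +
      (1 - w) * exp(-(x - 9)^2 / 0.3) + 0.01
    arr[, 2, i] <- 1
  }
  traj <- structure(list(model = "minimal", grid = g, times = times,
                         states = arr,
                         final = mcas_state(arr[, , 11], time = 10),
                         steady = FALSE),
                    class = "mcas_trajectory")
  trace <- competition_trace(traj, minimal_model())
  expect_equal(ncol(trace$fractions), 2L)
  # fractions evolve monotonically without label switches
  expect_true(all(diff(trace$fractions[, 1]) < 0) ||
                all(diff(trace$fractions[, 1]) > 0))
  expect_equal(rowSums(trace$fractions), rep(1, 11), tolerance = 1e-12)
})
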