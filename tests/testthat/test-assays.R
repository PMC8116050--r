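test_that("initial conditions hit requested totals exactly and reproducibly", {
  m <- minimal_model()
  g <- mcas_grid(128, 10)
  one_x <- model_1x_totals(m) * 10   # totals scale with domain length
  # amplitude 0: exact homogeneous state
  st0 <- noisy_initial_condition(m, g, 1.2, amplitude = 0, seed = 1)
  expect_equal(diff(range(st0$fields[, "v"])), 0)
  # noisy: totals renormalized to the request at machine precision
  st1 <- noisy_initial_condition(m, g, 1.2, amplitude = 0.01, seed = 1)
  expect_equal(unname(conserved_totals(m, g, st1)), unname(one_x * 1.2),
               tolerance = 1e-12)
  expect_gt(diff(range(st1$fields[, "v"])), 0)
  # same seed -> identical fields; different seed -> different
  st2 <- noisy_initial_condition(m, g, 1.2, amplitude = 0.01, seed = 1)
  expect_identical(st1$fields, st2$fields)
  st3 <- noisy_initial_condition(m, g, 1.2, amplitude = 0.01, seed = 2)
  expect_false(identical(st1$fields, st3$fields))
  # amplitude validation
  expect_error(noisy_initial_condition(m, g, 1, amplitude = 0.5), "amplitude")
  # seeded bump route conserves totals exactly as well
  st4 <- seeded_initial_condition(m, g, 0.6, seed = 3)
  expect_equal(unname(conserved_totals(m, g, st4)), unname(one_x * 0.6),
               tolerance = 1e-12)
  # mechanistic: both groups exact
  mm <- mechanistic_model(FALSE)
  gm <- mcas_grid(64, 8.86)
  stm <- seeded_initial_condition(mm, gm, 1, seed = 3)
  expect_equal(unname(conserved_totals(mm, gm, stm)),
               unname(model_1x_totals(mm) * 8.86), tolerance = 1e-10)
})

test_that("single-peak preparation polarizes at 1x and reports sub-critical amounts", {
  m <- minimal_model()
  g <- mcas_grid(256, 10)
  prep <- prepare_single_peak(m, g, 1, seed = 2, max_time = 1000)
  expect_false(prep$no_peak)
  expect_equal(nrow(prep$peaks), 1L)
  # basal substrate is depleted below the starting uniform concentration 2
  basal <- basal_level(prep$state$fields[, "v"], prep$peaks)
  expect_lt(basal, 2)
  expect_gt(prep$peaks$amplitude, 2)
  # identical seeds give bit-identical preparations
  prep2 <- prepare_single_peak(m, g, 1, seed = 2, max_time = 1000)
  expect_identical(prep$state$fields, prep2$state$fields)
  # 100x below 1x: no peak; linear stability confirms no unstable mode
  prep0 <- prepare_single_peak(m, g, 0.01, seed = 2, max_time = 200)
  expect_true(prep0$no_peak)
  hss <- homogeneous_steady_state(m, model_1x_totals(m) * 0.01)
  expect_length(hss, 1)      # only the trivial all-substrate root
  qs <- 2 * pi * (1:20) / 10
  lam <- vapply(qs, function(q) {
    J <- mcaspolarity:::reaction_jacobian(m, unclass(hss[[1]]))
    max(Re(eigen(J - q^2 * diag(m$species$D), only.values = TRUE)$values))
  }, numeric(1))
  expect_true(all(lam <= 1e-12))
})

test_that("insulated two-half preparations conserve and add their amounts", {
  m <- minimal_model()
  g <- mcas_grid(128, 10)
  prep <- mcaspolarity:::prepare_two_halves(m, g, c(0.6, 1), seed = 1,
                                            amplitude = 0.01,
                                            controls = solver_controls(),
                                            max_time = 800)
  expect_true(all(vapply(prep$halves, function(h) nrow(h$peaks), 1L) == 1L))
  # per-half totals: amounts in units of 1x over half the domain
  halves <- mcaspolarity:::subdomain_totals(m, prep$grid, prep$state)
  expect_equal(unname(halves[[1]]), 0.6 * 2 * 5, tolerance = 1e-8)
  expect_equal(unname(halves[[2]]), 1.0 * 2 * 5, tolerance = 1e-8)
  # wall removal changes nothing about the global total
  tot <- conserved_totals(m, remove_insulation(prep$grid), prep$state)
  expect_equal(unname(tot), 0.6 * 10 + 1 * 10, tolerance = 1e-8)
})

test_that("the basal difference vanishes for symmetric amounts", {
  m <- indirect_model()
  g <- mcas_grid(128, 10)
  bp <- basal_difference_predictor(m, amounts = c(1, 1), grid = g, seed = 4,
                                   prep_max_time = 800)
  expect_lt(abs(bp$delta_v), 1e-4)
  expect_equal(bp$predicted, "coexistence")
})

test_that("competition assay validates its inputs", {
  m <- minimal_model()
  expect_error(competition_assay(m, amounts = c(1, -1)), "amounts")
  expect_error(competition_assay(m, amounts = c(0.005, 0.005),
                                 grid = mcas_grid(64, 10),
                                 prep_max_time = 100),
               "failed to form a peak")
})
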