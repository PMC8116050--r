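test_that("minimal model kinetics match direct substitution", {
  m <- minimal_model()
  expect_equal(reaction_rates(m, c(u = 1, v = 1)), c(u = 0, v = 0))
  expect_equal(reaction_rates(m, c(u = 2, v = 2)), c(u = 6, v = -6))
  # validation
  expect_error(minimal_model(a = -1), "positive")
  expect_error(minimal_model(Dm = 2, Dc = 1), "slower")
})

test_that("indirect model kinetics match direct substitution", {
  m <- indirect_model()
  expect_equal(reaction_rates(m, c(u = 1, v = 1, vi = 0)),
               c(u = -0.01, v = 0, vi = 0.01))
  expect_equal(reaction_rates(m, c(u = 0, v = 0, vi = 1)),
               c(u = 0, v = 1, vi = -1))
})

test_that("reaction kinetics conserve every group over random states", {
  for (model in all_models()) {
    states <- random_state(model, npts = 1000, scale = 5,
                           seed = match(model$name, names(all_models())))
    expect_lt(group_rate_residual(model, states), 1e-12)
  }
})

test_that("mechanistic exchange-only steady state has zero rates", {
  m <- mechanistic_model(FALSE)
  p <- m$params
  st <- c(Cdc42T = 0, Cdc42Dm = 1, BemGEF42 = 0, BemGEFm = 0,
          Cdc42Dc = p$k5b / p$k5a * 1, BemGEFc = 0)
  expect_equal(max(abs(reaction_rates(m, st))), 0, tolerance = 1e-15)
})

test_that("NFB phosphorylation rate is a bounded increasing Hill function", {
  m <- mechanistic_model(TRUE)
  p <- m$params
  # with only BemGEF42 / BemGEF42_p populated, k8 can be read back from the
  # BemGEF42_p production term: rate = k8 * B42t * B42 (plus the k4b decay)
  k8_of <- function(B42, B42p) {
    st <- setNames(numeric(9), m$species$name)
    st["BemGEF42"] <- B42; st["BemGEF42_p"] <- B42p
    r <- reaction_rates(m, st)
    (r[["BemGEF42_p"]] + p$k4b * B42p) / ((B42 + B42p) * B42)
  }
  x <- c(0.5, 1, 5, 10, 20, 100, 1000)
  k8v <- vapply(x, function(b) k8_of(b, 0), numeric(1))
  expect_true(all(diff(k8v) > 0))
  expect_true(all(k8v <= p$k8max))
  # saturating limit -> k8max = 0.0063
  expect_equal(k8_of(1e6, 0), 0.0063, tolerance = 1e-6)
  # half-saturation at k8h
  expect_equal(k8_of(p$k8h, 0), p$k8max / 2, tolerance = 1e-9)
})

test_that("NFB dephosphorylation rate is bounded by k9max and increasing", {
  m <- mechanistic_model(TRUE)
  p <- m$params
  k9_of <- function(Bcp) {
    st <- setNames(numeric(9), m$species$name)
    st["BemGEFc_p"] <- Bcp
    r <- reaction_rates(m, st)
    r[["BemGEFc"]] / Bcp
  }
  x <- c(1e-4, 3e-4, 1e-3, 3e-3, 1e-2, 1)
  k9v <- vapply(x, k9_of, numeric(1))
  expect_true(all(diff(k9v) > 0))
  expect_true(all(k9v <= p$k9max))
  expect_equal(k9_of(p$k9h), p$k9max / 2, tolerance = 1e-9)
})

test_that("minimal-model homogeneous roots satisfy u v = b/a exactly", {
  m <- minimal_model()
  roots <- homogeneous_steady_state(m, c(total = 2.5))
  nontriv <- roots[-1]
  expect_length(nontriv, 2)
  us <- vapply(nontriv, `[[`, numeric(1), "u")
  vs <- vapply(nontriv, `[[`, numeric(1), "v")
  expect_equal(sort(us), c(0.5, 2))
  expect_equal(us * vs, rep(1, 2))          # u v = b / a, exact
  expect_equal(us + vs, rep(2.5, 2))
  # T = 2: double root at (1, 1)
  r2 <- homogeneous_steady_state(m, c(total = 2))
  expect_equal(r2[[2]][["u"]], 1)
  # sub-critical: only the trivial root
  expect_length(homogeneous_steady_state(m, c(total = 1)), 1)
})

test_that("indirect-model homogeneous roots zero the kinetics", {
  m <- indirect_model()
  roots <- homogeneous_steady_state(m, c(total = 2.5))
  for (r in roots)
    expect_lt(max(abs(reaction_rates(m, unclass(r)))), 1e-12)
})

test_that("mechanistic steady state with zero BemGEF has no active Cdc42", {
  m <- mechanistic_model(FALSE)
  h <- homogeneous_steady_state(m, c(Cdc42 = 500, BemGEF = 0))[[1]]
  expect_lt(max(abs(reaction_rates(m, unclass(h)))), 1e-10)
  expect_equal(h[["Cdc42T"]], 0, tolerance = 1e-12)
  expect_equal(h[["BemGEFc"]], 0, tolerance = 1e-12)
})

test_that("linear stability analysis matches the analytic 2x2 eigenvalues", {
  m <- minimal_model()
  hss <- homogeneous_steady_state(m, c(total = 2.5))[[3]]  # (2, 0.5)
  expect_equal(unname(hss[["u"]]), 2)
  # q = 0: eigenvalues {0, -3} (trace -3, det 0 of [[1,4],[-1,-4]])
  ev0 <- attr(linear_growth_rate(m, hss, 0), "eigenvalues")[[1]]
  expect_equal(sort(Re(ev0)), c(-3, 0), tolerance = 1e-8)
  # analytic instability window 0 < q^2 < 96
  qs <- sqrt(c(10, 95, 97, 150))
  lg <- linear_growth_rate(m, hss, qs)
  expect_true(lg[1] > 0 && lg[2] > 0)
  expect_true(lg[3] < 0 && lg[4] < 0)
  # oracle: characteristic-polynomial roots of J - q^2 D
  char_max <- function(q) {
    J <- matrix(c(1, -1, 4, -4), 2, 2)
    M <- J - q^2 * diag(c(0.01, 1))
    tr <- sum(diag(M)); dt <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
    max(Re((tr + c(-1, 1) * sqrt(as.complex(tr^2 - 4 * dt))) / 2))
  }
  expect_equal(lg, vapply(qs, char_max, numeric(1)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # non-steady input is rejected
  expect_error(linear_growth_rate(m, structure(c(u = 1, v = 2.5),
                                               class = "mcas_hss"), 1),
               "not a steady state")
})

test_that("model configuration rejects unknown parameters", {
  expect_error(mechanistic_model(params = list(k99 = 1)), "unknown")
  expect_error(mechanistic_model(params = list(eta = 2)), "eta")
})
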