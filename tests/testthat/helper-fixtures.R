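# Shared helpers: small grids, random states, and closed-form oracles.

all_models <- function() list(
  minimal = minimal_model(),
  indirect = indirect_model(),
  mechanistic = mechanistic_model(FALSE),
  mechanistic_nfb = mechanistic_model(TRUE))

small_grid <- function(n = 64, length = 10, ...) mcas_grid(n, length, ...)

# random nonnegative state matrix for a model (concentration scale ~ scale)
random_state <- function(model, npts = 10, scale = 2, seed = 1) {
  set.seed(seed)
  nm <- model$species$name
  matrix(runif(npts * length(nm), 0, scale), npts, length(nm),
         dimnames = list(NULL, nm))
}

# closed-form heat kernel on a circle of circumference L (image sums)
heat_kernel_circle <- function(x, x0, D, t, L, n_images = 20) {
  out <- numeric(length(x))
  for (m in -n_images:n_images)
    out <- out + exp(-(x - x0 + m * L)^2 / (4 * D * t))
  out / sqrt(4 * pi * D * t)
}

# weighted conservation-group residual of reaction rates (max abs)
group_rate_residual <- function(model, states) {
  r <- reaction_rates(model, states)
  nm <- model$species$name
  max(vapply(model$groups, function(w) {
    idx <- match(names(w), nm)
    max(abs(r[, idx, drop = FALSE] %*% w)) /
      max(abs(r), 1e-300)
  }, numeric(1)))
}
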