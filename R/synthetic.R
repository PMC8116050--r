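# Synthetic inputs: every input the pipeline needs is generated in code --
# perturbed fields, exponential FRAP traces with known ground truth, and
# schedule-driven competition traces for exercising the classifier.

# evaluate expr under a local, seeded RNG without disturbing global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Noise-perturbed homogeneous initial condition
#'
#' Builds the standardized symmetry-breaking initial condition: the
#' (least-activated non-trivial) homogeneous steady state for the requested
#' amount, with seeded multiplicative uniform noise applied to the substrate
#' field(s), then renormalized so every conserved group total matches the
#' request exactly. With `amplitude = 0` the exact homogeneous state is
#' returned. If no non-trivial homogeneous root exists (sub-critical
#' amount), the all-substrate state is used.
#'
#' @param model An `mcas_model`.
#' @param grid An `mcas_grid`.
#' @param amount Amount multiplier in units of the model's "1x" composition
#'   (see [model_1x_totals()]).
#' @param amplitude Relative noise amplitude in (0, 0.1] (default 0.01).
#' @param seed Integer seed.
#' @param mask Optional logical vector of grid points to fill (default all);
#'   other points are left at zero, for insulated-subdomain preparations.
#' @return An `mcas_state`.
#' @export
noisy_initial_condition <- function(model, grid, amount, amplitude = 0.01,
                                    seed = 1L, mask = NULL) {
  if (amplitude < 0 || amplitude > 0.1)
    stop("noise amplitude must lie in [0, 0.1]")
  nm <- model$species$name
  totals <- model_1x_totals(model) * amount
  roots <- homogeneous_steady_state(model, totals)
  base <- if (length(roots) > 1L) roots[[2]] else roots[[1]]
  np <- n_points(grid)
  if (is.null(mask)) mask <- rep(TRUE, np)
  fields <- matrix(0, np, length(nm), dimnames = list(NULL, nm))
  for (s in nm) fields[mask, s] <- base[[s]]
  if (amplitude > 0) {
    noise <- with_seed(seed, matrix(runif(sum(mask) * length(model$substrates),
                                          -amplitude, amplitude),
                                    ncol = length(model$substrates)))
    for (j in seq_along(model$substrates))
      fields[mask, model$substrates[j]] <-
        fields[mask, model$substrates[j]] * (1 + noise[, j])
  }
  # renormalize each group by rescaling its substrate members so the
  # masked-region total is exact
  cv <- cell_volume(grid)
  for (g in names(model$groups)) {
    w <- model$groups[[g]]
    target <- totals[[g]] * sum(mask) * cv
    subs <- intersect(names(w), model$substrates)
    fixed <- setdiff(names(w), subs)
    tot_fixed <- sum(vapply(fixed, function(s)
      w[[s]] * sum(fields[mask, s]), numeric(1))) * cv
    tot_subs <- sum(vapply(subs, function(s)
      w[[s]] * sum(fields[mask, s]), numeric(1))) * cv
    if (tot_subs > 0)
      for (s in subs)
        fields[mask, s] <- fields[mask, s] * (target - tot_fixed) / tot_subs
  }
  mcas_state(fields)
}

#' Localized-seed initial condition
#'
#' Initial condition for preparing a single polarized peak on the
#' subcritical branch: a raised-cosine activator bump at the (sub)domain
#' centre holding a fraction `phi` of each conserved group's mass, the
#' remainder spread uniformly over the substrate. Unlike the noise-only
#' preparation this reaches the polarized steady state also below the
#' Turing onset, where a finite-amplitude stimulus is required. Group
#' totals match the request exactly.
#'
#' @inheritParams noisy_initial_condition
#' @param phi Mass fraction placed in the bump (default 0.5).
#' @param width_frac Bump width as a fraction of the (sub)domain length
#'   (default 0.2).
#' @return An `mcas_state`.
#' @export
seeded_initial_condition <- function(model, grid, amount, seed = 1L,
                                     amplitude = 0.01, phi = 0.5,
                                     width_frac = 0.2, mask = NULL) {
  nm <- model$species$name
  totals <- model_1x_totals(model) * amount
  np <- n_points(grid)
  if (is.null(mask)) mask <- rep(TRUE, np)
  # bump species carrying each group's seeded mass (activator-side,
  # chosen so no species is shared between groups)
  bump_sp <- switch(model$name,
    minimal = c(total = "u"),
    indirect = c(total = "u"),
    c(Cdc42 = "Cdc42T", BemGEF = "BemGEFm"))
  sub_sp <- switch(model$name,
    minimal = c(total = "v"),
    indirect = c(total = "v"),
    c(Cdc42 = "Cdc42Dc", BemGEF = "BemGEFc"))
  xs <- rep(grid_coords(grid)$x, times = grid$n[2])
  xm <- xs[mask]
  x0 <- (min(xm) + max(xm)) / 2
  w <- width_frac * (max(xm) - min(xm) + grid$h[1])
  shape <- ifelse(abs(xm - x0) < w / 2,
                  (1 + cos(2 * pi * (xm - x0) / w)) / 2, 0)
  fields <- matrix(0, np, length(nm), dimnames = list(NULL, nm))
  cv <- cell_volume(grid)
  for (g in names(model$groups)) {
    wts <- model$groups[[g]]
    target_mass <- totals[[g]] * sum(mask) * cv
    bsp <- bump_sp[[g]]; ssp <- sub_sp[[g]]
    bump_field <- shape / (sum(shape) * cv) * phi * target_mass
    fields[mask, bsp] <- fields[mask, bsp] + bump_field / wts[[bsp]]
    fields[mask, ssp] <- fields[mask, ssp] +
      (1 - phi) * target_mass / (sum(mask) * cv) / wts[[ssp]]
  }
  if (amplitude > 0) {
    noise <- with_seed(seed, runif(sum(mask), -amplitude, amplitude))
    for (g in names(model$groups)) {
      ssp <- sub_sp[[g]]
      tot_before <- sum(fields[mask, ssp])
      fields[mask, ssp] <- fields[mask, ssp] * (1 + noise)
      fields[mask, ssp] <- fields[mask, ssp] *
        tot_before / sum(fields[mask, ssp])
    }
  }
  mcas_state(fields)
}

#' Synthetic FRAP trace with known ground truth
#'
#' Generates an intensity time series from one of the exponential fit
#' models (`decay`: `a e^{-k t} + c`; `recovery`: `-a e^{-k t} + c`;
#' `two_term`: `a e^{-k t} + b e^{k2 t} + d`) plus seeded additive Gaussian
#' noise, with the generating parameters stored alongside.
#'
#' @param model_kind One of `"decay"`, `"recovery"`, `"two_term"`.
#' @param true_params Named list of generating parameters (`a`, `k`, `c`,
#'   and for `two_term` also `b`, `k2`, `d`).
#' @param noise_sigma Gaussian noise standard deviation.
#' @param n_points Number of samples (>= 6).
#' @param seed Integer seed.
#' @param times Sample times (default `seq(0, 10, length.out = n_points)`).
#' @param spacing `"uniform"` (default) or `"geometric"`, mimicking
#'   acquisition schedules that sample densely at early times.
#' @return List of class `frap_trace`: `times`, `intensity`, `truth`.
#' @export
synthetic_frap_trace <- function(model_kind = c("decay", "recovery", "two_term"),
                                 true_params, noise_sigma = 0, n_points = 15,
                                 seed = 1L, times = NULL,
                                 spacing = c("uniform", "geometric")) {
  model_kind <- match.arg(model_kind)
  spacing <- match.arg(spacing)
  if (n_points < 6) stop("need at least 6 samples")
  p <- true_params
  if (is.null(p$k) || p$k <= 0) stop("true rate constant k must be > 0")
  if (is.null(times)) {
    t_end <- 5 / p$k
    times <- if (spacing == "uniform") seq(0, t_end, length.out = n_points)
      else t_end * (exp(seq(0, 1, length.out = n_points) * log(21)) - 1) / 20
  }
  y <- switch(model_kind,
    decay = p$a * exp(-p$k * times) + p$c,
    recovery = -p$a * exp(-p$k * times) + p$c,
    two_term = p$a * exp(-p$k * times) + p$b * exp(p$k2 * times) + p$d)
  if (noise_sigma > 0)
    y <- y + with_seed(seed, rnorm(length(times), 0, noise_sigma))
  structure(list(times = times, intensity = y,
                 truth = c(list(model_kind = model_kind), p)),
            class = "frap_trace")
}

#' Synthetic competition trace from a fraction schedule
#'
#' Builds a `competition_trace` directly from a piecewise schedule of peak
#' mass fractions, for exercising the outcome classifier on every label
#' (including censored and peaks-split edge cases) without running the PDE.
#'
#' @param times Sample times.
#' @param fractions Matrix (length(times) x n_peaks) of mass fractions;
#'   `NA` before a peak appears or where no peaks exist.
#' @param steady Whether the trace ended at steady state (default TRUE).
#' @param final_range_rel Relative activator range at the end (default 1;
#'   set below the homogeneity epsilon to emulate a flat field).
#' @return A `competition_trace`.
#' @export
synthetic_competition_trace <- function(times, fractions, steady = TRUE,
                                        final_range_rel = 1) {
  fractions <- as.matrix(fractions)
  stopifnot(nrow(fractions) == length(times))
  count <- apply(fractions, 1, function(r) sum(!is.na(r) & r > 0))
  structure(list(times = times, fractions = fractions,
                 peak_count = count, initial_count = count[1],
                 steady = steady, final_range_rel = final_range_rel),
            class = "competition_trace")
}

#' Named fixtures: model parameter tables and assay presets
#'
#' Returns the catalogue of canned parameter sets (the four model tables)
#' and named assay presets (paired subsystem amounts and the phase-diagram
#' sweep template) shipped with the package as YAML.
#'
#' @param name Optional fixture name; omitted returns the whole catalogue.
#' @return A list (the catalogue or the named entry).
#' @export
mcas_fixtures <- function(name = NULL) {
  path <- system.file("extdata", "fixtures.yaml", package = "mcaspolarity",
                      mustWork = TRUE)
  cat_ <- yaml::read_yaml(path)
  if (is.null(name)) return(cat_)
  for (section in cat_) if (name %in% names(section)) return(section[[name]])
  stop("unknown fixture: ", name)
}
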