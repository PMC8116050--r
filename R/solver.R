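#' Finite-difference grid
#'
#' Regular 1D or 2D grid for the IMEX solver. Internal no-flux walls can be
#' placed on x-interfaces to insulate subdomains (see [insulate()]).
#'
#' @param n Points per axis: a scalar (1D, default 500) or length-2 vector
#'   (2D, e.g. `c(100, 100)`).
#' @param length Domain length per axis (scalar or length-2). Defaults to 10
#'   (dimensionless models); mechanistic models use um.
#' @param bc Outer boundary condition, `"periodic"` (default) or `"no-flux"`.
#' @param walls Integer interface indices `i` (1-based) placing a no-flux
#'   wall between grid columns `i` and `i + 1`; `i = n[1]` denotes the
#'   periodic seam.
#' @return An object of class `mcas_grid` with fields `n`, `length`, `h`
#'   (spacing), `bc`, `walls`, `dim`.
#' @export
mcas_grid <- function(n = 500, length = 10, bc = c("periodic", "no-flux"),
                      walls = integer()) {
  bc <- match.arg(bc)
  n <- as.integer(n)
  if (base::length(n) == 1L) n <- c(n, 1L)
  if (base::length(length) == 1L)
    length <- c(length, if (n[2] > 1L) length else 0)
  if (any(n < 1L)) stop("grid must have at least one point per axis")
  h <- c(length[1] / n[1], if (n[2] > 1L) length[2] / n[2] else 1)
  if (any(h[n > 1L] <= 0)) stop("grid spacing must be positive")
  walls <- sort(unique(as.integer(walls)))
  if (base::length(walls) && (min(walls) < 1L || max(walls) > n[1]))
    stop("wall interfaces must lie within the domain")
  structure(list(n = n, length = length, h = h, bc = bc, walls = walls,
                 dim = if (n[2] > 1L) 2L else 1L),
            class = "mcas_grid")
}

#' @export
print.mcas_grid <- function(x, ...) {
  cat(sprintf("%dD grid: %s points, length %s, %s boundaries",
              x$dim, paste(x$n[seq_len(x$dim)], collapse = " x "),
              paste(signif(x$length[seq_len(x$dim)], 4), collapse = " x "),
              x$bc))
  if (length(x$walls)) cat(", walls at interfaces",
                           paste(x$walls, collapse = ", "))
  cat("\n")
  invisible(x)
}

n_points <- function(grid) prod(grid$n)

cell_volume <- function(grid) if (grid$dim == 2L) grid$h[1] * grid$h[2] else grid$h[1]

#' Grid coordinates
#'
#' Cell-center coordinates along the first axis (and second for 2D grids).
#' @param grid An `mcas_grid`.
#' @return List with numeric vectors `x` (and `y` for 2D grids).
#' @export
grid_coords <- function(grid) {
  out <- list(x = (seq_len(grid$n[1]) - 0.5) * grid$h[1])
  if (grid$dim == 2L) out$y <- (seq_len(grid$n[2]) - 0.5) * grid$h[2]
  out
}

#' Insulate subdomains with internal no-flux walls
#'
#' Returns a copy of the grid whose diffusion operator has zero flux across
#' the given x-interfaces, partitioning the domain into insulated
#' subdomains; per-subdomain species totals are conserved while the walls
#' are in place. [remove_insulation()] restores the original operator
#' exactly (walls modify operator coefficients only, no state is touched).
#'
#' @param grid An `mcas_grid`.
#' @param walls Interface indices as in [mcas_grid()].
#' @return The modified grid.
#' @export
insulate <- function(grid, walls) {
  mcas_grid_update(grid, walls = sort(unique(c(grid$walls, as.integer(walls)))))
}

#' @rdname insulate
#' @export
remove_insulation <- function(grid) mcas_grid_update(grid, walls = integer())

mcas_grid_update <- function(grid, walls) {
  mcas_grid(n = grid$n[seq_len(grid$dim)],
            length = grid$length[seq_len(grid$dim)],
            bc = grid$bc, walls = walls)
}

# interfaces that split the domain into two equal insulated halves
half_split_walls <- function(grid) {
  nx <- grid$n[1]
  if (nx %% 2L != 0L) stop("need an even number of x points to split in half")
  if (grid$bc == "periodic") c(nx %/% 2L, nx) else nx %/% 2L
}

# logical index of the subdomain left of the first wall
subdomain_masks <- function(grid) {
  nx <- grid$n[1]
  w <- setdiff(grid$walls, nx)
  xs <- rep(seq_len(nx), times = grid$n[2])
  if (length(w) == 0L) return(list(rep(TRUE, n_points(grid))))
  bounds <- c(0L, w, nx)
  lapply(seq_len(length(bounds) - 1L), function(i)
    xs > bounds[i] & xs <= bounds[i + 1L])
}

#' Field state on a grid
#'
#' Bundles a time point with per-species concentration fields (matrix of
#' `n_points x n_species`, columns named by species).
#' @param fields Numeric matrix of concentrations.
#' @param time Time stamp (default 0).
#' @return An `mcas_state`.
#' @export
mcas_state <- function(fields, time = 0) {
  structure(list(time = time, fields = as.matrix(fields)),
            class = "mcas_state")
}

#' Spatially uniform state
#'
#' @param model An `mcas_model`.
#' @param grid An `mcas_grid`.
#' @param conc Named concentrations (missing species default to 0); defaults
#'   to the model's "1x" reference composition.
#' @param time Time stamp.
#' @return An `mcas_state`.
#' @export
uniform_state <- function(model, grid, conc = model$one_x, time = 0) {
  nm <- model$species$name
  full <- setNames(numeric(length(nm)), nm)
  full[names(conc)] <- conc
  mcas_state(matrix(rep(full, each = n_points(grid)), ncol = length(nm),
                    dimnames = list(NULL, nm)), time = time)
}

#' Solver controls
#'
#' Tolerances and step bounds for the adaptive IMEX integrator. The step is
#' accepted when the step-doubling estimate of the relative error in the
#' reaction term is below `rtol`; it halves on rejection and at most doubles
#' on success.
#'
#' @param rtol Relative reaction-error tolerance per step (default 1e-4).
#' @param dt_init,dt_min,dt_max Initial / minimum / maximum step.
#' @param steady_tol Steady-state tolerance: converged when the maximum
#'   rate of change, relative to each field's scale, drops below this
#'   (default 1e-8).
#' @param max_steps Step budget before aborting.
#' @param neg_tol Tolerated relative undershoot below zero (default 1e-9);
#'   larger negativity triggers step reduction, never clamping.
#' @return A list of class `solver_controls`.
#' @export
solver_controls <- function(rtol = 1e-4, dt_init = 1e-3, dt_min = 1e-10,
                            dt_max = 1, steady_tol = 1e-8, max_steps = 5e7,
                            neg_tol = 1e-9) {
  stopifnot(rtol > 0, dt_min > 0, dt_min <= dt_max, steady_tol > 0,
            neg_tol >= 0)
  structure(list(rtol = rtol, dt_init = dt_init, dt_min = dt_min,
                 dt_max = dt_max, steady_tol = steady_tol,
                 max_steps = max_steps, neg_tol = neg_tol),
            class = "solver_controls")
}

bc_code <- function(grid) if (grid$bc == "periodic") 0L else 1L

#' Integrate a model on a grid
#'
#' Advances the reaction-diffusion system with the adaptive IMEX scheme:
#' linear diffusion treated implicitly (backward Euler, tridiagonal sweeps;
#' ADI splitting in 2D), the nonlinear reaction term explicitly, with time
#' steps adapted to the relative error in the reaction term. Conserved
#' group totals drift only at round-off level over a run.
#'
#' @param model An `mcas_model`.
#' @param grid An `mcas_grid`.
#' @param state Initial `mcas_state` (its `time` is the start time).
#' @param t_end Final time.
#' @param times Snapshot times (default: 50 evenly spaced). The initial
#'   state is always included as the first frame.
#' @param controls A [solver_controls()] list.
#' @param stop_at_steady If `TRUE`, return early once the state stops
#'   changing (relative rate below `controls$steady_tol`).
#' @return An `mcas_trajectory`: list with `times`, `states` (array
#'   `n_points x n_species x n_times`), `final` state, `steady` flag,
#'   `conservation` audit (start/end totals and relative drift), and solver
#'   statistics.
#' @export
integrate_model <- function(model, grid, state, t_end, times = NULL,
                            controls = solver_controls(),
                            stop_at_steady = FALSE) {
  t0 <- state$time
  if (t_end <= t0) stop("t_end must exceed the state's time")
  if (is.null(times))
    times <- seq(t0, t_end, length.out = 51)[-1]
  times <- sort(times[times > t0 & times <= t_end + 1e-12])
  fields <- state$fields
  stopifnot(ncol(fields) == n_species(model))
  tot0 <- conserved_totals(model, grid, state)
  res <- imex_integrate_cpp(
    fields, grid$n[1], grid$n[2], grid$h[1], grid$h[2], bc_code(grid),
    grid$walls, model$species$D, model$kernel, kernel_params(model),
    t0, t_end, times, controls$rtol, controls$dt_init, controls$dt_min,
    controls$dt_max, if (stop_at_steady) controls$steady_tol else -1,
    controls$max_steps, controls$neg_tol)
  nm <- model$species$name
  colnames(res$state) <- nm
  final <- mcas_state(res$state, time = res$t)
  tot1 <- conserved_totals(model, grid, final)
  drift <- max(abs(tot1 - tot0) / pmax(abs(tot0), 1e-300))
  nsnap <- length(res$times)
  states <- array(res$snapshots, dim = c(n_points(grid), length(nm), nsnap))
  # prepend initial frame
  states <- array(c(fields, states),
                  dim = c(n_points(grid), length(nm), nsnap + 1L),
                  dimnames = list(NULL, nm, NULL))
  structure(list(
    model = model$name, grid = grid,
    times = c(t0, res$times), states = states,
    final = final, steady = isTRUE(res$steady),
    maxrate = res$maxrate, nsteps = res$nsteps, nrejects = res$nrejects,
    conservation = list(start = tot0, end = tot1, rel_drift = drift)),
    class = "mcas_trajectory")
}

#' @export
print.mcas_trajectory <- function(x, ...) {
  cat(sprintf("mcas_trajectory: model %s, t in [%g, %g], %d frames\n",
              x$model, x$times[1], x$final$time, length(x$times)))
  cat(sprintf("  steps %d (rejected %d), conserved-total drift %.2e\n",
              as.integer(x$nsteps), as.integer(x$nrejects),
              x$conservation$rel_drift))
  invisible(x)
}

#' Integrate until the state stops changing
#'
#' Runs the solver until the maximum relative rate of change drops below
#' `controls$steady_tol`, or `max_time` is reached. Non-convergence (e.g. a
#' limit cycle of the negative-feedback model) is reported via
#' `converged = FALSE` together with the residual rate and the amplitude of
#' the residual oscillation over the final stretch of the run.
#'
#' @inheritParams integrate_model
#' @param max_time Time budget (default 2000).
#' @return List with `state` (final `mcas_state`), `converged`,
#'   `residual_rate`, `oscillation` (per-species relative amplitude over the
#'   last frames), and the underlying `trajectory`.
#' @export
run_to_steady_state <- function(model, grid, state, controls = solver_controls(),
                                max_time = 2000) {
  traj <- integrate_model(model, grid, state, t_end = state$time + max_time,
                          times = state$time + seq(0.02, 1, by = 0.02) * max_time,
                          controls = controls, stop_at_steady = TRUE)
  osc <- NA_real_
  if (!traj$steady) {
    nt <- length(traj$times)
    tail_idx <- unique(pmax(1L, seq(nt - min(10L, nt - 1L), nt)))
    if (length(tail_idx) > 1) {
      sub <- traj$states[, , tail_idx, drop = FALSE]
      rng <- apply(sub, 2, function(m) max(m) - min(m))
      scl <- pmax(apply(abs(traj$final$fields), 2, max), 1e-300)
      osc <- max(rng / scl)
    }
  }
  list(state = traj$final, converged = traj$steady,
       residual_rate = traj$maxrate, oscillation = osc, trajectory = traj)
}

#' Conserved group totals of a state
#'
#' Sum over the grid of the weighted species fields (weights 1 for membrane
#' species, `1/eta` for cytosolic species in the mechanistic models) times
#' the cell volume, one value per conservation group.
#'
#' @param model An `mcas_model`.
#' @param grid An `mcas_grid`.
#' @param state An `mcas_state` (or bare field matrix).
#' @return Named numeric vector of totals.
#' @export
conserved_totals <- function(model, grid, state) {
  fields <- if (inherits(state, "mcas_state")) state$fields else state
  nm <- model$species$name
  cv <- cell_volume(grid)
  vapply(model$groups, function(w) {
    idx <- match(names(w), nm)
    sum(fields[, idx, drop = FALSE] %*% w) * cv
  }, numeric(1))
}

# per-subdomain totals (list of masks from subdomain_masks)
subdomain_totals <- function(model, grid, state, masks = subdomain_masks(grid)) {
  fields <- if (inherits(state, "mcas_state")) state$fields else state
  nm <- model$species$name
  cv <- cell_volume(grid)
  lapply(masks, function(m)
    vapply(model$groups, function(w) {
      idx <- match(names(w), nm)
      sum(fields[m, idx, drop = FALSE] %*% w) * cv
    }, numeric(1)))
}

# extract one species' field from a state or matrix
species_field <- function(model, state, species) {
  fields <- if (inherits(state, "mcas_state")) state$fields else state
  fields[, match(species, model$species$name)]
}
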