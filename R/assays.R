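# Simulation protocols: standardized single-peak preparations, saturation
# scans, competition assays, competition-time curves, outcome phase diagrams
# and the basal-substrate-difference predictor.

#' Prepare an insulated single-peak steady state
#'
#' Standardized preparation: the homogeneous state for the requested amount
#' plus small seeded multiplicative noise on the substrate, integrated to
#' steady state. If the steady state carries more than one peak the
#' preparation retries with fresh seeds up to `max_retries`; a homogeneous
#' outcome (sub-critical amount) is reported explicitly as "no peak".
#'
#' @inheritParams noisy_initial_condition
#' @param controls [solver_controls()].
#' @param max_time Integration budget for reaching steady state.
#' @param max_retries Retry budget when multiple peaks persist.
#' @param method Preparation route: `"seeded"` (default) starts from a
#'   localized activator bump ([seeded_initial_condition()]), which reaches
#'   the polarized branch also below the Turing onset; `"noise"` uses only
#'   multiplicative noise on the homogeneous state; `"auto"` tries noise
#'   first and falls back to the seeded route if the field stays
#'   homogeneous.
#' @return List of class `peak_prep`: `state` (steady `mcas_state`),
#'   `peaks` (a `peak_set`), `no_peak`, `converged`, `seed_used`, `amount`.
#' @export
prepare_single_peak <- function(model, grid, amount, seed = 1L,
                                amplitude = 0.01,
                                controls = solver_controls(),
                                max_time = 2000, max_retries = 3L,
                                method = c("seeded", "noise", "auto")) {
  method <- match.arg(method)
  if (amount <= 0) stop("amount must be > 0")
  routes <- switch(method, seeded = "seeded", noise = "noise",
                   auto = c("noise", "seeded"))
  seed_used <- seed
  for (attempt in 0:max_retries) {
    for (route in routes) {
      st0 <- if (route == "noise")
        noisy_initial_condition(model, grid, amount, amplitude, seed_used)
      else seeded_initial_condition(model, grid, amount, seed_used, amplitude)
      res <- run_to_steady_state(model, grid, st0, controls, max_time)
      f <- species_field(model, res$state, model$activator)
      ps <- detect_peaks(f, grid,
                         min_amplitude = 1e-9 * amount *
                           max(model_1x_totals(model)))
      if (nrow(ps) == 0L && route != routes[length(routes)]) next
      if (nrow(ps) <= 1L) {
        return(structure(list(state = res$state, peaks = ps,
                              no_peak = nrow(ps) == 0L,
                              converged = res$converged,
                              seed_used = seed_used, amount = amount,
                              route = route),
                         class = "peak_prep"))
      }
    }
    seed_used <- seed_used + 1000L * (attempt + 1L)
  }
  stop(sprintf("more than one peak persisted after %d retries (amount %g)",
               max_retries, amount))
}

# no-flux subgrid view of one insulated half plus its point mask
half_views <- function(grid) {
  masks <- subdomain_masks(grid)
  if (length(masks) != 2L)
    stop("grid is not split into two insulated subdomains")
  sub <- mcas_grid(n = c(grid$n[1] %/% 2L, grid$n[2])[seq_len(grid$dim)],
                   length = c(grid$length[1] / 2, grid$length[2])[seq_len(grid$dim)],
                   bc = "no-flux")
  list(masks = masks, subgrid = sub)
}

# prepare two insulated halves simultaneously; returns the joint steady
# state plus per-half peak sets and basal substrate levels
prepare_two_halves <- function(model, grid, amounts, seed, amplitude,
                               controls, max_time, max_retries = 3L) {
  wg <- insulate(grid, half_split_walls(grid))
  hv <- half_views(wg)
  seed_used <- seed
  for (attempt in 0:max_retries) {
    f1 <- seeded_initial_condition(model, wg, amounts[1], seed_used,
                                   amplitude, mask = hv$masks[[1]])
    f2 <- seeded_initial_condition(model, wg, amounts[2], seed_used + 1L,
                                   amplitude, mask = hv$masks[[2]])
    st0 <- mcas_state(f1$fields + f2$fields)
    res <- run_to_steady_state(model, wg, st0, controls, max_time)
    halves <- lapply(1:2, function(h) {
      act <- species_field(model, res$state, model$activator)[hv$masks[[h]]]
      ps <- detect_peaks(act, hv$subgrid,
                         min_amplitude = 1e-9 * amounts[h] *
                           max(model_1x_totals(model)))
      basal <- if (nrow(ps) == 1L)
        vapply(model$substrates, function(s)
          basal_level(species_field(model, res$state, s)[hv$masks[[h]]], ps),
          numeric(1))
      else rep(NA_real_, length(model$substrates))
      list(peaks = ps, basal = setNames(basal, model$substrates))
    })
    npk <- vapply(halves, function(h) nrow(h$peaks), integer(1))
    if (any(npk == 0L))
      stop(sprintf("subsystem failed to form a peak (amounts %g:%g)",
                   amounts[1], amounts[2]))
    if (all(npk == 1L))
      return(list(state = res$state, grid = wg, halves = halves,
                  converged = res$converged, seed_used = seed_used))
    seed_used <- seed_used + 1000L * (attempt + 1L)
  }
  stop("multiple peaks persisted in an insulated subsystem after retries")
}

#' Two-peak competition assay
#'
#' The standardized competition protocol: two insulated subdomains (equal
#' halves) are brought to single-peak steady states holding the given
#' amounts, the walls are removed at t = 0, and the merged system is
#' integrated while the per-peak activator mass fractions are tracked and
#' the outcome classified. Fractions are computed on the model's activator
#' species (`u`, or `Cdc42T` for the mechanistic models).
#'
#' @param model An `mcas_model`.
#' @param amounts Length-2 amounts of the two subsystems, in units of "1x"
#'   (e.g. `c(0.6, 1)`).
#' @param grid Full-domain `mcas_grid` (even number of x points).
#' @param seed Integer seed for the symmetry-breaking noise.
#' @param amplitude Noise amplitude for the preparations.
#' @param controls [solver_controls()].
#' @param t_max Horizon of the competition phase (default 2000).
#' @param sample_dt Trace sampling interval (default 2).
#' @param prep_max_time Budget for each preparation phase.
#' @return List of class `competition_assay`: `trace`, `outcome`, `basal`
#'   (per-half basal substrate levels at the insulated steady states),
#'   `amounts`, `seed`, `prep_converged`, `trajectory`.
#' @export
competition_assay <- function(model, amounts, grid = NULL, seed = 1L,
                              amplitude = 0.01,
                              controls = solver_controls(), t_max = 2000,
                              sample_dt = 2, prep_max_time = 2000) {
  if (is.null(grid)) grid <- mcas_grid()
  stopifnot(length(amounts) == 2L, all(amounts > 0))
  prep <- prepare_two_halves(model, grid, amounts, seed, amplitude,
                             controls, prep_max_time)
  g2 <- remove_insulation(prep$grid)
  st <- mcas_state(prep$state$fields, time = 0)
  traj <- integrate_model(model, g2, st, t_end = t_max,
                          times = seq(sample_dt, t_max, by = sample_dt),
                          controls = controls, stop_at_steady = TRUE)
  trace <- competition_trace(traj, model)
  outcome <- classify_outcome(trace, t_max = t_max)
  basal <- do.call(rbind, lapply(prep$halves, `[[`, "basal"))
  rownames(basal) <- paste0("half", 1:2)
  structure(list(trace = trace, outcome = outcome, basal = basal,
                 amounts = amounts, seed = seed,
                 prep_converged = prep$converged, trajectory = traj),
            class = "competition_assay")
}

#' Saturation scan over total protein amounts
#'
#' Prepares one single-peak steady state per amount multiplier on the full
#' domain and tabulates the peak activator concentration and the basal
#' level of every cytoplasmic substrate. As the amount grows, the peak
#' concentration approaches a saturation point while the limiting
#' substrate's basal level declines to a limit.
#'
#' @param model An `mcas_model`.
#' @param multipliers Ascending amount multipliers (units of "1x").
#' @param grid An `mcas_grid`.
#' @param seed,amplitude,controls,max_time As in [prepare_single_peak()].
#' @param conc_override Optional named "1x" concentrations overriding the
#'   model default (used by [limiting_species_scan()]).
#' @return data.frame: `amount`, `peak_conc`, `no_peak`, `converged`, one
#'   `basal_<species>` column per substrate.
#' @export
saturation_scan <- function(model, multipliers, grid = NULL, seed = 1L,
                            amplitude = 0.01, controls = solver_controls(),
                            max_time = 2000, conc_override = NULL) {
  if (is.null(grid)) grid <- mcas_grid()
  if (is.unsorted(multipliers))
    stop("amount multipliers must be sorted ascending")
  if (!is.null(conc_override)) model$one_x[names(conc_override)] <- conc_override
  rows <- lapply(seq_along(multipliers), function(i) {
    m <- multipliers[i]
    basal <- rep(NA_real_, length(model$substrates))
    peak_conc <- NA_real_
    prep <- tryCatch(
      prepare_single_peak(model, grid, m, seed = seed + 10L * i,
                          amplitude = amplitude, controls = controls,
                          max_time = max_time),
      error = function(e) e)
    if (inherits(prep, "error")) {
      # e.g. a single peak is unstable to splitting at this amount;
      # flagged, never dropped
      return(c(list(amount = m, peak_conc = peak_conc, no_peak = FALSE,
                    converged = FALSE, note = conditionMessage(prep)),
               setNames(as.list(basal), paste0("basal_", model$substrates))))
    }
    if (!prep$no_peak) {
      peak_conc <- prep$peaks$amplitude[1]
      basal <- vapply(model$substrates, function(s)
        basal_level(species_field(model, prep$state, s), prep$peaks),
        numeric(1))
    }
    c(list(amount = m, peak_conc = peak_conc, no_peak = prep$no_peak,
           converged = prep$converged, note = ""),
      setNames(as.list(basal), paste0("basal_", model$substrates)))
  })
  do.call(rbind.data.frame, rows)
}

#' Identify the limiting substrate of the mechanistic circuit
#'
#' Scans single-peak steady states while increasing the total amount of
#' both conserved proteins, or of Cdc42 or BemGEF alone, and identifies the
#' limiting species: the cytoplasmic substrate whose basal level plateaus
#' (relative increment below `plateau_threshold` over the top of the
#' scanned range).
#'
#' @param model A mechanistic `mcas_model`.
#' @param which Which conserved totals to scale: `"both"`, `"Cdc42"`, or
#'   `"BemGEF"`.
#' @param multipliers Ascending amount multipliers.
#' @param plateau_threshold Relative basal increment below which a species
#'   counts as plateaued (default 0.05).
#' @param ... Passed to [saturation_scan()].
#' @return List: `table` (the scan), `limiting` (species name or
#'   `"undetermined"`), `rel_increment` (per-substrate tail increment).
#' @export
limiting_species_scan <- function(model, which = c("both", "Cdc42", "BemGEF"),
                                  multipliers, plateau_threshold = 0.05, ...) {
  which <- match.arg(which)
  if (!model$name %in% c("mechanistic", "mechanistic_nfb"))
    stop("limiting-species scans apply to the mechanistic models")
  base <- model$one_x
  scans <- lapply(multipliers, function(m) {
    conc <- base
    if (which %in% c("both", "Cdc42")) conc["Cdc42Dc"] <- base[["Cdc42Dc"]] * m
    if (which %in% c("both", "BemGEF")) conc["BemGEFc"] <- base[["BemGEFc"]] * m
    conc
  })
  # express each row as a unit amount with overridden "1x" composition
  rows <- lapply(seq_along(multipliers), function(i)
    cbind(saturation_scan(model, 1, conc_override = scans[[i]], ...),
          multiplier = multipliers[i]))
  tab <- do.call(rbind, rows)
  tab$amount <- tab$multiplier
  k <- nrow(tab)
  rel <- vapply(model$substrates, function(s) {
    b <- tab[[paste0("basal_", s)]]
    ok <- which(!is.na(b))
    if (length(ok) < 2L) return(NA_real_)
    i2 <- ok[length(ok)]; i1 <- ok[length(ok) - 1L]
    (b[i2] - b[i1]) / max(abs(b[i1]), 1e-300)
  }, numeric(1))
  # the limiting substrate is depleted: its basal level declines/plateaus
  # (signed relative increment below threshold) while non-limiting
  # substrates keep rising with added protein
  plateaued <- names(rel)[!is.na(rel) & rel < plateau_threshold]
  limiting <- if (length(plateaued) == 0L) "undetermined"
    else plateaued[which.min(rel[plateaued])]
  list(table = tab, limiting = limiting, rel_increment = rel)
}

#' Competition time as a function of total amount
#'
#' Runs the two-peak competition assay over an ascending ladder of total
#' amounts (each subsystem holding `2 * m * split` of "1x") and measures
#' the 70:30 -> 99:1 competition time. Times grow steeply as the peaks
#' approach saturation; runs whose trace never reaches 99:1 within `t_max`
#' are censored (reported with `censored = TRUE`, never as numbers).
#'
#' @param model An `mcas_model`.
#' @param multipliers Ascending overall amount multipliers.
#' @param split Mass split between the two subsystems (default 0.6/0.4).
#' @param ... Passed to [competition_assay()].
#' @return data.frame: `amount`, `time`, `censored`, `reason`, `outcome`.
#' @export
competition_time_curve <- function(model, multipliers, split = c(0.6, 0.4),
                                   ...) {
  rows <- lapply(multipliers, function(m) {
    asy <- competition_assay(model, amounts = 2 * m * split, ...)
    ct <- competition_time(asy$trace)
    data.frame(amount = m, time = as.numeric(ct), censored = is.na(ct),
               reason = if (is.na(ct)) attr(ct, "reason") else "",
               outcome = asy$outcome$label, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Outcome phase diagram of the indirect-substrate model
#'
#' Sweeps the indirect-substrate diffusivity `Dvi` against the total
#' protein amount, running a 0.4:0.6 two-peak competition assay in every
#' cell and recording the classified outcome alongside the basal-substrate
#' difference of the two insulated starting peaks (v at the 0.6 peak minus
#' v at the 0.4 peak), whose sign predicts the outcome.
#'
#' @param Dvi_values Indirect-substrate diffusivities (sweep axis 1).
#' @param amount_values Overall amount multipliers (sweep axis 2).
#' @param model_args Extra arguments to [indirect_model()].
#' @param grid,seed,controls,t_max,sample_dt As in [competition_assay()].
#' @param split Subsystem mass split (default 0.4/0.6).
#' @param band Coexistence band on the basal difference (default 1e-4).
#' @return data.frame of class `mcas_phase_diagram`: `Dvi`, `amount`,
#'   `label`, `censored`, `delta_v`, `predicted`, `seed`, `error`.
#' @export
phase_diagram <- function(Dvi_values, amount_values, model_args = list(),
                          grid = NULL, seed = 1L,
                          controls = solver_controls(), t_max = 2000,
                          sample_dt = 2, split = c(0.4, 0.6), band = 1e-4) {
  if (length(Dvi_values) < 3L || length(amount_values) < 3L)
    stop("phase diagram sweeps need at least a 3 x 3 grid")
  cells <- expand.grid(Dvi = Dvi_values, amount = amount_values,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    Dvi <- cells$Dvi[i]; m <- cells$amount[i]
    cell_seed <- seed + 7L * i
    res <- tryCatch({
      mod <- do.call(indirect_model, c(list(Dvi = Dvi), model_args))
      asy <- competition_assay(mod, amounts = 2 * m * split, grid = grid,
                               seed = cell_seed, controls = controls,
                               t_max = t_max, sample_dt = sample_dt)
      dv <- unname(asy$basal["half2", "v"] - asy$basal["half1", "v"])
      data.frame(Dvi = Dvi, amount = m, label = asy$outcome$label,
                 censored = asy$outcome$censored, delta_v = dv,
                 predicted = predict_from_delta(dv, band),
                 seed = cell_seed, error = "", stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(Dvi = Dvi, amount = m, label = NA_character_,
                 censored = NA, delta_v = NA_real_,
                 predicted = NA_character_, seed = cell_seed,
                 error = conditionMessage(e), stringsAsFactors = FALSE))
    res
  })
  out <- do.call(rbind, rows)
  structure(out, band = band, split = split,
            class = c("mcas_phase_diagram", "data.frame"))
}

predict_from_delta <- function(delta_v, band = 1e-4) {
  if (is.na(delta_v)) return(NA_character_)
  if (delta_v > band) "equalization"
  else if (delta_v < -band) "competition"
  else "coexistence"
}

#' Basal-substrate-difference outcome predictor
#'
#' Prepares the two insulated single-peak steady states and returns the
#' difference in basal substrate level, `delta_v` = basal v at the
#' larger-amount peak minus basal v at the smaller-amount peak, together
#' with the outcome it predicts: negative -> competition (flux toward the
#' larger peak), positive -> equalization, |delta_v| below `band` ->
#' coexistence.
#'
#' @param model An `mcas_model`.
#' @param amounts Length-2 subsystem amounts, smaller first
#'   (default `c(0.8, 1.2)`, the 0.4:0.6 split of 1x overall).
#' @param species Substrate species measured (default the model's primary
#'   substrate).
#' @param band Coexistence band (default 1e-4).
#' @inheritParams competition_assay
#' @return List: `delta_v`, `predicted`, `basal` (per-half levels).
#' @export
basal_difference_predictor <- function(model, amounts = c(0.8, 1.2),
                                       species = model$substrates[1],
                                       band = 1e-4, grid = NULL, seed = 1L,
                                       amplitude = 0.01,
                                       controls = solver_controls(),
                                       prep_max_time = 2000) {
  if (is.null(grid)) grid <- mcas_grid()
  prep <- prepare_two_halves(model, grid, amounts, seed, amplitude,
                             controls, prep_max_time)
  b <- vapply(prep$halves, function(h) h$basal[[species]], numeric(1))
  small <- which.min(amounts); large <- which.max(amounts)
  dv <- b[large] - b[small]
  list(delta_v = dv, predicted = predict_from_delta(dv, band),
       basal = setNames(b, paste0("amount_", amounts)))
}
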