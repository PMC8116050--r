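# Configuration-driven runs and result (de)serialization: YAML configs in,
# CSV tables + JSON run records out, with lossless round-trips.

model_from_config <- function(mc) {
  name <- mc$model %||% stop("config must name a model")
  pars <- mc$params %||% list()
  switch(name,
    minimal = do.call(minimal_model, pars),
    indirect = do.call(indirect_model, pars),
    mechanistic = mechanistic_model(FALSE, params = pars),
    mechanistic_nfb = mechanistic_model(TRUE, params = pars),
    stop("unknown model '", name, "' (field: model)"))
}

grid_from_config <- function(gc) {
  gc <- gc %||% list()
  allowed <- c("n", "length", "bc", "walls")
  bad <- setdiff(names(gc), allowed)
  if (length(bad)) stop("unknown grid field(s): ", paste(bad, collapse = ", "))
  do.call(mcas_grid, lapply(gc, unlist))
}

controls_from_config <- function(cc) {
  cc <- cc %||% list()
  bad <- setdiff(names(cc), names(formals(solver_controls)))
  if (length(bad))
    stop("unknown controls field(s): ", paste(bad, collapse = ", "))
  do.call(solver_controls, cc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and validate a run configuration
#'
#' Configurations are YAML with sections `model` (name + parameter map),
#' `grid`, `controls`, and `assay` (subcommand-specific fields such as
#' `amounts`, `multipliers`, `Dvi_values`, `seed`, `t_max`). Unknown keys
#' are rejected with the offending field path.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return The validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  allowed <- c("model", "params", "grid", "controls", "assay", "preset")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$preset)) {
    pre <- mcas_fixtures(cfg$preset)
    cfg$model <- cfg$model %||% pre$model
    cfg$assay <- utils::modifyList(pre[setdiff(names(pre), "model")],
                                   cfg$assay %||% list())
  }
  cfg
}

#' Run a configured assay and write its outputs
#'
#' Dispatches a subcommand (`simulate`, `competition`, `competition-curve`,
#' `saturation`, `phase-diagram`, `frap3d`, `frap-fit`, `fixtures`) on a
#' validated config, writes CSV tables plus a JSON run record (config
#' snapshot, seeds, wall time, conservation audit, output manifest) into
#' `out_dir`, and returns the results invisibly.
#'
#' @param config Path to a YAML config, or a config list.
#' @param subcommand One of the assay subcommands.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional override of the config seed.
#' @return Invisibly, a list with the computed result and the run record.
#' @export
mcas_run <- function(config,
                     subcommand = c("competition", "simulate",
                                    "competition-curve", "saturation",
                                    "phase-diagram", "frap3d", "frap-fit",
                                    "fixtures"),
                     out_dir = ".", seed = NULL) {
  subcommand <- match.arg(subcommand)
  t_start <- Sys.time()
  cfg <- read_run_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  a <- cfg$assay %||% list()
  if (!is.null(seed)) a$seed <- seed
  a$seed <- a$seed %||% 1L
  files <- character()
  conservation <- NULL

  emit_csv <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
    p
  }

  result <- switch(subcommand,
    fixtures = mcas_fixtures(),
    simulate = {
      model <- model_from_config(cfg)
      grid <- grid_from_config(cfg$grid)
      st <- noisy_initial_condition(model, grid, a$amount %||% 1,
                                    a$amplitude %||% 0.01, a$seed)
      traj <- integrate_model(model, grid, st, t_end = a$t_end %||% 100,
                              controls = controls_from_config(cfg$controls))
      conservation <- traj$conservation
      co <- grid_coords(grid)
      for (i in seq_along(traj$times)) {
        df <- data.frame(x = co$x, traj$states[, , i])
        names(df)[-1] <- dimnames(traj$states)[[2]]
      }
      prof <- data.frame(time = rep(traj$times, each = n_points(grid)),
                         x = rep(co$x, length(traj$times)),
                         apply(traj$states, 2, as.vector))
      emit_csv(prof, "profiles")
      traj
    },
    competition = {
      model <- model_from_config(cfg)
      grid <- grid_from_config(cfg$grid)
      asy <- competition_assay(model, amounts = unlist(a$amounts),
                               grid = grid, seed = a$seed,
                               controls = controls_from_config(cfg$controls),
                               t_max = a$t_max %||% 2000)
      conservation <- asy$trajectory$conservation
      emit_csv(trace_to_df(asy$trace), "trace")
      asy
    },
    `competition-curve` = {
      model <- model_from_config(cfg)
      grid <- grid_from_config(cfg$grid)
      tab <- competition_time_curve(
        model, multipliers = unlist(a$multipliers),
        split = unlist(a$split %||% c(0.6, 0.4)), grid = grid,
        seed = a$seed, controls = controls_from_config(cfg$controls),
        t_max = a$t_max %||% 2000)
      emit_csv(tab, "competition_times")
      tab
    },
    saturation = {
      model <- model_from_config(cfg)
      grid <- grid_from_config(cfg$grid)
      tab <- saturation_scan(model, multipliers = unlist(a$multipliers),
                             grid = grid, seed = a$seed,
                             controls = controls_from_config(cfg$controls))
      emit_csv(tab, "saturation")
      tab
    },
    `phase-diagram` = {
      grid <- grid_from_config(cfg$grid)
      pd <- phase_diagram(Dvi_values = unlist(a$Dvi_values),
                          amount_values = unlist(a$amount_values),
                          model_args = cfg$params %||% list(),
                          grid = grid, seed = a$seed,
                          controls = controls_from_config(cfg$controls),
                          t_max = a$t_max %||% 2000,
                          split = unlist(a$split %||% c(0.4, 0.6)))
      emit_csv(as.data.frame(pd), "phase_diagram")
      pd
    },
    frap3d = {
      geom <- do.call(frap_geometry, a$geometry %||% list())
      ns <- neck_slowdown(geom, D = a$D %||% 10)
      emit_csv(data.frame(
        time = rep(ns$sim_times, 2),
        roi = rep(c("mother", "daughter"), each = length(ns$sim_times)),
        intensity = c(ns$rois$mother$intensity, ns$rois$daughter$intensity)),
        "roi_traces")
      ns
    },
    `frap-fit` = {
      df <- utils::read.csv(a$trace_csv %||% stop("frap-fit needs trace_csv"))
      need <- c("time", "raw", "background", "unbleached")
      miss <- setdiff(need, names(df))
      if (length(miss)) stop("trace_csv missing column(s): ",
                             paste(miss, collapse = ", "))
      yn <- normalize_frap_trace(df$raw, df$background, df$unbleached)
      fit <- fit_frap(df$time, yn, kind = a$kind %||% "recovery")
      fit
    })

  record <- list(
    subcommand = subcommand,
    config = cfg, seed = a$seed,
    package_version = as.character(utils::packageVersion("mcaspolarity")),
    wall_time_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    conservation = conservation,
    outputs = basename(files))
  rec_path <- file.path(out_dir, "run_record.json")
  jsonlite::write_json(record, rec_path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(list(result = result, record = record,
                 files = c(files, rec_path)))
}

trace_to_df <- function(trace) {
  df <- data.frame(time = trace$times)
  fm <- trace$fractions
  colnames(fm) <- paste0("fraction_peak", colnames(fm))
  cbind(df, fm, peak_count = trace$peak_count)
}

df_to_trace <- function(df, steady = TRUE) {
  fcols <- grep("^fraction_peak", names(df), value = TRUE)
  fm <- as.matrix(df[fcols])
  colnames(fm) <- sub("^fraction_peak", "", fcols)
  synthetic_competition_trace(df$time, fm, steady = steady)
}

#' Write / load typed result tables
#'
#' Results are stored as a CSV table plus a JSON sidecar naming the result
#' type, so they round-trip losslessly. Supported types: competition
#' traces, phase diagrams, and plain data.frame tables (saturation scans,
#' competition-time curves).
#'
#' @param x Result object (`competition_trace`, `mcas_phase_diagram`, or
#'   data.frame).
#' @param path Basename path (without extension); writes `path.csv` and
#'   `path.json`.
#' @return `write_results`: the paths invisibly. `load_results`: the
#'   reconstructed object.
#' @export
write_results <- function(x, path) {
  type <- if (inherits(x, "competition_trace")) "competition_trace"
    else if (inherits(x, "mcas_phase_diagram")) "phase_diagram"
    else if (is.data.frame(x)) "table"
    else stop("unsupported result type: ", paste(class(x), collapse = "/"))
  df <- switch(type,
    competition_trace = trace_to_df(x),
    phase_diagram = as.data.frame(x),
    table = x)
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  meta <- list(type = type, columns = names(df))
  if (type == "competition_trace")
    meta$steady <- x$steady
  if (type == "phase_diagram") {
    meta$band <- attr(x, "band")
    meta$split <- attr(x, "split")
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(paste0(path, ".csv"), paste0(path, ".json")))
}

#' @rdname write_results
#' @export
load_results <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(path, ".csv"), stringsAsFactors = FALSE)
  miss <- setdiff(meta$columns, names(df))
  if (length(miss))
    stop("result file missing column(s): ", paste(miss, collapse = ", "))
  switch(meta$type,
    competition_trace = df_to_trace(df, steady = isTRUE(meta$steady)),
    phase_diagram = structure(df, band = meta$band, split = meta$split,
                              class = c("mcas_phase_diagram", "data.frame")),
    table = df,
    stop("unknown result type in metadata: ", meta$type))
}
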