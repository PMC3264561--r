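## Experiment orchestration: full simulations (wild type, mutants, batches,
## sensitivity sweeps) with explicit seeding and reproducible outputs.

#' Full parameter bundle for a simulation
#'
#' Collects the transport and mechanics parameters together with the
#' simulation-loop settings. The macro time step applies the operator split
#' (1) mechanics relaxation, (2) target growth, (3) transport integration over
#' `dt`, (4) differentiation update, (5) division sweep.
#'
#' @param transport a [transport_params()] list.
#' @param mechanics a [mechanics_params()] list.
#' @param dt macro time step.
#' @param stop_cells stop meristematic growth at this cell count (default 700,
#'   where meristem growth slows down substantially).
#' @param settle_time additional transport time simulated after growth stops.
#' @param sample_every record a trace snapshot every this many macro steps.
#' @param initial_cells number of starting cells (default 4).
#' @param cell_scale initial linear cell size.
#' @param stage2_cells cell-count milestone defining the start of floral
#'   stage 2 (used by the sepal/petal onset rule); a modeling convention.
#' @param whorl_radius_fraction whorl-circle radius fraction for
#'   [classify_organs()].
#' @param t_gap temporal organ-separation parameter for [detect_clusters()].
#' @param pin_division `"renormalize"` or `"conserve"`, see
#'   [divide_if_ready()].
#' @param auxin0 initial auxin concentration.
#' @param max_steps safety cap on macro steps.
#' @return a list of class `model_params`.
#' @export
model_params <- function(transport = transport_params(),
                         mechanics = mechanics_params(),
                         dt = 1, stop_cells = 700L, settle_time = 120,
                         sample_every = 1L, initial_cells = 4L,
                         cell_scale = 1, stage2_cells = 100L,
                         whorl_radius_fraction = 0.35, t_gap = 5,
                         pin_division = "renormalize", auxin0 = 0,
                         max_steps = 5000L) {
  stopifnot(dt > 0, stop_cells > initial_cells, settle_time >= 0)
  structure(list(transport = transport, mechanics = mechanics, dt = dt,
                 stop_cells = as.integer(stop_cells),
                 settle_time = settle_time,
                 sample_every = as.integer(sample_every),
                 initial_cells = as.integer(initial_cells),
                 cell_scale = cell_scale,
                 stage2_cells = as.integer(stage2_cells),
                 whorl_radius_fraction = whorl_radius_fraction,
                 t_gap = t_gap, pin_division = pin_division,
                 auxin0 = auxin0, max_steps = as.integer(max_steps)),
            class = "model_params")
}

#' Mutant and wild-type parameter presets
#'
#' Maps the simulated genotypes onto the nominal parameter bundle:
#' \describe{
#'   \item{wildtype}{the nominal bundle, unchanged.}
#'   \item{yuc}{reduced/boosted auxin biosynthesis: `p_production` and the
#'     inflow `f_influx` are multiplied by `scale`.}
#'   \item{pid}{altered polarization capacity: the endosome-to-membrane rate
#'     `k1` is multiplied by `scale`.}
#'   \item{pin}{defective PIN1: the fixed per-cell PIN pool `pin_total` is
#'     multiplied by `scale` (the strong mutant uses `scale = 0.2`).}
#' }
#'
#' @param preset one of `"wildtype"`, `"yuc"`, `"pid"`, `"pin"`.
#' @param scale multiplier applied to the preset's target parameter(s).
#' @param base the nominal [model_params()] bundle.
#' @return a `model_params` bundle.
#' @export
preset_params <- function(preset = c("wildtype", "yuc", "pid", "pin"),
                          scale = 1, base = model_params()) {
  preset <- match.arg(preset)
  stopifnot(scale > 0)
  p <- base
  if (preset == "yuc") {
    p$transport$p_production <- p$transport$p_production * scale
    p$transport$f_influx <- p$transport$f_influx * scale
  } else if (preset == "pid") {
    p$transport$k1 <- p$transport$k1 * scale
  } else if (preset == "pin") {
    p$transport$pin_total <- p$transport$pin_total * scale
  }
  p
}

#' Experiment specification
#'
#' @param preset genotype preset name.
#' @param scale preset scale multiplier.
#' @param n_runs number of seeded runs.
#' @param seeds explicit seed vector, or `NULL` to use `base_seed + 0:(n-1)`.
#' @param base_seed base seed when `seeds` is `NULL`.
#' @param stop_cells growth-stop cell count.
#' @param params optional `model_params` bundle overriding the preset default.
#' @param output_dir optional directory for CSV/JSON outputs.
#' @return a list of class `experiment_spec`.
#' @export
experiment_spec <- function(preset = "wildtype", scale = 1, n_runs = 1L,
                            seeds = NULL, base_seed = 1L, stop_cells = 700L,
                            params = NULL, output_dir = NULL) {
  stopifnot(n_runs >= 1, scale > 0)
  if (is.null(seeds)) seeds <- base_seed + seq_len(n_runs) - 1L
  if (is.null(params)) {
    params <- preset_params(preset, scale)
    params$stop_cells <- as.integer(stop_cells)
  }
  structure(list(preset = preset, scale = scale, n_runs = as.integer(n_runs),
                 seeds = as.integer(seeds), stop_cells = as.integer(stop_cells),
                 params = params, output_dir = output_dir),
            class = "experiment_spec")
}

#' One macro step of the coupled simulation
#'
#' Operator split: Monte Carlo relaxation of the vertex energy; growth of the
#' resting areas (skipped once meristematic growth has ceased); subdivision of
#' over-long boundary walls; transport integration over `dt` on the frozen
#' geometry; differentiation update; division sweep.
#'
#' @param mesh a `tissue_mesh`.
#' @param params a `model_params` bundle.
#' @param growing logical; `FALSE` freezes the resting areas (growth ceased).
#' @return the advanced mesh (epoch incremented by `dt`).
#' @export
step_simulation <- function(mesh, params, growing = TRUE) {
  tp <- params$transport; mp <- params$mechanics
  mesh <- relax(mesh, mp)
  if (growing) mesh <- grow_targets(mesh, mp, params$dt)
  mesh <- subdivide_boundary_walls(mesh, mp$wall_length_cap)
  mesh <- integrate_transport(mesh, tp, params$dt)
  mesh$epoch <- mesh$epoch + params$dt
  mesh <- update_differentiation(mesh, tp, mesh$epoch)
  if (growing)
    mesh <- divide_ready(mesh, mp, params$pin_division, tp$pin_total)
  mesh
}

#' Run one full simulation
#'
#' Starts from the compact initial tissue, iterates the macro step until the
#' cell count reaches `stop_cells` (meristematic growth then ceases), lets the
#' transport system settle for `settle_time`, and analyzes the recorded trace
#' into an organ report. Fully reproducible per seed.
#'
#' @param spec an [experiment_spec()] (its `params` bundle is used).
#' @param seed RNG seed for this run.
#' @param keep_mesh return the final mesh as well.
#' @return list with `trace` (a `tissue_trace`), `clusters` (classified),
#'   `report` (an `organ_report`), `stage2_time`, and optionally `mesh`.
#' @export
run_single <- function(spec, seed, keep_mesh = FALSE) {
  params <- spec$params
  set.seed(seed)
  mesh <- build_initial_tissue(params$initial_cells, params$cell_scale)
  mesh <- init_state(mesh, params$transport, params$auxin0)
  trace <- new_trace()
  trace$snapshots[[1L]] <- trace_snapshot(mesh, mesh$epoch)
  stage2_time <- Inf
  step <- 0L
  growing <- TRUE
  settle_steps <- ceiling(params$settle_time / params$dt)
  settled <- 0L
  repeat {
    step <- step + 1L
    if (step > params$max_steps)
      stop("simulation exceeded max_steps before reaching stop_cells")
    mesh <- step_simulation(mesh, params, growing)
    n <- length(mesh$cells)
    if (is.infinite(stage2_time) && n >= params$stage2_cells)
      stage2_time <- mesh$epoch
    if (growing && n >= params$stop_cells) growing <- FALSE
    if (!growing) settled <- settled + 1L
    if (step %% params$sample_every == 0L || (!growing && settled >= settle_steps))
      trace$snapshots[[length(trace$snapshots) + 1L]] <-
        trace_snapshot(mesh, mesh$epoch)
    if (!growing && settled >= settle_steps) break
  }
  trace$stage2_time <- stage2_time
  clusters <- detect_clusters(trace, params$transport$A_threshold, params$t_gap)
  clusters <- merge_fused(clusters, trace, params$transport$A_threshold)
  clusters <- classify_organs(clusters, trace, params$whorl_radius_fraction,
                              stage2_time)
  rep <- organ_report(clusters, run_seed = seed)
  out <- list(trace = trace, clusters = clusters, report = rep,
              stage2_time = stage2_time)
  if (keep_mesh) out$mesh <- mesh
  out
}

#' Run a seeded batch of simulations
#'
#' Runs `n_runs` simulations with the spec's seeds and aggregates the organ
#' reports with [summarize_batch()]. Individual run failures are recorded and
#' excluded from the summary; any failure makes `ok` FALSE.
#'
#' @param spec an [experiment_spec()].
#' @param verbose print one line per completed run.
#' @return list with `summary` (a `batch_summary`), `reports`, `failures`,
#'   `ok`. If `spec$output_dir` is set, writes `organ_reports.csv` and
#'   `batch_summary.json` there.
#' @export
run_batch <- function(spec, verbose = FALSE) {
  reports <- list()
  failures <- list()
  for (seed in spec$seeds) {
    res <- tryCatch(run_single(spec, seed), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(seed = seed,
                                                message = conditionMessage(res))
      if (verbose) message(sprintf("seed %d: FAILED (%s)", seed,
                                   conditionMessage(res)))
    } else {
      reports[[length(reports) + 1L]] <- res$report
      if (verbose) message(sprintf("seed %d: pattern %s", seed,
                                   paste(res$report$pattern, collapse = "-")))
    }
  }
  summ <- if (length(reports)) summarize_batch(reports) else NULL
  if (!is.null(spec$output_dir) && length(reports)) {
    dir.create(spec$output_dir, recursive = TRUE, showWarnings = FALSE)
    df <- do.call(rbind, lapply(reports, function(r)
      data.frame(seed = r$run_seed, sepal = r$counts[["sepal"]],
                 petal = r$counts[["petal"]],
                 reproductive = r$counts[["reproductive"]])))
    write.csv(df, file.path(spec$output_dir, "organ_reports.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(pattern_frequency = as.list(summ$pattern_frequency),
           per_class = summ$per_class, n_runs = summ$n_runs),
      file.path(spec$output_dir, "batch_summary.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(summary = summ, reports = reports, failures = failures,
       ok = length(failures) == 0L)
}

## mapping of sweep parameter names to scaling actions on a model_params bundle
apply_sweep_scale <- function(params, name, level) {
  switch(name,
    D_passive = { params$transport$D_passive <- params$transport$D_passive * level; params },
    g0 = { params$mechanics$g0 <- params$mechanics$g0 * level; params },
    influx_window = {
      params$transport$influx_window <-
        as.integer(round(params$transport$influx_window * level)); params },
    k1 = { params$transport$k1 <- params$transport$k1 * level; params },
    gA = { params$mechanics$gA <- params$mechanics$gA * level; params },
    d_depletion = { params$transport$d_depletion <- params$transport$d_depletion * level; params },
    stop("unknown sweep parameter: ", name))
}

#' Parameter-sensitivity sweep
#'
#' Varies each named parameter to the given multiples of its nominal value
#' (50/100/150% by default) and, for each (parameter, level), reports the mean
#' and standard deviation of each organ-class count over `n_per_level` seeded
#' runs. The influx-window timing is varied by scaling both window edges (so
#' level 0.5 turns the `[50, 100]` window into `[25, 50]`).
#'
#' @param params_to_vary character vector among `"D_passive"`, `"g0"`,
#'   `"influx_window"`, `"k1"`, `"gA"`, `"d_depletion"`.
#' @param levels multipliers (default `c(0.5, 1, 1.5)`).
#' @param n_per_level runs per (parameter, level).
#' @param base_seed seeds are `base_seed + 0:(n-1)`, shared across conditions.
#' @param base nominal `model_params` bundle.
#' @param verbose print progress lines.
#' @return data frame with one row per (parameter, level, organ class):
#'   columns `parameter`, `level`, `class`, `mean`, `sd`, `n`.
#' @export
sensitivity_sweep <- function(params_to_vary = c("D_passive", "g0",
                                                 "influx_window", "k1", "gA",
                                                 "d_depletion"),
                              levels = c(0.5, 1, 1.5), n_per_level = 30L,
                              base_seed = 1L, base = model_params(),
                              verbose = FALSE) {
  rows <- list()
  for (name in params_to_vary) {
    for (lev in levels) {
      p <- apply_sweep_scale(base, name, lev)
      spec <- experiment_spec(preset = "wildtype", n_runs = n_per_level,
                              base_seed = base_seed, params = p,
                              stop_cells = p$stop_cells)
      bat <- run_batch(spec, verbose = FALSE)
      if (verbose) message(sprintf("%s x%.2f: done (%d ok)", name, lev,
                                   length(bat$reports)))
      pc <- bat$summary$per_class
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = name, level = lev, class = pc$class,
                   mean = pc$mean, sd = pc$sd, n = length(bat$reports))
    }
  }
  do.call(rbind, rows)
}

#' Write a trace as a long-format CSV
#'
#' One row per (sampled time, cell): time, cell id, auxin concentration,
#' endosomal PIN, differentiation flag and cell area.
#'
#' @param trace a `tissue_trace`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- do.call(rbind, lapply(trace$snapshots, function(s)
    data.frame(time = s$time, cell = seq_len(s$n_cells), auxin = s$auxin,
               pin_endosome = s$pin_endo, differentiated = s$differentiated,
               area = s$area)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
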