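#' Build a scenario restriction grid
#'
#' Combines the policy masks into the binary development-restriction grid R
#' (0 = no transition allowed): the inertial scenario S1 restricts nothing;
#' S2 freezes the ecological-protection red line (EPRL) zone; S3 freezes the
#' capital-farmland (CF) zone; S4 freezes their union.
#'
#' @param scenario `"S1"`, `"S2"`, `"S3"` or `"S4"`.
#' @param eprl,cf binary masks (1 = inside the zone); required by the
#'   scenarios that use them.
#' @param ref a [lulc_raster] giving the grid shape (used by S1 and for
#'   checks).
#' @return binary matrix R.
#' @export
build_restriction <- function(scenario, eprl = NULL, cf = NULL, ref) {
  scenario <- match.arg(scenario, c("S1", "S2", "S3", "S4"))
  shape <- dim(ref$values)
  R <- matrix(1L, shape[1], shape[2])
  needs <- switch(scenario, S1 = character(0), S2 = "eprl", S3 = "cf",
                  S4 = c("eprl", "cf"))
  if ("eprl" %in% needs) {
    if (is.null(eprl)) stop(scenario, " needs the EPRL mask")
    if (!all(dim(eprl) == shape)) stop("EPRL mask is not aligned")
    R[eprl == 1] <- 0L
  }
  if ("cf" %in% needs) {
    if (is.null(cf)) stop(scenario, " needs the CF mask")
    if (!all(dim(cf) == shape)) stop("CF mask is not aligned")
    R[cf == 1] <- 0L
  }
  R
}

#' Markov demand in cells
#'
#' Projects the base map's class composition `n_steps` applications of the
#' transition matrix ahead and rounds to whole cells by largest remainder, so
#' the demand total equals the valid-cell total exactly.
#'
#' @param base a [lulc_raster].
#' @param tm a `transition_matrix` (or matrix).
#' @param n_steps whole Markov steps.
#' @return named integer vector of target cells per class.
#' @export
demand_from_markov <- function(base, tm, n_steps = 1L) {
  counts <- class_counts(base)
  dem <- project_demand(stats::setNames(counts, names(base$legend)), tm,
                        n_steps)
  stats::setNames(round_largest_remainder(dem, sum(counts)),
                  names(base$legend))
}

#' Scenario configuration
#'
#' @param scenario scenario id (`"S1"`..`"S4"`).
#' @param engine `"plus"`, `"flus"` or `"ca_markov"`.
#' @param horizon_steps whole Markov steps from the base date to the horizon
#'   (e.g. a 5-year matrix projected 15 years = 3).
#' @param cfg a [ca_config()].
#' @param pcfg a [plus_config()] (PLUS engine only).
#' @param seed integer seed (overrides `cfg$seed`).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = "S1",
                            engine = c("plus", "flus", "ca_markov"),
                            horizon_steps = 3, cfg = ca_config(),
                            pcfg = plus_config(), seed = 1L) {
  engine <- match.arg(engine)
  scenario <- match.arg(scenario, c("S1", "S2", "S3", "S4"))
  if (horizon_steps < 1) stop("`horizon_steps` must be >= 1")
  cfg$seed <- as.integer(seed)
  structure(list(scenario = scenario, engine = engine,
                 horizon_steps = horizon_steps, cfg = cfg, pcfg = pcfg,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# engine-specific occurrence potentials from a calibration pair + drivers
calibration_potentials <- function(engine, date1, date2, drivers, seed,
                                   window = 5, sample_rate = 0.05,
                                   rf_trees = 60) {
  switch(engine,
    ca_markov = transition_suitability(date1, date2, window = window),
    flus = {
      s <- sample_cells(date2, drivers, rate = sample_rate,
                        strategy = "stratified", seed = seed)
      predict_ann(train_ann(s, seed = seed), drivers)
    },
    plus = {
      exp_grids <- lapply(stats::setNames(nm = names(date1$legend)),
                          function(k) extract_expansion(date1, date2,
                                                        as.integer(k)))
      train_leas_rf(exp_grids, drivers, trees = rf_trees, seed = seed)$prob
    })
}

#' Run the full calibrate / validate / project / value / measure pipeline
#'
#' One scenario run: estimate the transition matrix on the first date pair,
#' simulate the third date with the chosen engine and compare it against the
#' observation (kappa validation), re-calibrate on the later pair, project
#' demand to the horizon, allocate it under the scenario restriction, and
#' report the horizon area table, ESV snapshot and change, landscape
#' metrics, and convergence log. Deterministic under the config seed.
#'
#' @param t0,t1,t2 three dated [lulc_raster]s (t2 the latest observation).
#' @param drivers driver stack.
#' @param sc a [scenario_config].
#' @param masks list with `eprl` and `cf` binary masks (policy scenarios).
#' @param coeff coefficient table for the valuation.
#' @param validate run the historical validation stage.
#' @param output_dir optional directory for delimited outputs.
#' @return list of class `pipeline_run`: `tm_calibration`, `tm_projection`,
#'   `validation`, `horizon`, `areas`, `esv`, `esv_change`, `metrics`,
#'   `convergence`.
#' @export
run_pipeline <- function(t0, t1, t2, drivers, sc = scenario_config(),
                         masks = NULL, coeff = load_coefficients(),
                         validate = TRUE, output_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  R <- stage("restriction",
             build_restriction(sc$scenario, masks$eprl, masks$cf, t2))
  cfg <- sc$cfg
  cfg$restriction <- R

  tm_cal <- stage("calibrate",
                  estimate_transition_matrix(crosstab(t0, t1)))
  val <- NULL
  if (validate) {
    val <- stage("validate", {
      P <- calibration_potentials(sc$engine, t0, t1, drivers, sc$seed)
      dem <- demand_from_markov(t1, tm_cal, 1L)
      sim <- allocate_with_engine(sc$engine, t1, P, dem, cfg, sc$pcfg,
                                  sc$seed)
      list(map = sim, report = agreement(t2, sim))
    })
  }
  tm_proj <- stage("recalibrate",
                   estimate_transition_matrix(crosstab(t1, t2)))
  horizon <- stage("project", {
    P <- calibration_potentials(sc$engine, t1, t2, drivers, sc$seed)
    dem <- demand_from_markov(t2, tm_proj, sc$horizon_steps)
    allocate_with_engine(sc$engine, t2, P, dem, cfg, sc$pcfg, sc$seed)
  })
  areas <- area_table(horizon)
  esv_now <- esv_from_areas(area_table(t2), coeff)
  esv_hor <- esv_from_areas(areas, coeff)
  metrics <- landscape_metrics(list(horizon = horizon))
  out <- structure(list(
    scenario = sc$scenario, engine = sc$engine,
    tm_calibration = tm_cal, tm_projection = tm_proj,
    validation = val, horizon = horizon, areas = areas,
    esv = esv_table(list(base = esv_now, horizon = esv_hor), changes = TRUE),
    esv_change = esv_change(esv_now, esv_hor), metrics = metrics,
    convergence = attr(horizon, "convergence")), class = "pipeline_run")
  if (!is.null(output_dir)) write_pipeline_outputs(out, output_dir)
  out
}

allocate_with_engine <- function(engine, base, P, demand, cfg, pcfg, seed) {
  cfg$seed <- as.integer(seed)
  switch(engine,
    ca_markov = ca_markov_allocate(base, P, demand, window = 5, seed = seed,
                                   restriction = cfg$restriction),
    flus = flus_allocate(base, P, demand, cfg),
    plus = plus_allocate(base, P, demand, cfg, pcfg))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> scenario %s, engine %s\n", x$scenario,
              x$engine))
  if (!is.null(x$validation))
    cat(sprintf("  validation kappa: %.4f (%s)\n",
                x$validation$report$kappa, x$validation$report$band))
  cat(sprintf("  horizon total ESV: %.2f x10^6 yuan/yr (change %+.2f)\n",
              sum(x$esv[nrow(x$esv), 2]), attr(x$esv_change, "total")))
  invisible(x)
}

write_pipeline_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_transition_matrix(run$tm_calibration,
                          file.path(dir, "transition_calibration.csv"))
  write_transition_matrix(run$tm_projection,
                          file.path(dir, "transition_projection.csv"))
  utils::write.csv(data.frame(class = names(run$areas),
                              area_km2 = as.numeric(run$areas)),
                   file.path(dir, "areas_horizon.csv"), row.names = FALSE)
  utils::write.csv(run$esv, file.path(dir, "esv.csv"))
  utils::write.csv(run$metrics, file.path(dir, "metrics.csv"))
  utils::write.csv(run$convergence$log, file.path(dir, "convergence.csv"),
                   row.names = FALSE)
  write_asc(run$horizon, file.path(dir, "lulc_horizon.asc"))
  if (!is.null(run$validation))
    write_agreement(run$validation$report, file.path(dir, "validation.csv"))
  invisible(dir)
}
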