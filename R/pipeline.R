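pipeline_defaults <- function() {
  list(
    mode = "synthetic",
    synthetic = list(
      n_layers = 6, n_rows = 100, n_cols = 100, autocorr_range_cells = 10,
      collinear_pairs = 2, n_presences = 300, prevalence = 0.15,
      relief_m = 3000, developed_fraction = 0.1,
      species = list(coefficients = list(bio1 = c(0, -30),
                                         bio12 = c(0, -30)),
                     intercept = 0),
      shift_direction = c(bio1 = 1),
      severity = c(rcp45_2050 = 0.5, rcp45_2070 = 0.75,
                   rcp85_2050 = 1.0, rcp85_2070 = 1.5),
      base_shift = 0.8, gcm_noise_sd = 0.1),
    paths = list(stack_dir = NULL, occurrences_csv = NULL,
                 footprint_asc = NULL, dem_asc = NULL),
    clade_map = NULL,
    exclusions = list(),
    thinning_radius_km = 10,
    n_pseudo_absences = 10000,
    vif_threshold = 6,
    cor_threshold = 0.75,
    algorithms = c("GLM", "GBM", "SRE", "MAXENT"),
    algorithm_settings = list(),
    n_replicates = 10,
    train_fraction = 0.75,
    gcms = c("gcmA", "gcmB", "gcmC", "gcmD"),
    rcps = c("rcp45", "rcp85"),
    periods = c("2050", "2070"),
    footprint_cutoff = 50,
    dispersal = c("none", "unlimited"),
    connectivity = "rook",
    seed = 1)
}

#' Validate and complete a pipeline configuration
#'
#' Fills unspecified keys with the package defaults (10 km thinning radius,
#' 10,000 pseudo-absences, VIF threshold 6, correlation threshold 0.75, all
#' four algorithms, 10 split-sample replicates at 75/25, footprint cutoff
#' 50, both dispersal scenarios). Unknown keys and non-positive counts are
#' rejected.
#'
#' @param config Named list of overrides (possibly empty), or a path to a
#'   JSON file containing one.
#' @return The resolved configuration list, classed \code{enm_config}.
#' @export
enm_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  if (!is.null(config$synthetic)) {
    unknown <- setdiff(names(config$synthetic), names(defaults$synthetic))
    if (length(unknown))
      stop("unknown synthetic key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  for (key in c("n_pseudo_absences", "n_replicates"))
    cfg[[key]] <- check_count(cfg[[key]], key)
  if (cfg$thinning_radius_km <= 0)
    stop("`thinning_radius_km` must be > 0", call. = FALSE)
  if (cfg$vif_threshold <= 0 || cfg$cor_threshold <= 0)
    stop("collinearity thresholds must be > 0", call. = FALSE)
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  cfg$algorithms <- match.arg(cfg$algorithms,
                              c("GLM", "GBM", "SRE", "MAXENT"),
                              several.ok = TRUE)
  cfg$dispersal <- match.arg(cfg$dispersal, c("none", "unlimited"),
                             several.ok = TRUE)
  if (!cfg$mode %in% c("synthetic", "files"))
    stop("`mode` must be 'synthetic' or 'files'", call. = FALSE)
  structure(cfg, class = c("enm_config", "list"))
}

synthetic_inputs <- function(cfg) {
  s <- cfg$synthetic
  seed <- cfg$seed
  stack <- make_climate_stack(derive_seed(seed, "stack"), s$n_layers,
                              s$n_rows, s$n_cols, s$autocorr_range_cells,
                              s$collinear_pairs)
  g <- stack_geometry(stack)
  dem <- make_dem(derive_seed(seed, "dem"), s$n_rows, s$n_cols, s$relief_m,
                  origin_lon = g$origin_lon, origin_lat = g$origin_lat,
                  cell_size = g$cell_size)
  footprint <- make_footprint(derive_seed(seed, "footprint"), g,
                              s$developed_fraction)
  species <- virtual_species(s$species$coefficients,
                             intercept = s$species$intercept,
                             prevalence_target = s$prevalence)
  species <- freeze_intercept(stack, species)
  truth <- true_suitability(stack, species)
  occs <- sample_occurrences(truth, s$n_presences,
                             derive_seed(seed, "occurrences"))
  # one perturbation per GCM x RCP x period; severity grows with RCP and
  # period, GCMs differ by their smooth disagreement fields
  scenarios <- list()
  direction <- expand_shift(stack, s$shift_direction)
  for (gcm in cfg$gcms) for (rcp in cfg$rcps) for (per in cfg$periods) {
    sev <- s$severity[[paste(rcp, per, sep = "_")]]
    if (is.null(sev)) sev <- 1
    scenarios[[paste(gcm, rcp, per, sep = "|")]] <-
      scenario_perturbation(gcm, rcp, per,
                            additive_shift = s$base_shift * sev * direction,
                            noise_sd = s$gcm_noise_sd)
  }
  list(stack = stack, dem = dem, footprint = footprint, species = species,
       truth = truth, occurrences = occs, scenarios = scenarios)
}

file_inputs <- function(cfg) {
  p <- cfg$paths
  if (is.null(p$stack_dir) || is.null(p$occurrences_csv))
    stop("files mode needs `paths$stack_dir` and `paths$occurrences_csv`",
         call. = FALSE)
  list(stack = read_stack(p$stack_dir),
       dem = if (!is.null(p$dem_asc)) read_ascii_grid(p$dem_asc),
       footprint = if (!is.null(p$footprint_asc))
         read_ascii_grid(p$footprint_asc),
       species = NULL, truth = NULL,
       occurrences = read_occurrences(p$occurrences_csv),
       scenarios = list())
}

#' Run the full range-loss assessment pipeline
#'
#' Executes every stage in order: input generation (or loading), spatial
#' thinning, clade pooling, pseudo-absence sampling, collinearity-based
#' predictor selection, ensemble fitting with split-sample evaluation,
#' current-climate projection, MPA binarization, human-footprint masking,
#' per-scenario future projection under each dispersal scenario,
#' range-change statistics, threat classification and landscape metrics.
#' Every random stage draws from a seed derived from the master seed and
#' the stage name, so the whole run is reproducible from the configuration
#' alone.
#'
#' @param config An \code{enm_config} (or a list of overrides passed
#'   through \code{enm_config}).
#' @param scenarios Optional named list of \code{scenario_perturbation}s to
#'   use instead of the configuration's synthetic default grid.
#' @param out_dir Optional directory: when given, maps, tables, the risk
#'   report and a checksum manifest are written there.
#' @return List of class \code{enm_run} with elements \code{config},
#'   \code{inputs}, \code{selection}, \code{model} (the fitted
#'   \code{enm}), \code{mpa}, \code{current} (binary range),
#'   \code{changes}, \code{risk} (a \code{risk_report}), \code{gcm_summary}.
#' @export
run_enm_pipeline <- function(config = list(), scenarios = NULL,
                             out_dir = NULL) {
  cfg <- if (inherits(config, "enm_config")) config else enm_config(config)
  seed <- cfg$seed
  inputs <- if (cfg$mode == "synthetic") synthetic_inputs(cfg)
            else file_inputs(cfg)
  if (!is.null(scenarios)) inputs$scenarios <- scenarios

  # occurrences: thin, then pool (identity map when none given)
  thinned <- thin_occurrences(inputs$occurrences, cfg$thinning_radius_km,
                              seed = derive_seed(seed, "thin"))
  clade_map <- cfg$clade_map
  if (is.null(clade_map)) {
    labs <- unique(thinned$clade)
    clade_map <- stats::setNames(as.list(labs), labs)
  }
  clades <- pool_by_clade(thinned, clade_map, cfg$exclusions)

  pa <- sample_pseudo_absences(inputs$stack, cfg$n_pseudo_absences,
                               seed = derive_seed(seed, "pseudo_absences"))
  pa_values <- extract_values(inputs$stack, pa)

  results <- lapply(names(clades), function(cl) {
    occs <- clades[[cl]]
    pres_values <- extract_values(inputs$stack, occs)
    table <- build_training_table(pres_values, pa_values)
    selection <- select_predictors(table, cfg$vif_threshold,
                                   cfg$cor_threshold)
    model <- enm(table, cfg$algorithms, cfg$n_replicates,
                 cfg$train_fraction, seed = derive_seed(seed, "enm", cl),
                 settings = cfg$algorithm_settings,
                 predictors = as.character(selection))
    current_map <- predict(model, inputs$stack)
    mpa <- mpa_threshold(current_map, occs)
    current <- binarize(current_map, mpa)
    if (!is.null(inputs$footprint))
      current <- apply_footprint_mask(current, inputs$footprint,
                                      cfg$footprint_cutoff)
    changes <- list()
    future_bins <- list()
    for (sc_name in names(inputs$scenarios)) {
      pert <- inputs$scenarios[[sc_name]]
      fut_stack <- make_future_stack(inputs$stack, pert,
                                     seed = derive_seed(seed, "future", cl))
      fut_map <- predict(model, fut_stack)
      fut_bin0 <- binarize(fut_map, mpa)
      if (!is.null(inputs$footprint))
        fut_bin0 <- apply_footprint_mask(fut_bin0, inputs$footprint,
                                         cfg$footprint_cutoff)
      for (disp in cfg$dispersal) {
        fb <- apply_dispersal(current, fut_bin0, disp)
        ch <- range_change(current, fb)
        key <- paste(pert$gcm_name, pert$rcp_name, pert$period, disp,
                     sep = "|")
        changes[[key]] <- cbind(
          data.frame(gcm = pert$gcm_name, rcp = pert$rcp_name,
                     period = pert$period, dispersal = disp), ch)
        future_bins[[key]] <- fb
      }
    }
    changes <- if (length(changes)) do.call(rbind, changes) else
      data.frame()
    rownames(changes) <- NULL
    risk <- if (nrow(changes))
      assess_risk(cl, changes, current, future_bins, inputs$dem,
                  cfg$connectivity) else NULL
    list(clade = cl, table = table, selection = selection, model = model,
         current_map = current_map, mpa = mpa, current = current,
         changes = changes, future_bins = future_bins, risk = risk)
  })
  names(results) <- names(clades)

  changes_all <- do.call(rbind, c(lapply(results, function(r)
    if (nrow(r$changes))
      cbind(data.frame(clade = r$clade), r$changes) else NULL),
    make.row.names = FALSE))
  risk_all <- do.call(rbind, c(lapply(results, function(r) r$risk),
                               make.row.names = FALSE))
  gcm_summary <- summarize_across_gcms(changes_all)

  run <- structure(
    list(config = cfg, inputs = inputs, clades = results,
         changes = changes_all, risk = risk_all,
         gcm_summary = gcm_summary),
    class = "enm_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Summarize range change across GCMs
#'
#' Mean and standard deviation of the change statistics across GCMs for
#' each clade x RCP x period x dispersal combination, mirroring the
#' convention of reporting per-GCM statistics with a between-GCM SD.
#'
#' @param changes Data frame of per-scenario change rows (with clade, gcm,
#'   rcp, period, dispersal columns).
#' @return Data frame of grouped means and SDs.
#' @export
summarize_across_gcms <- function(changes) {
  if (is.null(changes) || !nrow(changes)) return(NULL)
  groups <- split(changes,
                  interaction(changes$clade, changes$rcp, changes$period,
                              changes$dispersal, drop = TRUE))
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(clade = g$clade[1L], rcp = g$rcp[1L], period = g$period[1L],
               dispersal = g$dispersal[1L], n_gcms = nrow(g),
               mean_stable_pct = mean(g$stable_pct),
               sd_stable_pct = stats::sd(g$stable_pct),
               mean_loss_pct = mean(g$loss_pct),
               sd_loss_pct = stats::sd(g$loss_pct),
               mean_gain_pct = mean(g$gain_pct),
               sd_gain_pct = stats::sd(g$gain_pct))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.enm_run <- function(x, ...) {
  cat(sprintf("<enm_run> %d clade(s), %d scenario row(s)\n",
              length(x$clades),
              if (is.null(x$changes)) 0L else nrow(x$changes)))
  if (!is.null(x$gcm_summary)) {
    cat("Across-GCM no-dispersal loss summary:\n")
    s <- x$gcm_summary[x$gcm_summary$dispersal == "none", ]
    print(s[, c("clade", "rcp", "period", "mean_loss_pct", "sd_loss_pct")],
          row.names = FALSE)
  }
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(fname, writer) {
    path <- file.path(out_dir, fname)
    writer(path)
    files <<- c(files, fname)
  }
  if (!is.null(run$changes) && nrow(run$changes))
    put("range_change.csv", function(p)
      utils::write.csv(run$changes, p, row.names = FALSE, quote = FALSE))
  if (!is.null(run$risk))
    put("risk_report.csv", function(p) write_risk_report(run$risk, p))
  if (!is.null(run$gcm_summary))
    put("gcm_summary.csv", function(p)
      utils::write.csv(run$gcm_summary, p, row.names = FALSE, quote = FALSE))
  for (cl in names(run$clades)) {
    r <- run$clades[[cl]]
    put(sprintf("suitability_current_%s.asc", cl), function(p)
      write_ascii_grid(r$current_map, p))
    put(sprintf("evaluation_%s.csv", cl), function(p)
      utils::write.csv(r$model$evaluation, p, row.names = FALSE,
                       quote = FALSE))
  }
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(files = stats::setNames(as.list(unname(sums)), files),
                   seed = run$config$seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
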