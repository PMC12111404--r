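#' Pipeline configuration
#'
#' Bundles every knob of the simulate -> fit -> importance -> optimize
#' workflow. Exactly one data source must be active: a synthetic surface
#' (`surface`) or a CSV of measured experiments (`input_csv`). A single
#' master seed fans out to stage seeds through [derive_seed()] with fixed
#' stage counters, so each stage is individually reproducible.
#'
#' @param bounds a [process_bounds()].
#' @param surface a [surface_spec()], or NULL when reading measured data.
#' @param input_csv path to an experiment CSV, or NULL when simulating.
#' @param design list `(scheme, n)` for the synthetic design (default
#'   Latin hypercube, 33 runs).
#' @param topology list `(sizes, repeats, inits)`; a single size skips the
#'   scan and fits that topology directly (best of `inits`).
#' @param pso a [pso_config()]; its seed is overridden by the master seed.
#' @param n_restarts swarm restarts (default 5).
#' @param master_seed integer master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(bounds = process_bounds(),
                            surface = make_default_spec(),
                            input_csv = NULL,
                            design = list(scheme = "latin_hypercube", n = 33),
                            topology = list(sizes = 10, repeats = 10, inits = 10),
                            pso = pso_config(),
                            n_restarts = 5,
                            master_seed = 1) {
  if (is.null(surface) == is.null(input_csv)) {
    stop("exactly one of 'surface' and 'input_csv' must be given",
         call. = FALSE)
  }
  if (!is.null(surface)) stopifnot(inherits(surface, "surface_spec"))
  stopifnot(inherits(bounds, "process_bounds"), inherits(pso, "pso_config"))
  stop_if_not_scalar_number(master_seed, "master_seed")
  structure(list(bounds = bounds, surface = surface, input_csv = input_csv,
                 design = design, topology = topology, pso = pso,
                 n_restarts = n_restarts,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Run the full dephenolization-optimization workflow
#'
#' Executes, in order: data acquisition (simulate from the configured
#' surface, or read a measured CSV), hidden-layer selection (skipped when a
#' single size is configured), best-of-inits Levenberg-Marquardt training,
#' connection-weight importance, and particle-swarm maximization of the
#' fitted surrogate with restart-stability checking. The whole run is a
#' deterministic function of the configuration and its master seed.
#'
#' Stage seeds: design/simulation uses counter 1, topology scan counter 2,
#' final fit counter 3, swarm counter 4.
#'
#' @param config a [pipeline_config()].
#' @param output_dir if non-NULL, persists `experiments.csv` (+ sidecar),
#'   `model.json`, `report.json` and a human-readable `summary.txt` there.
#' @param verbose print stage progress (default FALSE).
#' @return object of class `optimization_report`: the experiment table,
#'   topology scan (or NULL), fit metrics, relative importance, swarm
#'   result, the optimal condition with its predicted TPC, and a config
#'   echo.
#' @export
run_pipeline <- function(config, output_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$master_seed

  if (!is.null(config$surface)) {
    design <- generate_design(config$bounds, n = config$design$n,
                              scheme = config$design$scheme,
                              seed = derive_seed(seed, 1, 1))
    tab <- simulate_experiments(config$surface, design,
                                seed = derive_seed(seed, 1, 2))
    say("data: simulated %d runs (noise_sd = %g)", nrow(tab),
        config$surface$noise_sd)
  } else {
    tab <- read_experiments(config$input_csv)
    say("data: read %d runs from %s", nrow(tab), config$input_csv)
  }

  sizes <- as.integer(config$topology$sizes)
  scan <- NULL
  if (length(sizes) > 1L) {
    scan <- select_topology(tab, hidden_sizes = sizes,
                            n_repeats = config$topology$repeats,
                            n_inits = config$topology$inits,
                            seed = derive_seed(seed, 2, 1))
    n_hidden <- scan$selected
    say("topology: selected %d hidden neurons (mean R2 = %.3f)", n_hidden,
        scan$scan$mean_r2[scan$scan$n_hidden == n_hidden])
  } else {
    n_hidden <- sizes
    say("topology: fixed at %d hidden neurons", n_hidden)
  }

  fit <- fit_best(tab, n_hidden = n_hidden, n_inits = config$topology$inits,
                  seed = derive_seed(seed, 3, 1))
  say("fit: R2 = %.4f, MAE = %.2f mg GAE/100 g", fit$r2, fit$mae)

  ri <- yoon_ri(fit$params)
  say("importance: %s", paste(sprintf("%s %.1f%%", names(ri$ri), ri$ri),
                              collapse = ", "))

  pso_cfg <- config$pso
  pso_cfg$seed <- derive_seed(seed, 4, 1)
  opt <- optimize_surrogate(fit, config$bounds, pso_cfg,
                            n_restarts = config$n_restarts)
  say("optimum: etoh %.2f%%, S/L %.1f mL/g, %.2f min -> %.2f mg GAE/100 g (spread %.2f%%)",
      opt$best_x["etoh"], opt$best_x["sl"], opt$best_x["time"], opt$best_f,
      opt$restart_spread)

  report <- structure(
    list(table = tab, topology_scan = scan, n_hidden = n_hidden, fit = fit,
         r2 = fit$r2, mae = fit$mae, importance = ri, pso = opt,
         optimal_condition = opt$best_x, predicted_tpc = opt$best_f,
         config = config,
         version = as.character(utils::packageVersion("dephenolize"))),
    class = "optimization_report"
  )
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.optimization_report <- function(x, ...) {
  cat("Dephenolization optimization report\n")
  cat(sprintf("  data: %d runs (%s)\n", nrow(x$table),
              attr(x$table, "provenance")))
  cat(sprintf("  surrogate: %d hidden neurons, R2 = %.4f, MAE = %.2f mg GAE/100 g\n",
              x$n_hidden, x$r2, x$mae))
  cat(sprintf("  importance: %s\n",
              paste(sprintf("%s %+.2f%%", names(x$importance$ri),
                            x$importance$ri), collapse = ", ")))
  # display rounding: ethanol 0.1%, S/L 1 mL/g, time 0.1 min
  cat(sprintf("  optimum: %.1f%% EtOH, %.0f mL/g, %.1f min\n",
              x$optimal_condition["etoh"], x$optimal_condition["sl"],
              x$optimal_condition["time"]))
  cat(sprintf("  predicted TPC: %.2f mg GAE/100 g (restart spread %.2f%%%s)\n",
              x$predicted_tpc, x$pso$restart_spread,
              if (isTRUE(x$pso$stable)) "" else ", UNSTABLE"))
  invisible(x)
}

# Persist a report: experiments CSV + sidecar, model JSON, report JSON,
# plain-text summary. Numbers are stored unrounded; only summary.txt rounds.
write_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_experiments(report$table, file.path(output_dir, "experiments.csv"))
  write_fit(report$fit, file.path(output_dir, "model.json"))
  obj <- list(
    version = report$version,
    n_hidden = report$n_hidden,
    r2 = report$r2, mae = report$mae,
    topology_scan = if (!is.null(report$topology_scan))
      report$topology_scan$scan,
    importance = as.list(report$importance$ri),
    importance_rank = report$importance$rank_order,
    optimal_condition = as.list(report$optimal_condition),
    predicted_tpc_mg_gae_per_100g = report$predicted_tpc,
    restart_bests = report$pso$restart_bests,
    restart_spread_pct = report$pso$restart_spread,
    stable = report$pso$stable,
    master_seed = report$config$master_seed
  )
  jsonlite::write_json(obj, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(file.path(output_dir, "summary.txt"), "w")
  sink(con)
  print(report)
  sink()
  close(con)
  invisible(output_dir)
}
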