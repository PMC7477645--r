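# Orchestration: run configuration (YAML-backed, schema-validated) and the
# end-to-end pipeline from containers (real or synthetic) to statistics.

run_config_schema <- function() {
  list(
    seed = NULL, output_dir = NULL, log_level = NULL,
    input = list(container = NULL, subjects = NULL),
    tip = list(half_angle = NULL, radius = NULL,
               geometry_coefficient = NULL, poisson_ratio = NULL),
    preprocessing = list(baseline_fraction = NULL, noise_sigma = NULL,
                         spring_constant = NULL),
    tomography = list(max_depth = NULL, segment_width = NULL,
                      fit_segments = NULL, cell_aggregate = NULL,
                      subject_aggregate = NULL, render = NULL,
                      write_results = NULL),
    stats = list(alpha_var = NULL, variance_gate = NULL, p_adjust = NULL),
    simulate = list(
      enabled = NULL,
      cohort = list(scale = NULL),
      force_volumes = list(enabled = NULL, grid = NULL,
                           cells_per_subject = NULL)))
}

check_keys <- function(cfg, schema, path = "") {
  if (!is.list(cfg)) return(invisible())
  bad <- setdiff(names(cfg), names(schema))
  if (length(bad))
    cm_abort(sprintf("unknown config key%s: %s",
                     if (length(bad) > 1) "s" else "",
                     paste0(path, bad, collapse = ", ")),
             "cm_config_error")
  for (k in names(cfg))
    if (is.list(schema[[k]]))
      check_keys(cfg[[k]], schema[[k]], paste0(path, k, "."))
  invisible()
}

#' Default pipeline configuration
#'
#' A complete, resolved configuration for a simulate-then-analyze run:
#' default cohort design, force-volume measurement of Ea on 3 cells of
#' 4x4 curves per subject, median-over-pixels / mean-over-cells
#' aggregation, F-test variance gate, no multiplicity correction.
#'
#' @param seed integer seed driving every random stage.
#' @param output_dir directory for the report bundle.
#' @return a validated config list of class `"run_config"`.
#' @export
default_run_config <- function(seed = 1L, output_dir = tempfile("cmrun")) {
  validate_run_config(list(
    seed = as.integer(seed), output_dir = output_dir, log_level = "info",
    input = list(container = NULL, subjects = NULL),
    tip = list(half_angle = 20, radius = 10,
               geometry_coefficient = 2 / pi, poisson_ratio = 0.5),
    preprocessing = list(baseline_fraction = 0.3, noise_sigma = NULL,
                         spring_constant = NULL),
    tomography = list(max_depth = 50, segment_width = 5,
                      fit_segments = TRUE, cell_aggregate = "median",
                      subject_aggregate = "mean", render = "first",
                      write_results = TRUE),
    stats = list(alpha_var = 0.05, variance_gate = "ftest",
                 p_adjust = "none"),
    simulate = list(enabled = TRUE,
                    cohort = list(scale = 1),
                    force_volumes = list(enabled = TRUE, grid = c(4, 4),
                                         cells_per_subject = 3))))
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys anywhere in the nested structure and checks the
#' fields needed before any computation starts.
#'
#' @param config a config list (e.g. from [read_run_config()]).
#' @return the config, classed `"run_config"`.
#' @export
validate_run_config <- function(config) {
  check_keys(config, run_config_schema())
  if (is.null(config$seed) || !is_scalar_number(config$seed))
    cm_abort("config needs a scalar 'seed'", "cm_config_error")
  if (is.null(config$output_dir))
    cm_abort("config needs an 'output_dir'", "cm_config_error")
  sim <- isTRUE(config$simulate$enabled)
  if (!sim && is.null(config$input$subjects) && is.null(config$input$container))
    cm_abort("config needs either simulate.enabled or an input path",
             "cm_config_error")
  agg <- config$tomography$cell_aggregate %||% "median"
  if (!agg %in% c("median", "mean"))
    cm_abort("tomography.cell_aggregate must be 'median' or 'mean'",
             "cm_config_error")
  structure(config, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file mirroring [default_run_config()].
#' @return validated config of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    cm_abort(sprintf("config file not found: '%s'", path), "cm_config_error")
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_run_config(seed = cfg$seed %||% 1L))
  merged <- utils::modifyList(base, cfg, keep.null = TRUE)
  validate_run_config(merged)
}

config_tip <- function(config) {
  tip_geometry(half_angle = config$tip$half_angle %||% 20,
               radius = config$tip$radius %||% 10,
               geometry_coefficient = config$tip$geometry_coefficient %||% (2 / pi),
               poisson_ratio = config$tip$poisson_ratio %||% 0.5)
}

#' Run the full analysis pipeline
#'
#' Composes all stages in acquisition order: obtain a subject table
#' (simulated cohort or CSV), optionally measure each subject's apparent
#' modulus from force volumes (simulated per subject, or read from a
#' container), then compute the cohort statistics and write the report
#' bundle: subject table, comparison and correlation CSVs, tomogram and
#' heat-map PNGs, a machine-readable JSON summary and the resolved
#' configuration. Deterministic given config + seed.
#'
#' @param config a `"run_config"` (see [default_run_config()],
#'   [read_run_config()]).
#' @return invisibly, a list with the cohort, tomography counters,
#'   statistics objects and the paths written.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(unclass(config))
  quiet <- identical(config$log_level, "quiet")
  log <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tip <- config_tip(config)
  seed <- as.integer(config$seed)

  # stage 1: subject table ------------------------------------------------
  if (isTRUE(config$simulate$enabled)) {
    sim_cfg <- cohort_sim_config(scale = config$simulate$cohort$scale %||% 1,
                                 seed = child_seed(seed, 1))
    cohort <- generate_cohort(sim_cfg)
    log("stage cohort: simulated %d subjects (seed %d)", nrow(cohort),
        sim_cfg$seed)
  } else if (!is.null(config$input$subjects)) {
    cohort <- read_subjects_csv(config$input$subjects)
    log("stage cohort: read %d subjects from %s", nrow(cohort),
        config$input$subjects)
  } else {
    cohort <- NULL
  }

  # stage 2: force volumes -> Ea -------------------------------------------
  counters <- list(curves = 0L, pixels_fitted = 0L, pixels_masked = 0L,
                   cells = 0L)
  tomo_cfg <- list(baseline_fraction = config$preprocessing$baseline_fraction %||% 0.3,
                   noise_sigma = config$preprocessing$noise_sigma,
                   spring_constant = config$preprocessing$spring_constant,
                   max_depth = config$tomography$max_depth %||% 50,
                   segment_width = config$tomography$segment_width %||% 5,
                   fit_segments = config$tomography$fit_segments %||% TRUE)
  results_rows <- list()
  render <- config$tomography$render %||% "first"
  rendered <- FALSE

  analyze_cells <- function(cell_list, subject_id) {
    summaries <- list()
    for (cid in names(cell_list)) {
      tomo <- analyze_cell(cell_list[[cid]], tip,
                           c(tomo_cfg, list(cell_id = cid)))
      counters$curves <<- counters$curves + tomo$n_curves
      counters$pixels_fitted <<- counters$pixels_fitted + tomo$n_used
      counters$pixels_masked <<- counters$pixels_masked + tomo$n_failed
      counters$cells <<- counters$cells + 1L
      if (isTRUE(config$tomography$write_results %||% TRUE))
        results_rows[[length(results_rows) + 1L]] <<-
          cbind(subject_id = subject_id, as.data.frame(tomo))
      if ((render == "first" && !rendered) || render == "all") {
        render_tomogram(tomo, file.path(out_dir,
                                        paste0("tomogram_", cid, ".png")))
        rendered <<- TRUE
      }
      summaries[[cid]] <- summarize_cell(
        tomo, aggregate = config$tomography$cell_aggregate %||% "median")
    }
    summaries
  }

  fv_cfg <- config$simulate$force_volumes
  if (isTRUE(config$simulate$enabled) && isTRUE(fv_cfg$enabled)) {
    grid <- fv_cfg$grid %||% c(4, 4)
    n_cells <- fv_cfg$cells_per_subject %||% 3
    cohort$ea_true <- cohort$ea
    for (i in seq_len(nrow(cohort))) {
      prof <- subject_depth_profile(cohort$ea_true[i], tip = tip)
      cells <- list()
      for (j in seq_len(n_cells)) {
        cid <- sprintf("%s_cell%02d", cohort$subject_id[i], j)
        fv <- generate_force_volume(prof, instrument_model(),
                                    grid_shape = grid,
                                    seed = child_seed(seed, 100 + i * 101 + j),
                                    tip = tip, cell_id = cid)
        cells[[cid]] <- fv$curves
      }
      summaries <- analyze_cells(cells, cohort$subject_id[i])
      cohort$ea[i] <- summarize_subject(
        summaries,
        aggregate = config$tomography$subject_aggregate %||% "mean")$ea_subject
    }
    log("stage tomography: %d curves, %d pixels fitted, %d masked, %d cells (conservation %s)",
        counters$curves, counters$pixels_fitted, counters$pixels_masked,
        counters$cells,
        identical(counters$pixels_fitted + counters$pixels_masked,
                  counters$curves))
  } else if (!is.null(config$input$container)) {
    cell_list <- read_force_volume(config$input$container)
    summaries <- analyze_cells(cell_list, NA_character_)
    log("stage tomography: %d curves, %d pixels fitted, %d masked, %d cells",
        counters$curves, counters$pixels_fitted, counters$pixels_masked,
        counters$cells)
  }
  if (length(results_rows))
    utils::write.csv(do.call(rbind, results_rows),
                     file.path(out_dir, "results_pixels.csv"),
                     row.names = FALSE)

  # stage 3: statistics -----------------------------------------------------
  if (is.null(cohort))
    cm_abort("no subject table available for statistics", "cm_data_error")
  alpha_var <- config$stats$alpha_var %||% 0.05
  gate <- config$stats$variance_gate %||% "ftest"
  comparisons <- list()
  for (v in c("ea", "nmf", "tewl")) {
    comparisons[[v]] <- compare_groups(
      cohort[[v]][cohort$group == "AD"],
      cohort[[v]][cohort$group == "control"],
      alpha_var = alpha_var, variance_gate = gate, variable = v,
      groups = c("AD", "control"))
  }
  genotype <- compare_groups_by_genotype(
    cohort, alpha_var = alpha_var, variance_gate = gate,
    p_adjust = config$stats$p_adjust %||% "none")
  corr <- spearman_matrix(cohort)
  reg <- regression_r2(cohort$nmf, cohort$ea)
  demo <- summarize_demographics(cohort)
  log("stage stats: %d subjects analyzed (%d AD, %d control)",
      nrow(cohort), sum(cohort$group == "AD"),
      sum(cohort$group == "control"))

  # stage 4: report bundle --------------------------------------------------
  utils::write.csv(as.data.frame(cohort),
                   file.path(out_dir, "subjects.csv"), row.names = FALSE)
  comp_tab <- rbind(
    do.call(rbind, lapply(comparisons, as_row.group_comparison)),
    as.data.frame(genotype))
  utils::write.csv(comp_tab, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(corr$rho),
                   file.path(out_dir, "correlation_rho.csv"))
  utils::write.csv(as.data.frame(corr$p),
                   file.path(out_dir, "correlation_p.csv"))
  grDevices::png(file.path(out_dir, "correlation_heatmap.png"),
                 width = 700, height = 600)
  plot(corr)
  grDevices::dev.off()
  summary_json <- list(
    n_subjects = nrow(cohort),
    counters = counters,
    group_means = lapply(comparisons, function(gc) as.list(gc$group_means)),
    group_p = lapply(comparisons, function(gc) gc$p_two_sided),
    spearman = list(
      rho_ea_nmf = corr$rho["ea", "nmf"],
      rho_ea_tewl = corr$rho["ea", "tewl"],
      rho_nmf_tewl = corr$rho["nmf", "tewl"],
      rho_ea_scorad = corr$rho["ea", "scorad"],
      p_ea_nmf = corr$p["ea", "nmf"],
      p_ea_tewl = corr$p["ea", "tewl"],
      p_nmf_tewl = corr$p["nmf", "tewl"],
      p_ea_scorad = corr$p["ea", "scorad"]),
    regression_r2 = reg$r_squared)
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "resolved_config.yaml"))
  log("report bundle written to %s", out_dir)
  invisible(list(cohort = cohort, counters = counters,
                 comparisons = comparisons, genotype = genotype,
                 correlations = corr, regression = reg,
                 demographics = demo, output_dir = out_dir))
}
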