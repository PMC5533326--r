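default_run_config <- function() {
  list(
    simulate = list(
      axis_points = 467, axis_high = 1800, axis_low = 900,
      alpha_max = 0.7, tau = 12, noise_sd = 2e-4,
      scatter_range = c(0.95, 1.05),
      baseline_offset_range = c(-0.02, 0.02),
      baseline_slope_range = c(-1e-6, 1e-6),
      replicates = 1,
      calibration_design = list(pmi_h = seq(0, 48, 6), n = rep(8, 9)),
      prediction_design = list(pmi_h = seq(3, 45, 6), n = rep(3, 8))),
    input = list(calibration = NA_character_, prediction = NA_character_,
                 reference = NA_character_, a414 = NA_character_),
    preprocess = list(snv = TRUE, sg = TRUE, sg_window = 7, sg_polyorder = 2,
                      edge_policy = "shrink"),
    region = list(high = 1800, low = 900),
    outliers = list(policy = "default"),
    pls = list(max_lv = 15, improvement = 0.05),
    ga = list(enabled = TRUE, bin_width = 3, n_runs = 100, population = 30,
              n_evaluations = 200, p_crossover = 0.5, p_mutation = 0.01,
              elitism = 2, tournament = 3, fitness_max_lv = 10,
              frequency_threshold = 0.5),
    similarity = list(enabled = TRUE),
    a414 = list(enabled = TRUE, a0 = 0.05, gain = 1.2, late_dip = 0.03,
                noise_sd = 0.02),
    seed = 1)
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a JSON file path or a nested list. Exactly one of the `simulate`
#' or `input` blocks must be given; defaults are filled for everything else;
#' unknown keys are rejected by their dotted path (typo guard).
#'
#' @param config path to a JSON config file, or a nested list.
#' @return a normalized `run_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort_plasmapls(sprintf("no such config file: %s", config), "config_invalid")
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) abort_plasmapls("config must be a list", "config_invalid")
  defaults <- default_run_config()
  has_sim <- "simulate" %in% names(config)
  has_input <- "input" %in% names(config) &&
    !all(is.na(unlist(config$input)))
  if (has_sim == has_input) {
    abort_plasmapls(
      "exactly one of the required blocks `simulate` or `input` must be present",
      "config_invalid")
  }
  check_unknown <- function(x, ref, path) {
    extra <- setdiff(names(x), names(ref))
    if (length(extra) > 0) {
      abort_plasmapls(
        sprintf("unknown config key(s): %s",
                paste0(if (nzchar(path)) paste0(path, ".") else "", extra,
                       collapse = ", ")),
        "config_unknown_key")
    }
    for (nm in names(x)) {
      if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) && is.list(x[[nm]])) {
        check_unknown(x[[nm]], ref[[nm]],
                      if (nzchar(path)) paste0(path, ".", nm) else nm)
      }
    }
  }
  check_unknown(config, defaults, "")
  merged <- utils::modifyList(defaults, config, keep.null = TRUE)
  merged$mode <- if (has_sim) "simulate" else "input"
  if (has_input) {
    for (f in c("calibration", "prediction")) {
      path <- merged$input[[f]]
      if (is.na(path) || !file.exists(path)) {
        abort_plasmapls(sprintf("input.%s file not found: %s", f, path),
                        "config_invalid")
      }
    }
  }
  structure(merged, class = "run_config")
}

synth_config_from_run <- function(config) {
  s <- config$simulate
  synth_config(
    axis = seq(s$axis_high, s$axis_low, length.out = s$axis_points),
    alpha_max = s$alpha_max, tau = s$tau, noise_sd = s$noise_sd,
    scatter_range = s$scatter_range,
    baseline_offset_range = s$baseline_offset_range,
    baseline_slope_range = s$baseline_slope_range,
    calibration_design = as.data.frame(s$calibration_design),
    prediction_design = as.data.frame(s$prediction_design),
    a414_params = config$a414[c("a0", "gain", "late_dip", "noise_sd")],
    replicates = s$replicates,
    seed = config$seed)
}

run_stage <- function(name, expr, out_dir) {
  tryCatch(expr, error = function(e) {
    if (!is.null(out_dir)) {
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
    }
    abort_plasmapls(
      sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      "pipeline_stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Fixed stage order: acquire data (simulate or read) -> preprocess ->
#' region slice -> outlier screening -> full-spectrum PLS evaluation ->
#' GA-PLS selection and evaluation -> similarity profiling -> A414 trend.
#' The same config and seed give an identical report.
#'
#' @param config a [validate_config()] result, config file path, or list.
#' @param out_dir optional directory; stage artifacts (CSV/JSON) are written
#'   there when given.
#' @return a `run_report` list: `$table2` (one evaluation row per model),
#'   `$outliers`, `$selection`, `$similarity`, `$a414`, `$provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  save_csv <- function(x, name) {
    if (!is.null(out_dir)) readr::write_csv(x, file.path(out_dir, name))
  }

  # --- stage: data -----------------------------------------------------------
  reference_raw <- NULL
  if (config$mode == "simulate") {
    data <- run_stage("simulate", {
      scfg <- synth_config_from_run(config)
      sets <- simulate_dataset(scfg)
      if (config$simulate$replicates > 1) {
        sets$calibration <- average_replicates(sets$calibration)
        sets$prediction <- average_replicates(sets$prediction)
      }
      em <- make_endmembers(scfg)
      reference_raw <- new_spectra(matrix(em$formed, nrow = 1), em$wavenumber,
                                   sample_id = "formed_0h", pmi_h = 0)
      a414_tbl <- if (config$a414$enabled) simulate_a414(scfg) else NULL
      list(calibration = sets$calibration, prediction = sets$prediction,
           reference = reference_raw, a414 = a414_tbl)
    }, out_dir)
  } else {
    data <- run_stage("read", {
      ref <- if (!is.na(config$input$reference)) read_spectra(config$input$reference)
      a414_tbl <- if (!is.na(config$input$a414)) {
        readr::read_csv(config$input$a414, show_col_types = FALSE)
      }
      list(calibration = read_spectra(config$input$calibration),
           prediction = read_spectra(config$input$prediction),
           reference = ref, a414 = a414_tbl)
    }, out_dir)
  }

  # --- stage: preprocess + slice --------------------------------------------
  pp <- config$preprocess
  prep <- run_stage("preprocess", {
    f <- function(ds) {
      out <- preprocess_spectra(ds, snv = pp$snv, sg = pp$sg,
                                sg_window = pp$sg_window,
                                sg_polyorder = pp$sg_polyorder,
                                edge_policy = pp$edge_policy)
      slice_region(out, config$region$high, config$region$low)
    }
    ref <- if (!is.null(data$reference)) f(data$reference)
    list(calibration = f(data$calibration), prediction = f(data$prediction),
         reference = ref)
  }, out_dir)

  # --- stage: outliers -------------------------------------------------------
  scr <- run_stage("outliers", {
    flag_outliers(prep$calibration, policy = config$outliers$policy,
                  max_lv = config$pls$max_lv,
                  improvement = config$pls$improvement)
  }, out_dir)
  save_csv(scr$report, "outliers.csv")

  # --- stage: full-spectrum PLS ---------------------------------------------
  full_report <- run_stage("pls", {
    evaluate_pls(scr$retained, prep$prediction,
                 max_lv = config$pls$max_lv,
                 improvement = config$pls$improvement,
                 method = "Full-spectrum PLS")
  }, out_dir)

  # --- stage: GA-PLS ---------------------------------------------------------
  selection <- NULL
  ga_report <- NULL
  if (isTRUE(config$ga$enabled)) {
    selection <- run_stage("ga_select", {
      gcfg <- ga_config(
        bin_width = config$ga$bin_width, n_runs = config$ga$n_runs,
        population = config$ga$population,
        n_evaluations = config$ga$n_evaluations,
        p_crossover = config$ga$p_crossover,
        p_mutation = config$ga$p_mutation, elitism = config$ga$elitism,
        tournament = config$ga$tournament,
        fitness_max_lv = config$ga$fitness_max_lv,
        frequency_threshold = config$ga$frequency_threshold,
        seed = derive_seed(config$seed, "ga"))
      ga_select(scr$retained, config = gcfg)
    }, out_dir)
    save_csv(selection$frequency, "ga_frequency.csv")
    ga_report <- run_stage("ga_pls", {
      fit_selected(scr$retained, prep$prediction, selection,
                   max_lv = config$pls$max_lv,
                   improvement = config$pls$improvement)
    }, out_dir)
  }

  # --- stage: similarity -----------------------------------------------------
  similarity <- NULL
  if (isTRUE(config$similarity$enabled) && !is.null(prep$reference)) {
    similarity <- run_stage("similarity", {
      axis <- wavenumbers(prep$calibration)
      ref <- drop(spectra_matrix(prep$reference))
      masks <- list(full = axis)
      if (!is.null(selection)) {
        masks$ga_selected <- axis[selection$retained_variables]
        masks$ga_excluded <- setdiff(axis, masks$ga_selected)
      }
      profiles <- purrr::imap_dfr(masks, function(m, lab) {
        similarity_profile(prep$calibration, ref, mask = m, mask_label = lab)
      })
      stats_tbl <- profile_group_stats(profiles)
      anovas <- lapply(split(profiles, profiles$mask), function(d) {
        an <- one_way_anova(d, cos2, pmi_h)
        glance(an)
      })
      list(profiles = profiles, group_stats = stats_tbl,
           anova = dplyr::bind_rows(anovas, .id = "mask"))
    }, out_dir)
    save_csv(similarity$profiles, "similarity_profiles.csv")
    save_csv(similarity$group_stats, "similarity_group_stats.csv")
  }

  # --- stage: a414 -----------------------------------------------------------
  a414 <- NULL
  if (!is.null(data$a414)) {
    a414 <- run_stage("a414", a414_trend(data$a414), out_dir)
    save_csv(a414$groups, "a414_groups.csv")
  }

  table2 <- dplyr::bind_rows(
    glance(full_report),
    if (!is.null(ga_report)) glance(ga_report))
  save_csv(table2, "model_reports.csv")

  cfg_for_hash <- unclass(config)
  report <- list(
    table2 = table2,
    outliers = scr$report,
    outlier_thresholds = scr$thresholds,
    selection = selection,
    full_report = full_report,
    ga_report = ga_report,
    similarity = similarity,
    a414 = a414,
    provenance = list(seed = config$seed,
                      config_hash = rlang::hash(cfg_for_hash),
                      package_version = as.character(utils::packageVersion("plasmapls")),
                      mode = config$mode))
  class(report) <- "run_report"
  if (!is.null(out_dir)) {
    jsonlite::write_json(report_as_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# JSON-friendly subset of a run report (deterministic: no timestamps)
report_as_json <- function(report) {
  list(
    table2 = report$table2,
    outliers_removed = report$outliers$sample_id[report$outliers$outlier],
    selection = if (!is.null(report$selection)) {
      list(retained_bins = report$selection$retained_bins,
           retained_variables = report$selection$retained_variables,
           frequency = report$selection$frequency)
    },
    similarity_group_stats = if (!is.null(report$similarity)) {
      report$similarity$group_stats
    },
    similarity_anova = if (!is.null(report$similarity)) report$similarity$anova,
    a414_groups = if (!is.null(report$a414)) report$a414$groups,
    provenance = report$provenance)
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run report\n")
  print(x$table2)
  if (!is.null(x$selection)) print(x$selection)
  invisible(x)
}
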