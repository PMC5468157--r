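#' Default pipeline configuration
#'
#' One flat list drives the whole analysis. Defaults are the study
#' conditions the pipeline is designed around: a survey-scale occurrence
#' set (273 signs), 10,000 target-group background points, 15 replicated
#' 75/25 subsamples, |r| > 0.8 correlation screening with a 1% permutation
#' importance refit cutoff, a shared max-SSS threshold, 8-neighbor patches
#' filtered at 4 km^2 / 0.5 km, and a 19-reserve network.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param ... named overrides of any default.
#' @return named list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    # synthetic landscape
    n_rows = 100, n_cols = 100, cell_size_km = 1, n_climate_layers = 6,
    autocorrelation_range_cells = 9, temperature_delta = 1.5,
    precipitation_scale = 0.9, forest_fraction = 0.6,
    n_occurrences = 273, n_reserves = 19,
    # optional: read fixtures from disk instead of generating
    input_dir = NULL,
    # prep
    n_background = 10000,
    # screening
    correlation_cutoff = 0.8, importance_cutoff_pct = 1.0,
    # model
    n_rep = 15, train_frac = 0.75, hinge_knots = 5, beta_multiplier = 1,
    max_iter = 5000, tol = 1e-7,
    # habitat mapping
    threshold_mode = "shared",   # or "per-scenario"
    connectivity = 8, min_area_km2 = 4, max_gap_km = 0.5,
    seed = as.integer(seed))
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Returns every detectable problem (range violations, missing input
#' files) without side effects; an empty character vector means the config
#' is runnable.
#'
#' @param config a [default_config()] list.
#' @return character vector of problem descriptions.
#' @export
validate_config <- function(config) {
  p <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) p <<- c(p, msg)
  chk(config$train_frac > 0 && config$train_frac < 1,
      sprintf("train_frac = %s outside (0, 1)", config$train_frac))
  chk(config$correlation_cutoff > 0 && config$correlation_cutoff <= 1,
      "correlation_cutoff outside (0, 1]")
  chk(config$importance_cutoff_pct >= 0, "importance_cutoff_pct negative")
  chk(config$n_rep >= 1, "n_rep must be >= 1")
  chk(config$connectivity %in% c(4, 8), "connectivity must be 4 or 8")
  chk(config$min_area_km2 >= 0, "min_area_km2 negative")
  chk(config$max_gap_km >= 0, "max_gap_km negative")
  chk(config$threshold_mode %in% c("shared", "per-scenario"),
      "threshold_mode must be 'shared' or 'per-scenario'")
  chk(config$n_background >= 1, "n_background must be >= 1")
  chk(config$n_rows >= 1 && config$n_cols >= 1, "grid dimensions must be positive")
  chk(config$forest_fraction > 0 && config$forest_fraction <= 1,
      "forest_fraction outside (0, 1]")
  if (!is.null(config$input_dir)) {
    need <- c("forest.asc", "occurrences.csv", "reserves.geojson",
              file.path("current", "elevation.asc"),
              file.path("future", "elevation.asc"))
    for (f in need) {
      if (!file.exists(file.path(config$input_dir, f))) {
        p <- c(p, sprintf("missing input file: %s",
                          file.path(config$input_dir, f)))
      }
    }
  }
  p
}

read_layer_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  layers <- lapply(files, read_asc)
  habstack(layers)
}

load_pipeline_inputs <- function(config) {
  if (is.null(config$input_dir)) {
    spec <- scenario_spec(
      n_rows = config$n_rows, n_cols = config$n_cols,
      cell_size_km = config$cell_size_km,
      n_climate_layers = config$n_climate_layers,
      autocorrelation_range_cells = config$autocorrelation_range_cells,
      temperature_delta = config$temperature_delta,
      precipitation_scale = config$precipitation_scale,
      forest_fraction = config$forest_fraction, seed = config$seed)
    land <- make_landscape(spec)
    truth <- truth_spec()
    suit_true <- true_suitability(land$current, truth)
    occ <- sample_occurrences(suit_true, land$forest, config$n_occurrences,
                              seed = config$seed + 1L)
    reserves <- make_reserves(land$geometry, config$n_reserves,
                              seed = config$seed + 2L)
    list(current = land$current, future = land$future, forest = land$forest,
         geometry = land$geometry, occurrences = occ, reserves = reserves,
         true_suitability = suit_true)
  } else {
    d <- config$input_dir
    current <- read_layer_dir(file.path(d, "current"))
    future <- read_layer_dir(file.path(d, "future"))
    forest <- read_asc(file.path(d, "forest.asc"))
    list(current = current, future = future, forest = forest,
         geometry = grid_geometry(forest),
         occurrences = read_points_csv(file.path(d, "occurrences.csv")),
         reserves = read_reserves_geojson(file.path(d, "reserves.geojson")),
         true_suitability = if (file.exists(file.path(d, "true_suitability.asc")))
           read_asc(file.path(d, "true_suitability.asc")) else NULL)
  }
}

#' Run the full vulnerability-assessment pipeline
#'
#' Stages, in order: inputs (synthetic landscape or fixture directory);
#' occurrence thinning and target-group background sampling; correlation
#' screening at the model points followed by a first fit, permutation
#' importance and an importance-cutoff refit; replicated subsample model
#' fitting with mean suitability and mean max-SSS threshold; binary habitat
#' mapping and patch filtering per scenario; four-category change
#' classification with the vulnerability indicators and an elevation
#' contrast; and reserve gap analysis. Identical config (including seed)
#' gives identical output.
#'
#' @param config a [default_config()] list.
#' @param out_dir optional directory; when given, every intermediate
#'   artifact (grids, point sets, tables) plus a JSON and a Markdown report
#'   are written there.
#' @return list of class `pipeline_report` with all stage outputs and a
#'   `summary` list of headline numbers.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  problems <- validate_config(config)
  if (length(problems)) {
    stop(paste(c("invalid pipeline config:", problems), collapse = "\n  "),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  inp <- stage("inputs", load_pipeline_inputs(config))
  geom <- inp$geometry

  thinned <- stage("thin", thin_one_per_cell(inp$occurrences, geom,
                                             seed = config$seed + 10L))
  bg <- stage("background",
              sample_background(inp$forest, config$n_background,
                                seed = config$seed + 11L))

  # screening stage 1: correlation at presence + background points
  candidates <- names(inp$current$layers)
  scr <- stage("screen", {
    cm <- pairwise_correlation(inp$current, rbind(thinned[, c("x", "y")],
                                                  bg[, c("x", "y")]))
    eliminate_correlated(cm, cutoff = config$correlation_cutoff)
  })

  # screening stage 2: first model on the screened set, then importance
  first <- stage("first_model", {
    st <- habstack(inp$current$layers[scr$retained])
    pres_raw <- extract_at(st, thinned)
    bg_raw <- extract_at(st, bg)
    pres_raw <- pres_raw[stats::complete.cases(pres_raw), , drop = FALSE]
    bg_raw <- bg_raw[stats::complete.cases(bg_raw), , drop = FALSE]
    fx <- build_features(bg_raw, config$hinge_knots)
    mod <- maxent_fit(expand_features(fx, pres_raw),
                      expand_features(fx, bg_raw),
                      beta_multiplier = config$beta_multiplier,
                      max_iter = config$max_iter, tol = config$tol,
                      expansion = fx)
    imp <- permutation_importance(mod, pres_raw, bg_raw,
                                  seed = config$seed + 12L)
    list(model = mod, importance = imp)
  })
  final_vars <- stage("refit_selection",
                      refit_top_variables(first$importance,
                                          config$importance_cutoff_pct))

  ens <- stage("replicates",
               run_replicates(thinned, bg, inp$current,
                              variables = final_vars, n_rep = config$n_rep,
                              train_frac = config$train_frac,
                              seed = config$seed + 13L,
                              hinge_knots = config$hinge_knots,
                              beta_multiplier = config$beta_multiplier,
                              max_iter = config$max_iter, tol = config$tol,
                              predict_on = inp$future))

  thr_cur <- ens$mean_threshold
  habitat <- stage("habitat_maps", {
    map_cur <- binarize(ens$mean_suitability, thr_cur, "current")
    thr_fut <- if (config$threshold_mode == "shared") thr_cur else {
      # per-scenario: max-SSS on the ensemble-mean future scores of the
      # model points (presences kept at their current locations)
      fut_st <- habstack(inp$future$layers[final_vars])
      p_raw <- extract_at(fut_st, thinned)
      b_raw <- extract_at(fut_st, bg)
      p_raw <- p_raw[stats::complete.cases(p_raw), , drop = FALSE]
      b_raw <- b_raw[stats::complete.cases(b_raw), , drop = FALSE]
      score_mean <- function(raw) {
        fm <- expand_features(ens$models[[1]]$expansion, raw)
        rowMeans(vapply(ens$models, maxent_logistic_scores,
                        numeric(nrow(fm)), features = fm))
      }
      threshold_max_sss(score_mean(p_raw), score_mean(b_raw))$threshold
    }
    map_fut <- binarize(ens$mean_suitability_alt, thr_fut, "future")
    pc <- label_patches(map_cur, config$connectivity)
    pf <- label_patches(map_fut, config$connectivity)
    list(current = filter_patches(pc, config$min_area_km2, config$max_gap_km),
         future = filter_patches(pf, config$min_area_km2, config$max_gap_km),
         raw_current = map_cur, raw_future = map_fut)
  })

  change <- stage("change", classify_change(habitat$current, habitat$future))
  ind <- stage("indicators", indicators(change))
  elev <- stage("elevation_contrast",
                elevation_contrast(habitat$current, habitat$future,
                                   inp$current$layers$elevation))

  gap <- stage("gap", {
    labels <- rasterize_reserves(inp$reserves, geom)
    reserve_report(labels, habitat$current, habitat$future)
  })

  summary <- list(
    n_occurrences_in = nrow(inp$occurrences),
    n_presences_thinned = nrow(thinned),
    n_dropped_outside = attr(thinned, "n_dropped_outside"),
    n_background = nrow(bg),
    variables_screened = scr$retained,
    variables_final = final_vars,
    auc = as.list(ens$auc_summary),
    mean_threshold = ens$mean_threshold,
    area_current_km2 = ind$A_c, area_future_km2 = ind$A_f,
    area_overlap_km2 = ind$A_fc,
    AC_pct = ind$AC, SH_c_pct = ind$SH_c, SH_f_pct = ind$SH_f,
    mean_elev_current = elev$mean_x, mean_elev_future = elev$mean_y,
    elevation_z = elev$z, elevation_p = elev$p,
    protected_current_pct = unname(gap$network["protected_current_pct"]),
    protected_future_pct = unname(gap$network["protected_future_pct"]),
    seed = config$seed)

  report <- structure(list(
    config = config, screen = scr, importance_first = first$importance,
    ensemble = ens, habitat = habitat, change = change, indicators = ind,
    elevation = elev, gap = gap, summary = summary,
    true_suitability = inp$true_suitability), class = "pipeline_report")

  if (!is.null(out_dir)) write_pipeline_artifacts(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_report>\n")
  cat(sprintf("  presences %d (thinned from %d), background %d\n",
              s$n_presences_thinned, s$n_occurrences_in, s$n_background))
  cat(sprintf("  variables: %s\n", paste(s$variables_final, collapse = ", ")))
  cat(sprintf("  AUC test %.3f +/- %.3f, mean threshold %.4f\n",
              s$auc$test_mean, s$auc$test_sd, s$mean_threshold))
  cat(sprintf("  habitat %.0f -> %.0f km2 (AC %.2f%%, SH_c %.2f%%, SH_f %.2f%%)\n",
              s$area_current_km2, s$area_future_km2, s$AC_pct, s$SH_c_pct,
              s$SH_f_pct))
  cat(sprintf("  mean elevation %.1f -> %.1f m (z = %.3f, p = %.3g)\n",
              s$mean_elev_current, s$mean_elev_future, s$elevation_z,
              s$elevation_p))
  cat(sprintf("  protection %.2f%% current, %.2f%% future\n",
              s$protected_current_pct, s$protected_future_pct))
  invisible(x)
}

write_pipeline_artifacts <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(g, f) write_asc(g, file.path(out_dir, f))
  w(report$ensemble$mean_suitability, "suitability_current.asc")
  if (!is.null(report$ensemble$mean_suitability_alt)) {
    w(report$ensemble$mean_suitability_alt, "suitability_future.asc")
  }
  hab_grid <- function(h, nm) {
    habgrid(ifelse(h$valid, h$suitable * 1, NA_real_), h$cell_size_km,
            h$origin_xy, nm)
  }
  w(hab_grid(report$habitat$current, "habitat_current"), "habitat_current.asc")
  w(hab_grid(report$habitat$future, "habitat_future"), "habitat_future.asc")
  write_change_asc(report$change, file.path(out_dir, "change.asc"))
  utils::write.csv(report$gap$table, file.path(out_dir, "reserve_table.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$ensemble$evaluation,
                   file.path(out_dir, "replicates.csv"), row.names = FALSE,
                   quote = FALSE)
  cfg <- report$config
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                               null = "null")
  s <- report$summary
  s$config_sha <- config_hash(cfg_json)
  jsonlite::write_json(s, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  md <- c(
    "# Habitat vulnerability report", "",
    sprintf("- config hash: `%s`", s$config_sha),
    sprintf("- presences: %d thinned of %d; background: %d",
            s$n_presences_thinned, s$n_occurrences_in, s$n_background),
    sprintf("- final variables: %s", paste(s$variables_final, collapse = ", ")),
    sprintf("- AUC: train %.3f +/- %.3f, test %.3f +/- %.3f",
            s$auc$train_mean, s$auc$train_sd, s$auc$test_mean, s$auc$test_sd),
    sprintf("- mean max-SSS threshold: %.4f", s$mean_threshold),
    sprintf("- suitable habitat: current %.2f km2, future %.2f km2, overlap %.2f km2",
            s$area_current_km2, s$area_future_km2, s$area_overlap_km2),
    sprintf("- indicators: AC %.2f%%, SH_c %.2f%%, SH_f %.2f%%",
            s$AC_pct, s$SH_c_pct, s$SH_f_pct),
    sprintf("- mean elevation: current %.2f m, future %.2f m (z = %.3f, p = %.3g)",
            s$mean_elev_current, s$mean_elev_future, s$elevation_z,
            s$elevation_p),
    sprintf("- network protection: %.2f%% current, %.2f%% future",
            s$protected_current_pct, s$protected_future_pct))
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

# stable short hash of the config JSON (djb2 over bytes, hex)
config_hash <- function(txt) {
  bytes <- as.integer(charToRaw(as.character(txt)))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}
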