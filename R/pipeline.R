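# End-to-end pipeline driver and report rendering -----------------------------

#' Pipeline configuration
#'
#' Bundles every setting the end-to-end analysis needs, with all seeds
#' explicit so runs are reproducible.
#'
#' @param input Path to a trial CSV, or a [trial_dataset()] already in
#'   memory.
#' @param schema_map Schema map for CSV input (see [default_schema_map()]).
#' @param geometry `NULL` or per-direction reference-ball offsets.
#' @param outlier_k Tukey fence multiplier.
#' @param exclusion_fraction Per-task flagged fraction above which a
#'   participant is excluded.
#' @param n_boot Bootstrap replicates for LMM contrasts.
#' @param random Random-effects structure passed to [fit_gain_lmm()];
#'   the default zero-correlation form keeps all variance components while
#'   making the parametric bootstrap tractable.
#' @param seed Integer seed used for every stochastic stage.
#' @param out_dir Directory for stage outputs, or `NULL` to keep results in
#'   memory only.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, schema_map = default_schema_map(),
                            geometry = NULL, outlier_k = 1.5,
                            exclusion_fraction = 1 / 4, n_boot = 500,
                            random = "zero_corr",
                            seed = 1L, out_dir = NULL) {
  if (is.character(input) && !file.exists(input)) {
    stop("input file not found: ", input, call. = FALSE)
  }
  structure(list(input = input, schema_map = schema_map, geometry = geometry,
                 outlier_k = outlier_k,
                 exclusion_fraction = exclusion_fraction,
                 n_boot = n_boot, random = random, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes read -> gains -> outlier flagging -> participant exclusion ->
#' per-task linear mixed models with pairwise direction and speed
#' contrasts -> per-condition LSI fits with the nested no-leak comparison.
#' Returns a manifest of per-stage counts alongside every stage's result;
#' when `out_dir` is set, intermediates are written as CSV/JSON so stages
#' can be inspected and re-run independently.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `manifest`, `dataset`
#'   (preprocessed), `preprocess_report`, `lmm` (per task: fit + contrast
#'   tables), `lsi` (goodness-of-fit tables and fits), `mean_gains`
#'   (per-direction and per-speed raw-gain summaries per task).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dataset <- if (inherits(config$input, "trial_dataset")) config$input
    else read_trials(config$input, config$schema_map)
  n_in <- nrow(dataset$trials)

  pre <- preprocess(dataset, geometry = config$geometry,
                    k = config$outlier_k,
                    fraction = config$exclusion_fraction)
  ds <- pre$dataset

  mean_gains <- list(
    by_direction = gain_summary(ds, "direction"),
    by_speed = gain_summary(ds, "speed"))

  lmm <- list()
  for (task in TASKS) {
    fit <- fit_gain_lmm(ds, task, random = config$random)
    draws <- bootstrap_fixef(fit, n_boot = config$n_boot,
                             seed = config$seed + match(task, TASKS))
    lmm[[task]] <- list(
      fit = fit,
      direction_contrasts = all_pairwise_contrasts(fit, "direction",
                                                   draws = draws),
      speed_contrasts = all_pairwise_contrasts(fit, "speed", draws = draws))
  }

  lsi <- goodness_of_fit_by_condition(ds)

  manifest <- list(
    provenance = dataset$provenance,
    seed = config$seed,
    n_trials_in = n_in,
    n_trials_flagged = sum(ds$trials$flagged_outlier),
    n_participants_in = dplyr::n_distinct(dataset$trials$participant_id),
    n_participants_excluded = nrow(ds$exclusion_log),
    excluded_participants = ds$exclusion_log$participant_id,
    n_trials_analysed = sum(!ds$trials$flagged_outlier),
    n_boot = config$n_boot,
    random = config$random,
    outlier_k = config$outlier_k,
    exclusion_fraction = config$exclusion_fraction,
    geometry = config$geometry)

  result <- structure(
    list(manifest = manifest, dataset = ds,
         preprocess_report = pre$report, lmm = lmm, lsi = lsi,
         mean_gains = mean_gains),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config)
  result
}

gain_summary <- function(dataset, by) {
  dataset$trials |>
    dplyr::filter(!.data$flagged_outlier) |>
    dplyr::group_by(.data$task, .data[[by]]) |>
    dplyr::summarise(mean_gain = mean(.data$gain),
                     sd_gain = stats::sd(.data$gain),
                     n = dplyr::n(), .groups = "drop")
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out_dir, ...)
  write_trials(result$dataset, p("trials_preprocessed.csv"))
  utils::write.csv(result$lsi$by_cell, p("lsi_fits_by_cell.csv"),
                   row.names = FALSE)
  utils::write.csv(result$lsi$by_direction, p("lsi_mse_by_direction.csv"),
                   row.names = FALSE)
  utils::write.csv(result$mean_gains$by_direction,
                   p("mean_gains_by_direction.csv"), row.names = FALSE)
  utils::write.csv(result$mean_gains$by_speed,
                   p("mean_gains_by_speed.csv"), row.names = FALSE)
  for (task in names(result$lmm)) {
    utils::write.csv(result$lmm[[task]]$direction_contrasts,
                     p(paste0("contrasts_direction_", task, ".csv")),
                     row.names = FALSE)
    utils::write.csv(result$lmm[[task]]$speed_contrasts,
                     p(paste0("contrasts_speed_", task, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(config$out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("<pipeline_result>\n",
      "  trials in: ", m$n_trials_in,
      "; flagged: ", m$n_trials_flagged,
      "; analysed: ", m$n_trials_analysed, "\n",
      "  participants excluded: ", m$n_participants_excluded, "\n",
      sep = "")
  invisible(x)
}

# Report figures ---------------------------------------------------------------

#' Render report figures and tables from a pipeline result
#'
#' Produces analogues of the study's figures: box plots of gains by
#' direction and by speed for each task, per-condition data-versus-model
#' curves with +/- 1 SD bands in a direction x speed panel grid, and a bar
#' summary of per-direction model MSE — plus the contrast tables in the
#' estimate / SE / CI / significance layout.
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @return A list: `figures` (named ggplot objects: `gains_by_direction`,
#'   `gains_by_speed`, `lsi_curves`, `mse_by_direction`) and `tables`
#'   (named contrast tibbles).
#' @export
render_report <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  tr <- dplyr::filter(result$dataset$trials, !.data$flagged_outlier)
  tr$direction <- factor(tr$direction, levels = DIRECTIONS)

  gains_by_direction <- ggplot2::ggplot(
    tr, ggplot2::aes(x = .data$direction, y = .data$gain,
                     fill = .data$direction)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~task) +
    ggplot2::labs(x = "direction", y = "gain")

  gains_by_speed <- ggplot2::ggplot(
    tr, ggplot2::aes(x = factor(.data$speed), y = .data$gain,
                     fill = factor(.data$speed))) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~task) +
    ggplot2::labs(x = "speed (m/s)", y = "gain")

  means <- condition_means(result$dataset)
  curve_grid <- purrr::map_dfr(result$lsi$fits, function(fit) {
    grid <- seq(min(DISTANCES), max(DISTANCES), length.out = 60)
    tibble::tibble(
      direction = fit$condition$direction, speed = fit$condition$speed,
      d0 = rep(grid, 2),
      task = rep(c("adjust_target", "move_to_target"), each = length(grid)),
      pred = c(predict_adjust_target(fit$params, grid),
               predict_move_to_target(fit$params, grid)))
  })
  lsi_curves <- ggplot2::ggplot(
    means, ggplot2::aes(x = .data$d0, colour = .data$task)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$y - .data$sd,
                                      ymax = .data$y + .data$sd,
                                      fill = .data$task),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y), size = 0.8) +
    ggplot2::geom_line(data = curve_grid, ggplot2::aes(y = .data$pred)) +
    ggplot2::facet_grid(speed ~ factor(direction, levels = DIRECTIONS)) +
    ggplot2::labs(x = "target distance (m)", y = "response distance (m)")

  mse_by_direction <- ggplot2::ggplot(
    result$lsi$by_direction,
    ggplot2::aes(x = factor(.data$direction, levels = DIRECTIONS),
                 y = .data$mse, fill = .data$direction)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "direction", y = "model MSE (m^2)")

  tables <- list()
  for (task in names(result$lmm)) {
    tables[[paste0(task, "_direction")]] <-
      contrast_table(result$lmm[[task]]$direction_contrasts)
    tables[[paste0(task, "_speed")]] <-
      contrast_table(result$lmm[[task]]$speed_contrasts)
  }
  list(figures = list(gains_by_direction = gains_by_direction,
                      gains_by_speed = gains_by_speed,
                      lsi_curves = lsi_curves,
                      mse_by_direction = mse_by_direction),
       tables = tables)
}

contrast_table <- function(contrasts) {
  dplyr::transmute(
    contrasts,
    comparison = paste(.data$level_a, "vs.", .data$level_b),
    estimate = .data$estimate, std_error = .data$std_error,
    ci_low = .data$ci_low, ci_high = .data$ci_high,
    significant = ifelse(.data$significant, "*", "n.s."))
}
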