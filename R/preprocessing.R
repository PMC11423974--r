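# Gains, reference-ball correction, Tukey fences, participant exclusion ------

#' Reference-ball geometry offsets
#'
#' In the experiment a reference ball fixed relative to the observer (centre
#' 1.5 m ahead, 0.25 m below eye height, radius 0.25 m) marked when a
#' surface touched the remembered target: the far side for forward motion,
#' the near side for backward, the top for upward and the bottom for
#' downward. The leading surface therefore sits at a direction-specific
#' displacement from the observer along the motion axis; these offsets let
#' the stopping-point variation be taken into account when computing gains.
#'
#' The returned offsets are the leading-surface displacements (m):
#' forward `ball_distance + radius`, backward `-(ball_distance - radius)`,
#' up `radius - ball_drop`, down `ball_drop + radius`. How the correction is
#' applied is described in [compute_gains()]; supplying `NULL` there (the
#' default) disables it entirely.
#'
#' @param ball_distance Distance of the ball centre ahead of the observer, m.
#' @param ball_radius Ball radius, m.
#' @param ball_drop Drop of the ball centre below eye height, m.
#' @return Named numeric vector of per-direction offsets (m).
#' @export
reference_ball_offsets <- function(ball_distance = 1.5, ball_radius = 0.25,
                                   ball_drop = 0.25) {
  c(forward = ball_distance + ball_radius,
    backward = -(ball_distance - ball_radius),
    up = ball_radius - ball_drop,
    down = ball_drop + ball_radius)
}

#' Compute per-trial gains
#'
#' Gain is perceived travel distance divided by actual travel distance. For
#' the move-to-target task the perceived distance is the target distance and
#' the actual distance is the self-motion distance at the stop response:
#' `gain = target_distance / response_distance`. For the adjust-target task
#' the observer is displaced by `target_distance` and sets the target at the
#' felt distance: `gain = response_distance / target_distance`. A gain of 1
#' is veridical; above 1 the observer felt they moved further than they did.
#'
#' When `geometry` offsets are supplied, the move-to-target self-motion
#' distance is corrected for the reference-ball surface used to judge
#' arrival: the effective travelled distance of the judging surface is
#' `response_distance + offset[direction]`, and the gain divides by that.
#' Offsets of zero (or `geometry = NULL`) disable the correction. Trials
#' whose corrected distance is non-positive are flagged invalid (gain `NA`,
#' `flagged_outlier = TRUE`) rather than silently kept.
#'
#' @param dataset A [trial_dataset()] with responses.
#' @param geometry `NULL` (no correction) or a named per-direction offset
#'   vector such as [reference_ball_offsets()].
#' @return The dataset with the `gain` column filled.
#' @export
compute_gains <- function(dataset, geometry = NULL) {
  stopifnot(inherits(dataset, "trial_dataset"))
  tr <- dataset$trials
  offset <- rep(0, nrow(tr))
  if (!is.null(geometry)) {
    if (!all(DIRECTIONS %in% names(geometry))) {
      stop("geometry must name an offset for every direction", call. = FALSE)
    }
    is_mtt <- tr$task == "move_to_target"
    offset[is_mtt] <- geometry[tr$direction[is_mtt]]
  }
  corrected <- tr$response_distance + offset
  invalid <- corrected <= 0
  gain <- ifelse(tr$task == "move_to_target",
                 tr$target_distance / corrected,
                 corrected / tr$target_distance)
  gain[invalid] <- NA_real_
  tr$gain <- gain
  tr$flagged_outlier <- tr$flagged_outlier | invalid
  if (any(invalid)) {
    warning(sum(invalid), " trial(s) had non-positive corrected distance ",
            "and were flagged invalid")
  }
  dataset$trials <- tr
  dataset
}

#' Group-level Tukey-fence outlier removal
#'
#' Within each task x direction x speed x distance cell, pooling across
#' participants, computes the quartiles of the gains (linear interpolation
#' between order statistics, the default "type 7" convention) and flags
#' trials outside \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\]. Flagged trials are kept in
#' the dataset with `flagged_outlier = TRUE` so reports stay auditable, but
#' all downstream stages ignore them. Cells with fewer than 4 observations
#' have undefined fences and pass through unflagged with a warning entry in
#' the report.
#'
#' @param dataset A [trial_dataset()] with gains computed.
#' @param k Fence multiplier on the IQR (1.5).
#' @param quantile_type Quantile convention passed to [stats::quantile()]
#'   (recorded in the report).
#' @return A list: `dataset` (with flags), and `report` containing
#'   `by_cell` (fences and flag counts per cell), `by_participant` (flag
#'   counts per participant and task), `warnings` (small cells), and the
#'   quantile convention used.
#' @export
remove_outliers <- function(dataset, k = 1.5, quantile_type = 7) {
  stopifnot(inherits(dataset, "trial_dataset"))
  tr <- dataset$trials
  if (all(is.na(tr$gain))) stop("compute gains first", call. = FALSE)
  usable <- !tr$flagged_outlier & !is.na(tr$gain)

  cell_id <- paste(tr$task, tr$direction, tr$speed, tr$target_distance,
                   sep = "\r")
  flags <- rep(FALSE, nrow(tr))
  cell_rows <- split(which(usable), cell_id[usable])
  small_cells <- character(0)
  by_cell <- purrr::map_dfr(names(cell_rows), function(id) {
    rows <- cell_rows[[id]]
    parts <- strsplit(id, "\r", fixed = TRUE)[[1]]
    g <- tr$gain[rows]
    if (length(g) < 4) {
      small_cells <<- c(small_cells, gsub("\r", "/", id))
      return(tibble::tibble(
        task = parts[1], direction = parts[2],
        speed = as.numeric(parts[3]), target_distance = as.numeric(parts[4]),
        n = length(g), q1 = NA_real_, q3 = NA_real_,
        lower = NA_real_, upper = NA_real_, n_flagged = 0L))
    }
    q <- stats::quantile(g, c(0.25, 0.75), type = quantile_type,
                         names = FALSE)
    iqr <- q[2] - q[1]
    lower <- q[1] - k * iqr
    upper <- q[2] + k * iqr
    out <- g < lower | g > upper
    flags[rows[out]] <<- TRUE
    tibble::tibble(
      task = parts[1], direction = parts[2],
      speed = as.numeric(parts[3]), target_distance = as.numeric(parts[4]),
      n = length(g), q1 = q[1], q3 = q[2], lower = lower, upper = upper,
      n_flagged = sum(out))
  })
  if (length(small_cells) > 0) {
    warning(length(small_cells),
            " cell(s) had < 4 observations; fences undefined, left unflagged")
  }
  tr$flagged_outlier <- tr$flagged_outlier | flags
  dataset$trials <- tr
  by_participant <- tr |>
    dplyr::group_by(.data$participant_id, .data$task) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     n_flagged = sum(.data$flagged_outlier),
                     .groups = "drop")
  list(dataset = dataset,
       report = list(by_cell = by_cell, by_participant = by_participant,
                     warnings = small_cells, k = k,
                     quantile_type = quantile_type))
}

#' Exclude participants with too many removed trials
#'
#' A participant is removed entirely when more than `fraction` of their
#' trials in a single task are flagged (strictly more: with 144 trials per
#' task and the default quarter threshold, 36 flagged trials is retained and
#' 37 is excluded). Removals are appended to the dataset's exclusion log.
#'
#' @param dataset A [trial_dataset()] with outlier flags.
#' @param fraction Per-task flagged-trial fraction above which a participant
#'   is excluded (default 1/4).
#' @return The dataset with excluded participants' trials dropped and the
#'   exclusion log extended.
#' @export
exclude_participants <- function(dataset, fraction = 1 / 4) {
  stopifnot(inherits(dataset, "trial_dataset"))
  per <- dataset$trials |>
    dplyr::group_by(.data$participant_id, .data$task) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     n_flagged = sum(.data$flagged_outlier),
                     .groups = "drop") |>
    dplyr::filter(.data$n_flagged > fraction * .data$n_trials)
  excluded <- unique(per$participant_id)
  if (length(excluded) > 0) {
    log_add <- per |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(n_trials_removed = as.integer(sum(.data$n_flagged)),
                       .groups = "drop") |>
      dplyr::mutate(reason = sprintf(
        "more than %.3g of trials flagged in at least one task", fraction)) |>
      dplyr::select("participant_id", "reason", "n_trials_removed")
    dataset$exclusion_log <- dplyr::bind_rows(dataset$exclusion_log, log_add)
    dataset$trials <- dplyr::filter(
      dataset$trials, !.data$participant_id %in% excluded)
  }
  dataset
}

#' Run the full preprocessing chain
#'
#' Gains, optional reference-ball correction, group-level Tukey-fence
#' outlier flagging, and participant exclusion, in the order the analysis
#' prescribes.
#'
#' @inheritParams compute_gains
#' @inheritParams remove_outliers
#' @inheritParams exclude_participants
#' @return A list: `dataset` (preprocessed), `report` (outlier report plus
#'   the exclusion log).
#' @export
preprocess <- function(dataset, geometry = NULL, k = 1.5, fraction = 1 / 4) {
  ds <- compute_gains(dataset, geometry = geometry)
  out <- remove_outliers(ds, k = k)
  ds <- exclude_participants(out$dataset, fraction = fraction)
  list(dataset = ds,
       report = c(out$report, list(exclusion_log = ds$exclusion_log)))
}
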