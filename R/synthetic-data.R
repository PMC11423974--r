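# Full-factorial synthetic cohorts with known LSI ground truth ---------------

#' Ground truth for synthetic cohorts
#'
#' Collects the generative parameters of a synthetic cohort: the true LSI
#' (gain, alpha) per direction x speed condition, participant-level
#' heterogeneity, trial-level noise, and optional outlier contamination.
#' Both tasks in a condition are generated from the same (gain, alpha) pair,
#' as the integrator model implies.
#'
#' @param gain_by_condition Data frame with columns `direction`, `speed`,
#'   `gain` (one row per direction x speed cell; missing cells error).
#' @param alpha_by_condition Data frame with columns `direction`, `speed`,
#'   `alpha` (leak per metre, >= 0), or a single number recycled to all
#'   cells.
#' @param participant_gain_sd SD (log scale) of the lognormal participant
#'   multipliers applied to gain, drawn independently per participant for
#'   each direction and for each speed (inducing random-slope structure).
#' @param noise_sd Trial-level multiplicative response noise SD (log scale).
#' @param contamination_rate Fraction of trials multiplied by
#'   `outlier_factor`.
#' @param outlier_factor Multiplicative magnitude of contaminated responses.
#' @param n_participants Number of simulated participants.
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(gain_by_condition,
                            alpha_by_condition = 0.03,
                            participant_gain_sd = 0.1,
                            noise_sd = 0.2,
                            contamination_rate = 0,
                            outlier_factor = 3,
                            n_participants = 16) {
  grid <- tidyr::expand_grid(direction = DIRECTIONS, speed = SPEEDS)
  if (is.numeric(alpha_by_condition) && length(alpha_by_condition) == 1) {
    alpha_by_condition <- dplyr::mutate(grid, alpha = alpha_by_condition)
  }
  gains <- dplyr::left_join(grid, gain_by_condition,
                            by = c("direction", "speed"))
  alphas <- dplyr::left_join(grid, alpha_by_condition,
                             by = c("direction", "speed"))
  if (any(is.na(gains$gain)) || any(is.na(alphas$alpha))) {
    stop("gain/alpha must be supplied for every direction x speed cell",
         call. = FALSE)
  }
  if (any(gains$gain <= 0)) stop("all true gains must be > 0", call. = FALSE)
  if (any(alphas$alpha < 0)) stop("all alphas must be >= 0", call. = FALSE)
  if (contamination_rate < 0 || contamination_rate >= 1) {
    stop("contamination_rate must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(participant_gain_sd >= 0, noise_sd >= 0, n_participants >= 1)
  structure(list(
    gain_by_condition = gains, alpha_by_condition = alphas,
    participant_gain_sd = participant_gain_sd, noise_sd = noise_sd,
    contamination_rate = contamination_rate, outlier_factor = outlier_factor,
    n_participants = as.integer(n_participants)
  ), class = "synthetic_truth")
}

#' Default generative truth emulating the study conditions
#'
#' A 16-participant cohort whose true gains lie in the 1.3–2.5 range
#' reported for the group means, with slower speeds assigned slightly
#' higher gains, a common leak of 0.03 per metre, lognormal participant
#' heterogeneity (SD 0.1) and trial noise (SD 0.2).
#'
#' @param ... Overrides passed on to [synthetic_truth()].
#' @return A `synthetic_truth`.
#' @export
default_truth <- function(...) {
  base <- c(forward = 2.1, backward = 1.4, up = 1.95, down = 1.9)
  speed_mult <- c("1" = 1.12, "3" = 0.97, "5" = 0.95)
  gains <- tidyr::expand_grid(direction = DIRECTIONS, speed = SPEEDS) |>
    dplyr::mutate(gain = base[.data$direction] *
                    speed_mult[as.character(.data$speed)])
  args <- list(...)
  args$gain_by_condition <- args$gain_by_condition %||% gains
  do.call(synthetic_truth, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate the full-factorial trial schedule
#'
#' Builds the design skeleton for `n_participants` participants: 288 trials
#' each, covering the 4 direction x 3 speed x 12 distance x 2 task factorial
#' exactly once. Trials are blocked by task x direction (as in the
#' experiment, where tasks were blocked by direction); block order and the
#' trial order within each block are randomized per participant.
#'
#' @param n_participants Number of participants (>= 1).
#' @param seed Integer seed controlling the block/trial shuffles.
#' @return A [trial_dataset()] with `response_distance` absent (`NA`).
#' @export
generate_schedule <- function(n_participants, seed = 1L) {
  stopifnot(n_participants >= 1)
  withr_seed(seed)
  block_design <- tidyr::expand_grid(speed = SPEEDS,
                                     target_distance = DISTANCES)
  blocks <- tidyr::expand_grid(task = TASKS, direction = DIRECTIONS)
  per_participant <- function(pid) {
    order_idx <- sample.int(nrow(blocks))
    purrr::map_dfr(order_idx, function(b) {
      trials <- block_design[sample.int(nrow(block_design)), ]
      dplyr::mutate(trials, task = blocks$task[b],
                    direction = blocks$direction[b], .before = 1)
    }) |>
      dplyr::mutate(participant_id = pid, .before = 1)
  }
  ids <- sprintf("P%02d", seq_len(n_participants))
  trials <- purrr::map_dfr(ids, per_participant)
  trial_dataset(trials, provenance = sprintf("schedule(n=%d, seed=%d)",
                                             n_participants, seed),
                allow_missing_response = TRUE)
}

# Seed handling: isolate the generator from the caller's RNG state.
withr_seed <- function(seed, env = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = env)
}

#' Simulate responses for a schedule under known ground truth
#'
#' Generates responses by inverting the LSI closed forms with multiplicative
#' lognormal noise. For each participant, a lognormal gain multiplier is
#' drawn once per direction and once per speed (independently), so a
#' participant's effective gain in a cell is
#' `g' = g * m_direction * m_speed`; the adjust-target response is
#' `predict_adjust_target((g', a), d0) * eps` and the move-to-target
#' response is `predict_move_to_target((g', a), d0) * eps`, with
#' `eps ~ lognormal(0, noise_sd)` per trial (median 1). With probability
#' `contamination_rate` a trial's response is additionally multiplied by
#' `outlier_factor`. All randomness derives from `seed`: the same seed
#' yields an identical dataset.
#'
#' @param schedule A [trial_dataset()] from [generate_schedule()] (responses
#'   absent).
#' @param truth A [synthetic_truth()].
#' @param seed Integer seed for all response-level randomness.
#' @return A [trial_dataset()] with simulated `response_distance`. The
#'   participant multipliers and contamination flags are attached as the
#'   `"generative"` attribute for recovery tests.
#' @export
simulate_responses <- function(schedule, truth, seed = 1L) {
  stopifnot(inherits(schedule, "trial_dataset"),
            inherits(truth, "synthetic_truth"))
  trials <- schedule$trials
  if (any(!is.na(trials$response_distance))) {
    stop("schedule already has responses", call. = FALSE)
  }
  withr_seed(seed)
  ids <- unique(trials$participant_id)
  mult_dir <- tidyr::expand_grid(participant_id = ids,
                                 direction = DIRECTIONS) |>
    dplyr::mutate(m_dir = stats::rlnorm(dplyr::n(), 0,
                                        truth$participant_gain_sd))
  mult_spd <- tidyr::expand_grid(participant_id = ids, speed = SPEEDS) |>
    dplyr::mutate(m_spd = stats::rlnorm(dplyr::n(), 0,
                                        truth$participant_gain_sd))
  sim <- trials |>
    dplyr::select(-"gain") |>
    dplyr::left_join(truth$gain_by_condition, by = c("direction", "speed")) |>
    dplyr::left_join(truth$alpha_by_condition, by = c("direction", "speed")) |>
    dplyr::left_join(mult_dir, by = c("participant_id", "direction")) |>
    dplyr::left_join(mult_spd, by = c("participant_id", "speed"))
  g_eff <- sim$gain * sim$m_dir * sim$m_spd
  a_eff <- pmax(sim$alpha, ALPHA_FLOOR)
  d0 <- sim$target_distance
  mean_resp <- ifelse(
    sim$task == "adjust_target",
    (g_eff / a_eff) * (1 - exp(-a_eff * d0)),
    log1p(a_eff * d0 / g_eff) / a_eff)
  eps <- stats::rlnorm(nrow(sim), 0, truth$noise_sd)
  contaminated <- stats::runif(nrow(sim)) < truth$contamination_rate
  response <- mean_resp * eps * ifelse(contaminated, truth$outlier_factor, 1)

  out <- trials
  out$response_distance <- response
  ds <- trial_dataset(out, provenance = paste0(schedule$provenance,
                                               " + responses(seed=", seed, ")"),
                      exclusion_log = schedule$exclusion_log)
  attr(ds, "generative") <- list(
    truth = truth,
    participant_direction_multipliers = mult_dir,
    participant_speed_multipliers = mult_spd,
    contaminated = contaminated)
  ds
}

#' Simulate a complete cohort in one call
#'
#' Convenience wrapper: [generate_schedule()] then [simulate_responses()].
#' The schedule shuffle and response noise use seeds derived from `seed`.
#'
#' @param truth A [synthetic_truth()]; defaults to [default_truth()].
#' @param seed Integer master seed.
#' @return A [trial_dataset()] with responses.
#' @export
simulate_cohort <- function(truth = default_truth(), seed = 1L) {
  seed <- as.integer(seed)
  schedule <- generate_schedule(truth$n_participants, seed = seed)
  simulate_responses(schedule, truth, seed = seed + 1L)
}
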