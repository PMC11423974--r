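# Shared fixtures, built in code at test time.

# A truth object with a single (gain, alpha) everywhere and no participant
# heterogeneity unless asked for.
uniform_truth <- function(gain = 2, alpha = 0.05, noise_sd = 0,
                          participant_gain_sd = 0, n_participants = 4, ...) {
  grid <- expand.grid(direction = design_levels()$directions,
                      speed = design_levels()$speeds,
                      stringsAsFactors = FALSE)
  grid$gain <- gain
  synthetic_truth(gain_by_condition = grid[, c("direction", "speed", "gain")],
                  alpha_by_condition = alpha,
                  noise_sd = noise_sd,
                  participant_gain_sd = participant_gain_sd,
                  n_participants = n_participants, ...)
}

# Truth with per-direction gains (no speed effect), for LMM planted-shift
# and null tests; alpha = 0 keeps trial gains equal to the effective gain.
direction_truth <- function(base = c(forward = 2, backward = 1.5,
                                     up = 1.75, down = 1.75),
                            noise_sd = 0.2, participant_gain_sd = 0.1,
                            n_participants = 16, ...) {
  grid <- expand.grid(direction = design_levels()$directions,
                      speed = design_levels()$speeds,
                      stringsAsFactors = FALSE)
  grid$gain <- unname(base[grid$direction])
  synthetic_truth(gain_by_condition = grid,
                  alpha_by_condition = 0,
                  noise_sd = noise_sd,
                  participant_gain_sd = participant_gain_sd,
                  n_participants = n_participants, ...)
}

# Plant a heavily contaminated participant: multiply `n_bad` of their
# move-to-target responses by `factor`.
contaminate_participant <- function(dataset, participant = "P01",
                                    n_bad = 60, factor = 5, seed = 99) {
  tr <- dataset$trials
  idx <- which(tr$participant_id == participant &
                 tr$task == "move_to_target")
  stopifnot(length(idx) >= n_bad)
  set.seed(seed)
  bad <- sample(idx, n_bad)
  tr$response_distance[bad] <- tr$response_distance[bad] * factor
  dataset$trials <- tr
  dataset
}

# Model-implied mean gain per task x direction under a truth object:
# the gain curves averaged over the design distances and speeds, scaled by
# the means of the lognormal participant and trial multipliers.
implied_mean_gains <- function(truth) {
  d0 <- design_levels()$distances
  mult <- exp(truth$participant_gain_sd^2 / 2)^2 *
    exp(truth$noise_sd^2 / 2)
  cells <- merge(truth$gain_by_condition, truth$alpha_by_condition,
                 by = c("direction", "speed"))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    g <- cells$gain[i]; a <- max(cells$alpha[i], 1e-6)
    data.frame(
      direction = cells$direction[i], speed = cells$speed[i],
      adjust_target = mean(g * (1 - exp(-a * d0)) / (a * d0)) * mult,
      move_to_target = mean(a * d0 / log1p(a * d0 / g)) * mult)
  })
  cell_means <- do.call(rbind, rows)
  long <- rbind(
    data.frame(task = "adjust_target", direction = cell_means$direction,
               mean_gain = cell_means$adjust_target),
    data.frame(task = "move_to_target", direction = cell_means$direction,
               mean_gain = cell_means$move_to_target))
  stats::aggregate(mean_gain ~ task + direction, long, mean)
}

# Independent Tukey-fence oracle (used against remove_outliers).
brute_force_fences <- function(gains, k = 1.5) {
  q <- stats::quantile(gains, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
}
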