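make_trial <- function(task, direction, response, d0 = 20, speed = 1,
                       id = "s1") {
  trial_dataset(tibble::tibble(
    participant_id = id, task = task, direction = direction, speed = speed,
    target_distance = d0, response_distance = response))
}

test_that("gains are the task-appropriate response ratios", {
  mtt <- compute_gains(make_trial("move_to_target", "forward", 20, d0 = 40))
  expect_equal(mtt$trials$gain, 2)
  at <- compute_gains(make_trial("adjust_target", "forward", 10, d0 = 10))
  expect_equal(at$trials$gain, 1)
})

test_that("the reference-ball offset corrects the stop distance", {
  geom <- c(forward = 1.75, backward = -1.25, up = 0, down = 0.5)
  d <- compute_gains(make_trial("move_to_target", "forward", 18.25, d0 = 40),
                     geometry = geom)
  expect_equal(d$trials$gain, 40 / 20)
  # adjust-target responses are not judged against the ball
  at <- compute_gains(make_trial("adjust_target", "forward", 10, d0 = 10),
                      geometry = geom)
  expect_equal(at$trials$gain, 1)
  # a correction that wipes out the whole travelled distance is invalid
  expect_warning(
    bad <- compute_gains(make_trial("move_to_target", "backward", 1, d0 = 5),
                         geometry = geom),
    "non-positive")
  expect_true(is.na(bad$trials$gain))
  expect_true(bad$trials$flagged_outlier)
})

test_that("gains are invariant to the distance unit when offsets scale", {
  geom_m <- reference_ball_offsets()
  geom_cm <- geom_m * 100
  d_m <- compute_gains(make_trial("move_to_target", "forward", 18.25,
                                  d0 = 40), geometry = geom_m)
  d_cm <- make_trial("move_to_target", "forward", 1825, d0 = 40)
  d_cm$trials$target_distance <- 4000
  d_cm <- compute_gains(d_cm, geometry = geom_cm)
  expect_equal(d_m$trials$gain, d_cm$trials$gain)
})

cell_dataset <- function(gains, d0 = 20, speed = 1, direction = "forward",
                         task = "move_to_target") {
  n <- length(gains)
  resp <- if (task == "move_to_target") d0 / gains else gains * d0
  trial_dataset(tibble::tibble(
    participant_id = sprintf("s%02d", seq_len(n)), task = task,
    direction = direction, speed = speed, target_distance = d0,
    response_distance = resp))
}

test_that("Tukey fences match a brute-force oracle on random cells", {
  set.seed(31)
  for (rep in 1:20) {
    gains <- round(exp(rnorm(16, log(2), 0.4)), 6)
    d <- compute_gains(cell_dataset(gains))
    out <- remove_outliers(d)
    fences <- brute_force_fences(gains)
    expected <- gains < fences["lower"] | gains > fences["upper"]
    expect_identical(out$dataset$trials$flagged_outlier, unname(expected))
  }
})

test_that("a single extreme value in a cell is fenced out", {
  d <- compute_gains(cell_dataset(c(rep(1, 7), 10)))
  out <- remove_outliers(d)
  expect_identical(sum(out$dataset$trials$flagged_outlier), 1L)
  expect_identical(which(out$dataset$trials$flagged_outlier), 8L)
})

test_that("an all-equal cell flags nothing (fences collapse onto the value)", {
  d <- compute_gains(cell_dataset(rep(1.5, 8)))
  out <- remove_outliers(d)
  expect_false(any(out$dataset$trials$flagged_outlier))
})

test_that("cells too small for fences pass through with a report warning", {
  d <- compute_gains(cell_dataset(c(1, 1, 9)))
  expect_warning(out <- remove_outliers(d), "< 4 observations")
  expect_false(any(out$dataset$trials$flagged_outlier))
  expect_identical(length(out$report$warnings), 1L)
})

test_that("fencing is group-level within each task/direction/speed/distance cell", {
  # same gains in two different cells: fences are computed per cell, so the
  # extreme value is flagged in both independently
  a <- cell_dataset(c(rep(1, 7), 10), direction = "forward")$trials
  b <- cell_dataset(c(rep(1, 7), 10), direction = "backward")$trials
  d <- compute_gains(trial_dataset(rbind(a, b)))
  out <- remove_outliers(d)
  flagged <- out$dataset$trials[out$dataset$trials$flagged_outlier, ]
  expect_identical(nrow(flagged), 2L)
  expect_setequal(flagged$direction, c("forward", "backward"))
})

test_that("clean low-noise cohorts keep the fence false-positive rate small", {
  tr <- uniform_truth(noise_sd = 0.15, participant_gain_sd = 0,
                      n_participants = 16)
  d <- compute_gains(simulate_cohort(tr, seed = 17))
  out <- remove_outliers(d)
  expect_lt(mean(out$dataset$trials$flagged_outlier), 0.05)
})

test_that("outlier flagging is idempotent on the filtered fixtures", {
  d <- compute_gains(cell_dataset(c(rep(1, 7), 10)))
  once <- remove_outliers(d)
  kept <- once$dataset
  kept$trials <- kept$trials[!kept$trials$flagged_outlier, ]
  twice <- remove_outliers(kept)
  expect_false(any(twice$dataset$trials$flagged_outlier))
})

test_that("participants are excluded only above the per-task quarter rule", {
  tr <- uniform_truth(noise_sd = 0.1, n_participants = 3)
  d <- compute_gains(simulate_cohort(tr, seed = 2))
  flag_n <- function(d, id, task, n) {
    idx <- which(d$trials$participant_id == id & d$trials$task == task)
    d$trials$flagged_outlier[idx[seq_len(n)]] <- TRUE
    d
  }
  # 37 of 144 flagged in one task: excluded
  d37 <- flag_n(d, "P01", "move_to_target", 37)
  ex <- exclude_participants(d37)
  expect_false("P01" %in% ex$trials$participant_id)
  expect_identical(ex$exclusion_log$participant_id, "P01")
  # 36 in each task: retained ("more than a quarter" is strict)
  d36 <- flag_n(flag_n(d, "P02", "move_to_target", 36),
                "P02", "adjust_target", 36)
  ex36 <- exclude_participants(d36)
  expect_true("P02" %in% ex36$trials$participant_id)
  expect_identical(nrow(ex36$exclusion_log), 0L)
})

test_that("the full chain is a no-op on clean identity-observer data", {
  tr <- uniform_truth(gain = 1, alpha = 0, n_participants = 5)
  d <- simulate_cohort(tr, seed = 4)
  pre <- preprocess(d)
  expect_identical(nrow(pre$dataset$exclusion_log), 0L)
  expect_false(any(pre$dataset$trials$flagged_outlier))
  expect_equal(pre$dataset$trials$gain,
               rep(1, nrow(pre$dataset$trials)), tolerance = 1e-4)
})
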