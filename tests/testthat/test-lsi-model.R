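test_that("closed forms agree with the independent ODE oracle", {
  # spot grid here; the full 4 x 4 x 12 sweep runs in the acceptance suite
  for (g in c(0.5, 2)) {
    for (a in c(1e-6, 0.05, 0.2)) {
      p <- lsi_params(g, a)
      for (d0 in c(5, 20, 40)) {
        expect_equal(predict_adjust_target(p, d0),
                     lsi_ode_oracle(p, d0, "adjust_target"),
                     tolerance = 1e-6)
        expect_equal(predict_move_to_target(p, d0),
                     lsi_ode_oracle(p, d0, "move_to_target"),
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("the no-leak limit reduces to proportional responding", {
  p <- lsi_params(1, ALPHA_FLOOR)
  expect_equal(predict_adjust_target(p, 10), 10, tolerance = 1e-4)
  p15 <- lsi_params(1.5, ALPHA_FLOOR)
  expect_equal(predict_move_to_target(p15, 10), 10 / 1.5, tolerance = 1e-3)
})

test_that("the adjust-target prediction saturates at gain/alpha", {
  p <- lsi_params(2, 0.05)
  expect_lt(predict_adjust_target(p, 100), 40)
  expect_equal(predict_adjust_target(p, 1e4), 40, tolerance = 1e-6)
})

test_that("leak signatures: monotonicity in alpha and distance", {
  d0 <- design_levels()$distances
  g <- 1.8
  for (a in c(0.01, 0.05, 0.2)) {
    lo <- lsi_params(g, a); hi <- lsi_params(g, a * 2)
    # more leak -> shorter felt distances, and earlier stops (the remembered
    # target distance decays faster, so the button comes sooner)
    expect_true(all(predict_adjust_target(hi, d0) <
                      predict_adjust_target(lo, d0)))
    expect_true(all(predict_move_to_target(hi, d0) <
                      predict_move_to_target(lo, d0)))
    # implied task gains drift apart with distance
    at_gain <- predict_adjust_target(lo, d0) / d0
    mtt_gain <- d0 / predict_move_to_target(lo, d0)
    expect_true(all(diff(at_gain) < 0))
    expect_true(all(diff(mtt_gain) > 0))
    expect_true(all(mtt_gain >= g))
    expect_true(all(at_gain <= g))
  }
})

make_points <- function(g, a, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d0 <- design_levels()$distances
  p <- lsi_params(g, a)
  list(at = data.frame(d0 = d0, y = predict_adjust_target(p, d0) +
                         rnorm(length(d0), 0, noise)),
       mtt = data.frame(d0 = d0, y = predict_move_to_target(p, d0) +
                          rnorm(length(d0), 0, noise)))
}

test_that("the joint fit recovers exact generating parameters", {
  pts <- make_points(2, 0.05)
  fit <- fit_lsi_joint(pts$at, pts$mtt)
  expect_true(fit$converged)
  expect_equal(fit$params$gain, 2, tolerance = 1e-4)
  expect_equal(fit$params$alpha, 0.05, tolerance = 1e-4)
  expect_lt(fit$sse, 1e-8)
  # cross-check against a dense grid search oracle
  grid <- expand.grid(g = seq(1.5, 2.5, by = 0.01),
                      a = seq(0.01, 0.1, by = 0.001))
  sse <- mapply(function(g, a) {
    p <- lsi_params(g, a)
    sum((predict_adjust_target(p, pts$at$d0) - pts$at$y)^2) +
      sum((predict_move_to_target(p, pts$mtt$d0) - pts$mtt$y)^2)
  }, grid$g, grid$a)
  best <- grid[which.min(sse), ]
  expect_equal(fit$params$gain, best$g, tolerance = 0.011)
  expect_equal(fit$params$alpha, best$a, tolerance = 0.0011)
})

test_that("no-leak data drive the fitted alpha to the floor", {
  pts <- make_points(1.5, ALPHA_FLOOR)
  fit <- fit_lsi_joint(pts$at, pts$mtt)
  expect_equal(fit$params$gain, 1.5, tolerance = 1e-3)
  expect_lt(fit$params$alpha, 1e-3)
})

test_that("the nested no-leak fit can never beat the full fit", {
  for (seed in 1:8) {
    pts <- make_points(runif(1, 0.8, 3), runif(1, 0, 0.1), noise = 0.8,
                       seed = seed)
    full <- fit_lsi_joint(pts$at, pts$mtt)
    red <- fit_no_alpha(pts$at, pts$mtt)
    expect_lte(full$sse, red$sse * (1 + 1e-8))
    cmp <- compare_nested(full, red)
    expect_gte(cmp$deviance, 0)
    expect_lte(cmp$likelihood_ratio, 1)
    expect_equal(cmp$likelihood_ratio,
                 (full$sse / red$sse)^(full$n_points / 2),
                 tolerance = 1e-8)
  }
})

test_that("identical fits compare as ratio 1, deviance 0", {
  pts <- make_points(2, 0.05, noise = 0.5, seed = 2)
  fit <- fit_lsi_joint(pts$at, pts$mtt)
  cmp <- compare_nested(fit, fit)
  expect_identical(cmp$likelihood_ratio, 1)
  expect_identical(cmp$deviance, 0)
})

test_that("on no-leak data the nested fits attain the same optimum", {
  pts <- make_points(1.5, ALPHA_FLOOR, noise = 0.5, seed = 7)
  full <- fit_lsi_joint(pts$at, pts$mtt)
  red <- fit_no_alpha(pts$at, pts$mtt)
  expect_equal(full$params$gain, red$params$gain, tolerance = 0.02)
  expect_lte(full$sse, red$sse * (1 + 1e-8))
  # the free alpha can only soak up noise-level variance
  cmp <- compare_nested(full, red)
  expect_lt(cmp$deviance, stats::qchisq(0.999, 1))
})

test_that("with alpha pinned the single-task fit is least squares in g", {
  # AT responses are linear in g at fixed alpha, so the gain-only fit must
  # match the closed-form least-squares slope
  set.seed(9)
  d0 <- design_levels()$distances
  x <- (1 - exp(-ALPHA_FLOOR * d0)) / ALPHA_FLOOR
  y <- 1.7 * x + rnorm(12, 0, 0.5)
  fit <- fit_no_alpha(at_points = data.frame(d0 = d0, y = y),
                      mtt_points = NULL)
  expect_equal(fit$params$gain, sum(x * y) / sum(x * x), tolerance = 1e-6)
})

test_that("fits refuse underdetermined inputs", {
  expect_error(fit_lsi_joint(data.frame(d0 = c(5, 8), y = c(5, 8)), NULL),
               "at least 3 points")
  expect_error(compare_nested(
    fit_lsi_joint(make_points(2, 0.05)$at, NULL),
    fit_no_alpha(make_points(2, 0.05)$at[1:6, ], NULL)),
    "same data")
})

test_that("per-condition goodness of fit separates noisy directions", {
  tr <- uniform_truth(gain = 2, alpha = 0.03, noise_sd = 0.05,
                      participant_gain_sd = 0, n_participants = 8)
  d <- simulate_cohort(tr, seed = 12)
  # inject extra response noise into the backward direction only
  idx <- d$trials$direction == "backward"
  set.seed(1)
  d$trials$response_distance[idx] <-
    d$trials$response_distance[idx] * exp(rnorm(sum(idx), 0, 0.5))
  pre <- preprocess(d)
  gof <- goodness_of_fit_by_condition(pre$dataset)
  expect_identical(nrow(gof$by_cell), 12L)
  worst <- gof$by_direction$direction[which.max(gof$by_direction$mse)]
  expect_identical(worst, "backward")
})

test_that("zero-noise data yield near-zero MSE in every cell", {
  tr <- uniform_truth(gain = 2, alpha = 0.03, n_participants = 4)
  d <- simulate_cohort(tr, seed = 3)
  pre <- preprocess(d)
  gof <- goodness_of_fit_by_condition(pre$dataset)
  expect_true(all(gof$by_cell$mse < 1e-6))
  expect_true(all(gof$by_cell$converged))
})
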