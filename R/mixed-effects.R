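# Linear mixed model on gains: fitting, contrasts, random-effects ladder -----

# Factor coding shared by all LMM code: treatment contrasts with forward
# and 1 m/s as references, matching the "Forward vs. X" / "1 m/s vs. X"
# presentation of the contrast tables.
lmm_frame <- function(dataset, task) {
  stopifnot(inherits(dataset, "trial_dataset"))
  task <- match.arg(task, TASKS)
  df <- dataset$trials |>
    dplyr::filter(.data$task == !!task, !.data$flagged_outlier,
                  !is.na(.data$gain))
  if (nrow(df) == 0) stop("no usable trials for task ", task, call. = FALSE)
  df$direction <- factor(df$direction, levels = DIRECTIONS)
  df$speed <- factor(df$speed, levels = SPEEDS)
  df$distance <- df$target_distance
  df$participant <- factor(df$participant_id)
  df
}

#' Fit the gain linear mixed model for one task
#'
#' Fits `gain ~ direction + speed + distance + (1 + direction + speed |
#' participant)` by REML with `lme4::lmer`: direction (4 levels, reference
#' forward) and speed (3 levels, reference 1 m/s) as fixed factors, distance
#' (m) as a continuous fixed covariate, and per-participant random
#' intercepts plus direction and speed slopes. No direction x speed
#' interaction is included. If the maximal structure is singular or fails to
#' converge, correlations between random terms are dropped (each random
#' term gets an independent variance) and the simplification is recorded on
#' the result.
#'
#' @param dataset A preprocessed [trial_dataset()].
#' @param task `"move_to_target"` or `"adjust_target"`; the model is fitted
#'   per task.
#' @param random Random-effects structure: `"maximal"` (correlated
#'   intercept + direction + speed slopes, falling back to the
#'   zero-correlation form if singular or unfittable), `"zero_corr"`
#'   (the same variance components with correlations between random terms
#'   dropped — the structure used for bootstrap inference, where the
#'   7 x 7 covariance's correlations are weakly identified from a
#'   16-participant design), or `"intercept"` (random intercept only).
#' @return A list of class `gain_lmm`: `model` (the `lmerMod`), `task`,
#'   `fixed` (tibble of fixed effects), `singular`, `simplified`,
#'   `log_likelihood`.
#' @export
fit_gain_lmm <- function(dataset, task,
                         random = c("maximal", "zero_corr", "intercept")) {
  random <- match.arg(random)
  df <- lmm_frame(dataset, task)
  if (nlevels(droplevels(df$participant)) < 2) {
    stop("at least 2 participants are required for a mixed model",
         call. = FALSE)
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit_one <- function(formula, data) {
    suppressWarnings(suppressMessages(
      lme4::lmer(formula, data = data, REML = TRUE, control = ctrl)))
  }
  fit_zero_corr <- function() {
    # expand the factors to indicator columns so each random slope gets an
    # independent variance and no cross-term correlations
    ind <- indicator_columns(df)
    df2 <- cbind(df, ind)
    f <- stats::as.formula(paste(
      "gain ~ direction + speed + distance + (1 +",
      paste(colnames(ind), collapse = " + "), "|| participant)"))
    fit_one(f, df2)
  }
  simplified <- FALSE
  if (random == "intercept") {
    model <- fit_one(gain ~ direction + speed + distance + (1 | participant),
                     df)
  } else if (random == "zero_corr") {
    model <- fit_zero_corr()
    simplified <- TRUE
  } else {
    model <- tryCatch(
      fit_one(gain ~ direction + speed + distance +
                (1 + direction + speed | participant), df),
      error = function(e) NULL)
    if (is.null(model) || lme4::isSingular(model, tol = 1e-4)) {
      model2 <- tryCatch(fit_zero_corr(), error = function(e) NULL)
      if (!is.null(model2)) {
        model <- model2
        simplified <- TRUE
      }
      if (is.null(model)) {
        stop("mixed model failed to fit", call. = FALSE)
      }
    }
  }
  co <- summary(model)$coefficients
  fixed <- tibble::tibble(term = rownames(co), estimate = co[, "Estimate"],
                          std_error = co[, "Std. Error"])
  structure(list(model = model, task = task, fixed = fixed,
                 singular = lme4::isSingular(model, tol = 1e-4),
                 simplified = simplified,
                 log_likelihood = as.numeric(stats::logLik(model))),
            class = "gain_lmm")
}

indicator_columns <- function(df) {
  mm <- stats::model.matrix(~ direction + speed, df)[, -1, drop = FALSE]
  colnames(mm) <- gsub("[^A-Za-z0-9]", "_", colnames(mm))
  mm
}

#' @export
print.gain_lmm <- function(x, ...) {
  cat("<gain_lmm> task:", x$task,
      if (x$simplified) "(zero-correlation random structure)" else "", "\n")
  print(x$fixed)
  invisible(x)
}

# Contrast machinery ----------------------------------------------------------

factor_terms <- function(factor) {
  if (factor == "direction") {
    levels <- DIRECTIONS
    terms <- c(forward = "", backward = "directionbackward",
               up = "directionup", down = "directiondown")
  } else {
    levels <- as.character(SPEEDS)
    terms <- c("1" = "", "3" = "speed3", "5" = "speed5")
  }
  list(levels = levels, terms = terms)
}

# difference (level_a - level_b) as a linear combination of fixed effects
contrast_estimate <- function(beta, factor, a, b) {
  ft <- factor_terms(factor)
  val <- function(level) {
    term <- ft$terms[[as.character(level)]]
    if (term == "") 0 else unname(beta[term])
  }
  val(a) - val(b)
}

#' All pairwise contrasts of a fixed factor with bootstrap CIs
#'
#' For every unordered pair of levels of `factor`, computes the difference
#' in fixed-effect means as a linear combination of one fit's coefficients
#' (treatment coding; no refitting with rotated references) and a
#' parametric-bootstrap percentile confidence interval: responses are
#' simulated from the fitted model, the model is refitted, and the contrast
#' recomputed, `n_boot` times. A contrast is flagged significant when its
#' CI excludes 0.
#'
#' @param lmm A `gain_lmm` from [fit_gain_lmm()].
#' @param factor `"direction"` or `"speed"`.
#' @param n_boot Bootstrap replicates (default 500).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap simulations.
#' @param draws Optional precomputed fixed-effect draws from
#'   [bootstrap_fixef()]; contrasts on different factors of the same fit
#'   can then share one set of bootstrap refits.
#' @return A tibble of contrasts: `level_a`, `level_b`, `estimate`
#'   (level_a minus level_b), `std_error` (bootstrap SD), `ci_low`,
#'   `ci_high`, `significant`, `n_boot_ok` (successful refits).
#' @export
all_pairwise_contrasts <- function(lmm, factor = c("direction", "speed"),
                                   n_boot = 500, level = 0.95, seed = 1L,
                                   draws = NULL) {
  stopifnot(inherits(lmm, "gain_lmm"))
  factor <- match.arg(factor)
  ft <- factor_terms(factor)
  pairs <- utils::combn(ft$levels, 2)
  beta <- lme4::fixef(lmm$model)
  if (is.null(draws)) draws <- bootstrap_fixef(lmm, n_boot, seed)
  boot_beta <- draws$beta
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    est <- contrast_estimate(beta, factor, a, b)
    dr <- apply(boot_beta, 1, contrast_estimate, factor = factor,
                a = a, b = b)
    dr <- dr[!is.na(dr)]
    ci <- stats::quantile(dr, probs, names = FALSE)
    tibble::tibble(level_a = a, level_b = b, estimate = est,
                   std_error = stats::sd(dr),
                   ci_low = ci[1], ci_high = ci[2],
                   significant = ci[1] > 0 | ci[2] < 0,
                   n_boot_ok = length(dr))
  })
}

#' Parametric-bootstrap draws of the fixed effects
#'
#' Simulates `n_boot` response vectors from the fitted model (marginally,
#' i.e. redrawing the random effects), refits the model to each, and
#' collects the fixed-effect vectors. The draws can be shared by every
#' contrast computed from the same fit.
#'
#' @inheritParams all_pairwise_contrasts
#' @return A list: `beta` (n_boot x p matrix, failed refits as `NA` rows),
#'   `n_fail`.
#' @export
bootstrap_fixef <- function(lmm, n_boot = 500, seed = 1L) {
  stopifnot(inherits(lmm, "gain_lmm"))
  beta <- lme4::fixef(lmm$model)
  withr_seed(seed)
  boot_beta <- matrix(NA_real_, nrow = n_boot, ncol = length(beta),
                      dimnames = list(NULL, names(beta)))
  n_fail <- 0L
  sims <- stats::simulate(lmm$model, nsim = n_boot, use.u = FALSE)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  for (i in seq_len(n_boot)) {
    refit_i <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::refit(lmm$model, sims[[i]], control = ctrl))),
      error = function(e) NULL)
    if (is.null(refit_i)) {
      n_fail <- n_fail + 1L
    } else {
      boot_beta[i, ] <- lme4::fixef(refit_i)
    }
  }
  if (n_fail > 0.1 * n_boot) {
    warning(n_fail, " of ", n_boot, " bootstrap refits failed")
  }
  list(beta = boot_beta, n_fail = n_fail)
}

# Random-effects selection ladder ---------------------------------------------

#' Maximal-to-reduced random-effects comparison ladder
#'
#' Implements the keep-it-maximal selection procedure for the gain model's
#' random-effects structure. Distance slopes are not entertained (they
#' would push the model past a reasonable data-points-per-parameter ratio
#' for this design), so the ladder starts from intercept + direction +
#' speed slopes and tests dropping each slope term in turn by
#' likelihood-ratio tests on ML refits (`anova`), stopping at the simplest
#' structure not significantly worse than the one above it.
#'
#' @param dataset A preprocessed [trial_dataset()].
#' @param task Task to model.
#' @param alpha Significance level for the LRTs (default 0.05).
#' @return A list: `selected` (formula string of the chosen structure),
#'   `chain` (tibble of successive comparisons: models, df, chi-squared,
#'   p-value, decision), `models` (the fitted candidates).
#' @export
random_effects_ladder <- function(dataset, task, alpha = 0.05) {
  df <- lmm_frame(dataset, task)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  candidates <- c(
    maximal = "(1 + direction + speed | participant)",
    no_speed_slopes = "(1 + direction | participant)",
    no_direction_slopes = "(1 + speed | participant)",
    intercept_only = "(1 | participant)")
  fit_struct <- function(re) {
    f <- stats::as.formula(paste("gain ~ direction + speed + distance +", re))
    tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(f, data = df, REML = FALSE, control = ctrl))),
      error = function(e) NULL)
  }
  models <- lapply(candidates, fit_struct)
  if (is.null(models$maximal)) {
    # degenerate data: fall back down the ladder to whatever fits
    for (nm in names(candidates)) {
      if (!is.null(models[[nm]])) {
        return(list(selected = candidates[[nm]],
                    chain = tibble::tibble(
                      comparison = character(), df = integer(),
                      chisq = numeric(), p_value = numeric(),
                      decision = character()),
                    models = models,
                    note = "maximal model unfittable; fell back"))
      }
    }
    stop("no random-effects structure could be fitted", call. = FALSE)
  }
  chain <- list()
  compare <- function(bigger, smaller) {
    an <- suppressMessages(stats::anova(models[[bigger]], models[[smaller]]))
    tibble::tibble(comparison = paste(bigger, "vs", smaller),
                   df = an$Df[2],
                   chisq = an$Chisq[2], p_value = an$`Pr(>Chisq)`[2])
  }
  selected <- "maximal"
  # try dropping speed slopes, then direction slopes, then both
  for (step in list(c("maximal", "no_speed_slopes"),
                    c("maximal", "no_direction_slopes"))) {
    if (is.null(models[[step[2]]])) next
    cmp <- compare(step[2], step[1])
    keep_bigger <- !is.na(cmp$p_value) && cmp$p_value < alpha
    chain[[length(chain) + 1]] <- dplyr::mutate(
      cmp, decision = if (keep_bigger) paste("keep", step[1])
      else paste("reduce to", step[2]))
  }
  drop_speed <- chain[[1]]$decision == "reduce to no_speed_slopes"
  drop_direction <- length(chain) >= 2 &&
    chain[[2]]$decision == "reduce to no_direction_slopes"
  if (drop_speed && drop_direction) {
    if (!is.null(models$intercept_only)) {
      cmp <- compare("intercept_only", "maximal")
      keep_bigger <- !is.na(cmp$p_value) && cmp$p_value < alpha
      chain[[length(chain) + 1]] <- dplyr::mutate(
        cmp, decision = if (keep_bigger) "keep maximal"
        else "reduce to intercept_only")
      selected <- if (keep_bigger) "maximal" else "intercept_only"
    }
  } else if (drop_speed) {
    selected <- "no_speed_slopes"
  } else if (drop_direction) {
    selected <- "no_direction_slopes"
  } else {
    selected <- "maximal"
  }
  list(selected = unname(candidates[[selected]]),
       chain = dplyr::bind_rows(chain), models = models)
}
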