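#' @importFrom rlang .data
#' @import tibble
NULL

# Design vocabularies ---------------------------------------------------------

#' Experimental design constants
#'
#' The factorial design: two response tasks, four motion directions, three
#' simulated speeds (m/s) and twelve target distances (m). Every participant
#' sees each task x direction x speed x distance combination exactly once,
#' giving 288 trials per participant.
#'
#' @name design
#' @keywords internal
NULL

TASKS <- c("move_to_target", "adjust_target")
DIRECTIONS <- c("forward", "backward", "up", "down")
SPEEDS <- c(1, 3, 5)
DISTANCES <- c(5, 8, 11, 14, 17, 20, 23, 26, 29, 32, 35, 40)

#' Design vocabularies
#'
#' Returns the fixed design vocabularies used throughout the pipeline.
#'
#' @return A list with elements `tasks`, `directions`, `speeds`, `distances`.
#' @export
#' @examples
#' design_levels()$distances
design_levels <- function() {
  list(tasks = TASKS, directions = DIRECTIONS, speeds = SPEEDS,
       distances = DISTANCES)
}

# Canonical trial columns, in file order. `gain` and `flagged_outlier` are
# filled by preprocessing; `response_distance` may be NA in a bare schedule.
TRIAL_COLUMNS <- c("participant_id", "task", "direction", "speed",
                   "target_distance", "response_distance", "gain",
                   "flagged_outlier")

# Dataset constructor ---------------------------------------------------------

#' Construct a validated trial dataset
#'
#' Bundles a tibble of trial records with provenance and an exclusion log.
#' Validation enforces the design vocabularies, positive distances, and the
#' one-repetition-per-condition uniqueness of
#' participant x task x direction x speed x distance keys.
#'
#' @param trials A data frame with columns `participant_id`, `task`
#'   (`"move_to_target"` or `"adjust_target"`), `direction` (`"forward"`,
#'   `"backward"`, `"up"`, `"down"`), `speed` (1, 3 or 5 m/s),
#'   `target_distance` (m), and optionally `response_distance` (m), `gain`,
#'   `flagged_outlier`.
#' @param provenance Free-text source tag recorded on the object.
#' @param exclusion_log A tibble of participant-level exclusions
#'   (`participant_id`, `reason`, `n_trials_removed`); usually empty at
#'   construction.
#' @param allow_missing_response If `TRUE`, `response_distance` may be `NA`
#'   (a schedule awaiting simulation); otherwise responses must be positive.
#'
#' @return An object of class `trial_dataset`: a list with elements
#'   `trials` (tibble), `provenance`, `exclusion_log`.
#' @export
trial_dataset <- function(trials, provenance = "unspecified",
                          exclusion_log = empty_exclusion_log(),
                          allow_missing_response = FALSE) {
  trials <- tibble::as_tibble(trials)
  for (col in c("participant_id", "task", "direction", "speed",
                "target_distance")) {
    if (!col %in% names(trials)) {
      stop("trial data lack mandatory column '", col, "'", call. = FALSE)
    }
  }
  if (!"response_distance" %in% names(trials)) {
    trials$response_distance <- NA_real_
  }
  if (!"gain" %in% names(trials)) trials$gain <- NA_real_
  if (!"flagged_outlier" %in% names(trials)) trials$flagged_outlier <- FALSE
  trials$participant_id <- as.character(trials$participant_id)
  trials$task <- as.character(trials$task)
  trials$direction <- as.character(trials$direction)
  trials$speed <- as.numeric(trials$speed)
  trials$target_distance <- as.numeric(trials$target_distance)
  trials$response_distance <- as.numeric(trials$response_distance)
  trials$gain <- as.numeric(trials$gain)
  trials$flagged_outlier <- as.logical(trials$flagged_outlier)
  trials <- trials[, TRIAL_COLUMNS]

  bad_task <- !trials$task %in% TASKS
  if (any(bad_task)) {
    stop("unknown task label(s): ",
         paste(unique(trials$task[bad_task]), collapse = ", "), call. = FALSE)
  }
  bad_dir <- !trials$direction %in% DIRECTIONS
  if (any(bad_dir)) {
    stop("unknown direction label(s): ",
         paste(unique(trials$direction[bad_dir]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!trials$speed %in% SPEEDS)) {
    stop("speed must be one of ", paste(SPEEDS, collapse = ", "),
         " m/s", call. = FALSE)
  }
  if (any(!is.finite(trials$target_distance)) ||
      any(trials$target_distance <= 0)) {
    stop("target_distance must be positive and finite", call. = FALSE)
  }
  if (!allow_missing_response) {
    if (any(is.na(trials$response_distance)) ||
        any(trials$response_distance <= 0)) {
      stop("response_distance must be positive; use read_trials() to ",
           "collect invalid rows into a rejects report", call. = FALSE)
    }
  } else if (any(!is.na(trials$response_distance) &
                 trials$response_distance <= 0)) {
    stop("response_distance must be positive where present", call. = FALSE)
  }

  key <- paste(trials$participant_id, trials$task, trials$direction,
               trials$speed, trials$target_distance, sep = "\r")
  if (anyDuplicated(key) > 0) {
    dup <- key[duplicated(key)][1]
    stop("duplicated condition key (each condition is presented once): ",
         gsub("\r", " / ", dup), call. = FALSE)
  }

  structure(list(trials = trials, provenance = provenance,
                 exclusion_log = tibble::as_tibble(exclusion_log)),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("<trial_dataset> ", nrow(x$trials), " trials, ",
      dplyr::n_distinct(x$trials$participant_id), " participants (",
      x$provenance, ")\n", sep = "")
  if (nrow(x$exclusion_log) > 0) {
    cat("  excluded participants: ",
        paste(x$exclusion_log$participant_id, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

empty_exclusion_log <- function() {
  tibble::tibble(participant_id = character(), reason = character(),
                 n_trials_removed = integer())
}

# Readers / writers -----------------------------------------------------------

#' Default schema mapping for trial CSV files
#'
#' A schema map bridges arbitrary column names and category labels in a
#' source file onto the canonical trial schema. `column_map` maps canonical
#' field names to source column names; `task_synonyms` and
#' `direction_synonyms` map (case-insensitively) source labels onto the
#' canonical vocabularies. The default is the identity mapping for files
#' written by [write_trials()], plus common shorthand labels.
#'
#' @return A list with elements `column_map`, `task_synonyms`,
#'   `direction_synonyms`.
#' @export
default_schema_map <- function() {
  list(
    column_map = c(
      participant_id = "participant_id", task = "task",
      direction = "direction", speed = "speed",
      target_distance = "target_distance",
      response_distance = "response_distance",
      gain = "gain", flagged_outlier = "flagged_outlier"
    ),
    task_synonyms = c(
      "move_to_target" = "move_to_target", "mtt" = "move_to_target",
      "move-to-target" = "move_to_target",
      "adjust_target" = "adjust_target", "at" = "adjust_target",
      "adjust-target" = "adjust_target"
    ),
    direction_synonyms = c(
      "forward" = "forward", "fwd" = "forward", "forwards" = "forward",
      "backward" = "backward", "bwd" = "backward", "backwards" = "backward",
      "up" = "up", "upward" = "up", "upwards" = "up",
      "down" = "down", "downward" = "down", "downwards" = "down"
    )
  )
}

#' Read a schema map from a YAML config file
#'
#' @param path Path to a YAML file with keys `column_map`, and optionally
#'   `task_synonyms`, `direction_synonyms`; omitted parts fall back to
#'   [default_schema_map()].
#' @return A schema map list.
#' @export
read_schema_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  def <- default_schema_map()
  map <- def
  if (!is.null(cfg$column_map)) {
    cm <- unlist(cfg$column_map)
    map$column_map[names(cm)] <- cm
  }
  if (!is.null(cfg$task_synonyms)) {
    ts <- unlist(cfg$task_synonyms)
    map$task_synonyms[tolower(names(ts))] <- tolower(ts)
  }
  if (!is.null(cfg$direction_synonyms)) {
    ds <- unlist(cfg$direction_synonyms)
    map$direction_synonyms[tolower(names(ds))] <- tolower(ds)
  }
  map
}

normalize_labels <- function(x, synonyms, what) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(synonyms[key])
  bad <- is.na(out) & !is.na(key)
  if (any(bad)) {
    stop("unrecognized ", what, " label(s): ",
         paste(unique(key[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Read trial records from a delimited text file
#'
#' Reads a long-format CSV (one row per trial), maps source columns onto the
#' canonical schema, normalizes task/direction labels through the synonym
#' tables, and validates rows. Rows that fail row-level validation
#' (non-positive or missing distances) are collected into a rejects report
#' attached as the `"rejects"` attribute, never silently dropped.
#'
#' @param path Path to a CSV file.
#' @param schema_map A schema map (see [default_schema_map()]), or a path to
#'   a YAML schema-map config.
#' @param provenance Source tag recorded on the dataset; defaults to `path`.
#' @return A [trial_dataset()] with attribute `rejects`: a tibble of the
#'   rejected source rows and the reason each was rejected.
#' @export
read_trials <- function(path, schema_map = default_schema_map(),
                        provenance = path) {
  if (is.character(schema_map)) schema_map <- read_schema_map(schema_map)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  cm <- schema_map$column_map
  mandatory <- c("participant_id", "task", "direction", "speed",
                 "target_distance")
  missing_src <- setdiff(cm[mandatory], names(raw))
  if (length(missing_src) > 0) {
    stop("input file lacks mapped column(s): ",
         paste(missing_src, collapse = ", "), call. = FALSE)
  }
  get_col <- function(field) {
    src <- cm[[field]]
    if (!is.null(src) && src %in% names(raw)) raw[[src]] else NA
  }
  trials <- tibble::tibble(
    participant_id = as.character(get_col("participant_id")),
    task = normalize_labels(get_col("task"), schema_map$task_synonyms,
                            "task"),
    direction = normalize_labels(get_col("direction"),
                                 schema_map$direction_synonyms, "direction"),
    speed = suppressWarnings(as.numeric(get_col("speed"))),
    target_distance = suppressWarnings(as.numeric(get_col("target_distance"))),
    response_distance = suppressWarnings(
      as.numeric(get_col("response_distance")))
  )
  if ("gain" %in% names(cm) && cm[["gain"]] %in% names(raw)) {
    trials$gain <- suppressWarnings(as.numeric(raw[[cm[["gain"]]]]))
  }
  if ("flagged_outlier" %in% names(cm) &&
      cm[["flagged_outlier"]] %in% names(raw)) {
    trials$flagged_outlier <- as.logical(raw[[cm[["flagged_outlier"]]]])
  }

  reason <- rep(NA_character_, nrow(trials))
  reason[is.na(trials$target_distance) | trials$target_distance <= 0] <-
    "non-positive or missing target_distance"
  reason[!is.na(trials$response_distance) &
           trials$response_distance <= 0] <-
    "non-positive response_distance"
  reason[is.na(trials$response_distance)] <- "missing response_distance"
  reason[is.na(trials$speed) | !trials$speed %in% SPEEDS] <-
    "speed outside design"
  ok <- is.na(reason)
  rejects <- dplyr::mutate(trials[!ok, ], reject_reason = reason[!ok])

  ds <- trial_dataset(trials[ok, ], provenance = provenance)
  attr(ds, "rejects") <- rejects
  ds
}

#' Write trial records to a canonical CSV file
#'
#' Writes the dataset in the canonical long format (fixed header, one row
#' per trial, full precision) so that `read_trials()` on the result
#' reproduces the dataset field for field.
#'
#' @param dataset A [trial_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  out <- dataset$trials
  # full-precision doubles so read(write(d)) round-trips exactly
  for (col in c("speed", "target_distance", "response_distance", "gain")) {
    out[[col]] <- format(out[[col]], digits = 17, trim = TRUE,
                         scientific = FALSE)
    out[[col]][out[[col]] %in% c("NA", "NaN")] <- NA
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
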