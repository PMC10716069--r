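#' Absolute angular error between two bearings
#'
#' The angular disparity between a response bearing and the true bearing,
#' reduced to the shortest arc: `min(|d|, 360 - |d|)` with `d` the raw
#' difference modulo 360. This is the per-trial score of the direction
#' estimation (judgments of relative direction) task; a directionally
#' uninformative (uniform) response has an expected error of exactly 90
#' degrees, the chance level.
#'
#' @param response_bearing,true_bearing Bearings in degrees. Any finite
#'   values are accepted; the result is invariant to adding multiples of 360
#'   to either argument. Vectorized.
#' @return Error in degrees, in `[0, 180]`.
#' @examples
#' absolute_angular_error(350, 10) # 20, across the wrap
#' @export
absolute_angular_error <- function(response_bearing, true_bearing) {
  stopifnot(all(is.finite(response_bearing)), all(is.finite(true_bearing)))
  d <- abs((response_bearing - true_bearing) %% 360)
  pmin(d, 360 - d)
}

#' True bearing of a target in a landmark-facing reference frame
#'
#' The direction a participant should indicate on the pointer circle:
#' standing at `observer`, facing `facing_point`, the clockwise angle from
#' straight ahead to `target`.
#'
#' @param observer,facing_point,target Length-2 numeric coordinates
#'   (meters, planar).
#' @return Bearing in degrees, in `[0, 360)`. `0` is dead ahead, `90` is to
#'   the right.
#' @export
true_bearing <- function(observer, facing_point, target) {
  observer <- as.numeric(observer); facing_point <- as.numeric(facing_point)
  target <- as.numeric(target)
  u <- facing_point - observer
  v <- target - observer
  if (sqrt(sum(u^2)) == 0) stop("facing point coincides with observer", call. = FALSE)
  if (sqrt(sum(v^2)) == 0) stop("target coincides with observer", call. = FALSE)
  # clockwise angle from u to v: atan2 in the left-handed (screen) sense
  ang <- atan2(u[1] * v[2] - u[2] * v[1], u[1] * v[1] + u[2] * v[2])
  ((-ang) * 180 / pi) %% 360
}

pointing_cols <- c("participant_id", "phase", "trial_id", "start_landmark",
                   "target_landmark", "response_bearing_deg", "true_bearing_deg")
shortcut_cols <- c("participant_id", "trial_id", "start_landmark",
                   "target_landmark", "success", "traveled_length_m",
                   "shortest_length_m")

check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " table is missing column '", miss[1], "'", call. = FALSE)
  }
  df
}

#' Read trial tables from their CSV interchange formats
#'
#' One row per trial, UTF-8, "." decimal separator. Pointing tables carry
#' `participant_id, phase, trial_id, start_landmark, target_landmark,
#' response_bearing_deg, true_bearing_deg`; shortcutting tables carry
#' `participant_id, trial_id, start_landmark, target_landmark, success,
#' traveled_length_m, shortest_length_m` (`success` is 0/1 or TRUE/FALSE;
#' `traveled_length_m` may be empty on unsuccessful trials).
#'
#' @param path CSV file path.
#' @return A validated data.frame.
#' @export
read_pointing_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(df, pointing_cols, "pointing")
  validate_pointing(df)
}

#' @rdname read_pointing_trials
#' @export
read_shortcut_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(df, shortcut_cols, "shortcut")
  validate_shortcut(df)
}

validate_pointing <- function(df) {
  check_cols(df, pointing_cols, "pointing")
  stopifnot(all(df$phase %in% c("I", "II")))
  b <- c(df$response_bearing_deg, df$true_bearing_deg)
  if (any(!is.finite(b)) || any(b < 0) || any(b >= 360)) {
    stop("bearings must lie in [0, 360)", call. = FALSE)
  }
  df
}

validate_shortcut <- function(df) {
  check_cols(df, shortcut_cols, "shortcut")
  df$success <- as.logical(df$success)
  if (anyNA(df$success)) stop("success must be logical or 0/1", call. = FALSE)
  if (any(!is.finite(df$shortest_length_m)) || any(df$shortest_length_m <= 0)) {
    stop("shortest_length_m must be positive", call. = FALSE)
  }
  tr <- df$traveled_length_m[df$success]
  if (anyNA(tr)) stop("successful trials must record traveled_length_m", call. = FALSE)
  # allow a sliver of float summation error below the shortest path
  if (any(tr < df$shortest_length_m[df$success] * (1 - 1e-9))) {
    stop("traveled_length_m below shortest_length_m on a successful trial", call. = FALSE)
  }
  df
}

#' Apply participant- and trial-level exclusion rules
#'
#' Mirrors the screening applied to the shortcutting task: participants who
#' fail to reach the target on more than `participant_fail_max` of their
#' shortcutting trials are removed from both measures; then any shortcutting
#' trial whose failure fraction among the remaining participants is at least
#' `trial_fail_max` is dropped from the efficiency measure. The participant
#' rule is strict (`> 0.30`, "more than 30%"), the trial rule is inclusive
#' (`>= 0.30`: a trial failed by exactly 30% of the cohort is excluded).
#'
#' @param pointing Pointing trial table (see [read_pointing_trials()]).
#' @param shortcut Shortcutting trial table.
#' @param participant_fail_max Strict upper bound on a participant's failure
#'   fraction (default 0.30).
#' @param trial_fail_max Inclusive upper bound on a trial's failure fraction
#'   after participant removal (default 0.30).
#' @return A list with the filtered `pointing` and `shortcut` tables and an
#'   exclusion `log` data.frame (`type`, `id`, `fail_fraction`).
#' @export
apply_exclusions <- function(pointing, shortcut,
                             participant_fail_max = 0.30,
                             trial_fail_max = 0.30) {
  pointing <- validate_pointing(pointing)
  shortcut <- validate_shortcut(shortcut)
  stopifnot(participant_fail_max > 0, participant_fail_max < 1,
            trial_fail_max > 0, trial_fail_max < 1)

  p_fail <- tapply(!shortcut$success, shortcut$participant_id, mean)
  drop_p <- names(p_fail)[p_fail > participant_fail_max]
  log <- data.frame(type = character(0), id = character(0),
                    fail_fraction = numeric(0), stringsAsFactors = FALSE)
  if (length(drop_p)) {
    log <- rbind(log, data.frame(type = "participant", id = drop_p,
                                 fail_fraction = as.numeric(p_fail[drop_p])))
    shortcut <- shortcut[!shortcut$participant_id %in% drop_p, , drop = FALSE]
    pointing <- pointing[!pointing$participant_id %in% drop_p, , drop = FALSE]
  }
  if (!nrow(shortcut) || !nrow(pointing)) {
    stop("no trials remain after participant exclusion", call. = FALSE)
  }

  t_fail <- tapply(!shortcut$success, shortcut$trial_id, mean)
  drop_t <- names(t_fail)[t_fail >= trial_fail_max]
  if (length(drop_t)) {
    log <- rbind(log, data.frame(type = "trial", id = drop_t,
                                 fail_fraction = as.numeric(t_fail[drop_t])))
    shortcut <- shortcut[!as.character(shortcut$trial_id) %in% drop_t, , drop = FALSE]
  }
  if (!nrow(shortcut)) stop("no trials remain after trial exclusion", call. = FALSE)
  rownames(log) <- NULL
  list(pointing = pointing, shortcut = shortcut, log = log)
}

#' Per-trial travel efficiency with imputation for failed trials
#'
#' Travel efficiency is the ratio of the distance traveled to the shortest
#' traversable path length for that trial's start-goal pair (1 = optimal).
#' Unsuccessful trials carry no meaningful traveled distance; their
#' efficiency is replaced by the average learned-route efficiency — the
#' score of a participant who always follows the learned tour.
#'
#' @param shortcut Shortcutting trial table.
#' @param learned_route_eff The imputation constant (> 1); typically
#'   [learned_route_efficiency()] of the maze, or a published override such
#'   as 2.54 (desktop) or 2.19 (immersive).
#' @return The table with an added `efficiency` column and an `imputed`
#'   logical column.
#' @export
impute_failed <- function(shortcut, learned_route_eff) {
  shortcut <- validate_shortcut(shortcut)
  stopifnot(is.numeric(learned_route_eff), length(learned_route_eff) == 1,
            learned_route_eff > 1)
  eff <- ifelse(shortcut$success,
                shortcut$traveled_length_m / shortcut$shortest_length_m,
                learned_route_eff)
  shortcut$efficiency <- eff
  shortcut$imputed <- !shortcut$success
  shortcut
}

#' Participant-level scores for both measures
#'
#' Arithmetic mean of per-trial scores for each participant: absolute
#' pointing error per phase (degrees) and travel efficiency (ratio).
#' Participants present in only one table are retained with `NA` in the
#' missing measure (with a warning); participants without Phase II pointing
#' keep an `NA` there.
#'
#' @param pointing Pointing trial table (post-exclusion).
#' @param efficiency_trials Shortcutting table with an `efficiency` column
#'   (see [impute_failed()]).
#' @param matching_pairs_only If `TRUE`, restrict pointing trials to those
#'   whose unordered (start, target) landmark pair also occurs in the
#'   shortcutting task, the stricter scoring variant.
#' @return A data.frame with one row per participant: `participant_id`,
#'   `pointing_error_I`, `pointing_error_II`, `efficiency` and the trial
#'   counts behind each mean.
#' @export
score_participants <- function(pointing, efficiency_trials,
                               matching_pairs_only = FALSE) {
  pointing <- validate_pointing(pointing)
  if (!"efficiency" %in% names(efficiency_trials)) {
    stop("efficiency_trials must carry an 'efficiency' column; run impute_failed() first",
         call. = FALSE)
  }
  if (matching_pairs_only) {
    pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
    keep <- pair_key(pointing$start_landmark, pointing$target_landmark) %in%
      pair_key(efficiency_trials$start_landmark, efficiency_trials$target_landmark)
    pointing <- pointing[keep, , drop = FALSE]
    if (!nrow(pointing)) stop("no pointing trials match shortcutting pairs", call. = FALSE)
  }
  pointing$error <- absolute_angular_error(pointing$response_bearing_deg,
                                           pointing$true_bearing_deg)

  ids <- sort(unique(c(pointing$participant_id, efficiency_trials$participant_id)))
  only_one <- setdiff(ids, intersect(unique(pointing$participant_id),
                                     unique(efficiency_trials$participant_id)))
  if (length(only_one)) {
    warning("participant(s) present in only one measure: ",
            paste(only_one, collapse = ", "), call. = FALSE)
  }

  mean_by <- function(values, id) {
    out <- tapply(values, id, mean)
    as.numeric(out[match(ids, names(out))])
  }
  count_by <- function(id) {
    out <- tapply(id, id, length)
    n <- as.integer(out[match(ids, names(out))])
    ifelse(is.na(n), 0L, n)
  }
  p1 <- pointing[pointing$phase == "I", , drop = FALSE]
  p2 <- pointing[pointing$phase == "II", , drop = FALSE]
  data.frame(
    participant_id = ids,
    pointing_error_I  = mean_by(p1$error, p1$participant_id),
    pointing_error_II = mean_by(p2$error, p2$participant_id),
    efficiency = mean_by(efficiency_trials$efficiency,
                         efficiency_trials$participant_id),
    n_pointing_I = count_by(p1$participant_id),
    n_pointing_II = count_by(p2$participant_id),
    n_efficiency = count_by(efficiency_trials$participant_id),
    stringsAsFactors = FALSE
  )
}

#' Long-to-wide trial matrix for reliability estimation
#'
#' @param trials A trial table.
#' @param value One of `"pointing"` (absolute angular error is computed from
#'   the bearing columns) or `"efficiency"` (requires the `efficiency`
#'   column from [impute_failed()]).
#' @param phase For pointing, which phase to extract.
#' @return A numeric matrix, participants as rows (rownames are ids), trials
#'   as columns; missing cells are `NA`.
#' @export
trial_matrix <- function(trials, value = c("pointing", "efficiency"),
                         phase = "I") {
  value <- match.arg(value)
  if (value == "pointing") {
    trials <- validate_pointing(trials)
    trials <- trials[trials$phase == phase, , drop = FALSE]
    v <- absolute_angular_error(trials$response_bearing_deg,
                                trials$true_bearing_deg)
  } else {
    if (!"efficiency" %in% names(trials)) {
      stop("run impute_failed() before building an efficiency matrix", call. = FALSE)
    }
    v <- trials$efficiency
  }
  ids <- sort(unique(trials$participant_id))
  cols <- sort(unique(as.character(trials$trial_id)))
  m <- matrix(NA_real_, length(ids), length(cols),
              dimnames = list(ids, cols))
  m[cbind(match(trials$participant_id, ids),
          match(as.character(trials$trial_id), cols))] <- v
  m
}
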