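#' Generative specification for a synthetic cohort
#'
#' Encodes the statistical structure the analysis pipeline assumes: two
#' latent ability clusters ("high"/"low" spatial learners), correlated
#' pointing and shortcutting abilities within each cluster, per-trial
#' difficulty offsets, a uniform-guessing floor for pointing (which pins
#' expected error to the 90-degree chance level as guessing dominates) and
#' a ceiling at perfect efficiency (an ability-dependent point mass at
#' exactly 1) for shortcutting, with failed trials capped and later imputed
#' at the learned-route efficiency.
#'
#' The response models are:
#' \itemize{
#'   \item Pointing: with probability `plogis(guess_intercept -
#'     guess_slope * ability)` the response bearing is uniform on
#'     \code{[0, 360)}; otherwise the signed error is wrapped-normal around
#'     the true bearing with concentration `kappa = exp(conc_intercept +
#'     conc_gain * ability - b_j)` (error SD `(180/pi)/sqrt(kappa)`
#'     degrees before wrapping), `b_j` the trial difficulty offset. True
#'     bearings are uniform.
#'   \item Shortcutting: success is Bernoulli with probability
#'     `plogis(success_intercept + success_slope * ability - d_j)`;
#'     successful trials score efficiency exactly 1 with probability
#'     `plogis(ceiling_intercept + ceiling_slope * ability)` (the ceiling
#'     mass), otherwise `1 + excess` with `excess` exponential with mean
#'     `excess_scale * exp(d_j - excess_gain * ability)`, censored above at
#'     `learned_route_eff`.
#' }
#' All randomness flows from one root seed through named substreams
#' (cohort, difficulty, pointing phase I/II, shortcut, walks, trial pairs),
#' so each stage is independently reproducible.
#'
#' @param n_high,n_low Participants per latent cluster.
#' @param ability_mean_high,ability_mean_low Length-2 means (pointing,
#'   shortcutting ability) per cluster, unitless latent scale.
#' @param ability_sd_high,ability_sd_low Length-2 latent SDs per cluster.
#' @param rho Within-cluster correlation of the two abilities; either a
#'   single value or `c(high, low)`. The clusters may differ: near-chance
#'   pointing with preserved shortcutting implies the low cluster's latent
#'   coupling is itself weak, not merely attenuated.
#' @param n_pointing_trials,n_shortcut_trials Trial counts.
#' @param pointing_difficulty,shortcut_difficulty Optional explicit offset
#'   vectors `b_j` / `d_j`; by default drawn from the difficulty substream
#'   with SDs `pointing_difficulty_sd` / `shortcut_difficulty_sd`.
#' @param pointing_difficulty_sd,shortcut_difficulty_sd Difficulty spread.
#' @param guess_intercept,guess_slope Guessing-probability curve.
#' @param conc_intercept,conc_gain Log-concentration mapping.
#' @param phase2_bonus Ability shift applied in Phase II pointing (practice
#'   and further exposure between phases).
#' @param success_intercept,success_slope Shortcut success curve.
#' @param ceiling_intercept,ceiling_slope Probability of an exact-1
#'   (perfectly efficient) successful trial.
#' @param excess_scale,excess_gain Scale of the efficiency excess.
#' @param learned_route_eff Ceiling/imputation constant (> 1).
#' @param seed Root seed.
#' @return A list of class `sim_config`.
#' @seealso [sim_preset()] for ready-made configurations.
#' @export
sim_config <- function(n_high = 20, n_low = 37,
                       ability_mean_high = c(0.8, 1),
                       ability_mean_low = c(-1.1, -1),
                       ability_sd_high = c(0.75, 0.75),
                       ability_sd_low = c(0.85, 0.85),
                       rho = c(0.95, 0.15),
                       n_pointing_trials = 27,
                       n_shortcut_trials = 20,
                       pointing_difficulty = NULL,
                       shortcut_difficulty = NULL,
                       pointing_difficulty_sd = 0.4,
                       shortcut_difficulty_sd = 0.3,
                       guess_intercept = 0.675, guess_slope = 1.52,
                       conc_intercept = 0.15, conc_gain = 1.15,
                       phase2_bonus = 0.3,
                       success_intercept = 3.0, success_slope = 1.0,
                       ceiling_intercept = -2.2, ceiling_slope = 1.5,
                       excess_scale = 0.95, excess_gain = 0.7,
                       learned_route_eff = 2.54,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$rho <- rep_len(cfg$rho, 2L)  # c(high, low)
  stopifnot(cfg$n_high >= 0, cfg$n_low >= 0, cfg$n_high + cfg$n_low > 0,
            all(abs(cfg$rho) <= 1), cfg$learned_route_eff > 1,
            all(cfg$ability_sd_high > 0), all(cfg$ability_sd_low > 0),
            cfg$n_pointing_trials >= 1, cfg$n_shortcut_trials >= 1)
  if (!is.null(cfg$pointing_difficulty)) {
    stopifnot(length(cfg$pointing_difficulty) == cfg$n_pointing_trials)
  }
  if (!is.null(cfg$shortcut_difficulty)) {
    stopifnot(length(cfg$shortcut_difficulty) == cfg$n_shortcut_trials)
  }
  structure(cfg, class = "sim_config")
}

#' Ready-made cohort configurations
#'
#' `"desktop-like"` emulates a harder-to-learn desktop virtual maze: a
#' larger low-ability cluster pointing near chance with weak internal
#' consistency, 27 pointing trials, 20 shortcutting trials and a
#' learned-route efficiency of 2.54. `"immersive-like"` emulates an easier
#' ambulatory immersive maze: balanced clusters, better pointing, a heavier
#' efficiency ceiling (more exact-1 trials, depressing shortcut
#' reliability), 24 trials per task and a learned-route efficiency of 2.19.
#'
#' @param name `"desktop-like"` or `"immersive-like"`.
#' @param seed Root seed.
#' @return A `sim_config`.
#' @export
sim_preset <- function(name = c("desktop-like", "immersive-like"), seed = 1L) {
  name <- match.arg(name)
  if (name == "desktop-like") {
    sim_config(seed = seed)
  } else {
    sim_config(
      n_high = 24, n_low = 24,
      ability_mean_high = c(1.4, 1.4), ability_mean_low = c(-0.9, -1.0),
      n_pointing_trials = 24, n_shortcut_trials = 24,
      ceiling_intercept = -0.9, ceiling_slope = 1.6,
      excess_scale = 0.9,
      learned_route_eff = 2.19, seed = seed
    )
  }
}

# Named substreams off the root seed; keeps every stage independently
# reproducible and all derived seeds inside 32-bit range.
substream_seed <- function(seed, stream) {
  offsets <- c(cohort = 1L, difficulty = 2L, pointing_I = 3L,
               pointing_II = 4L, shortcut = 5L, walk = 6L, pairs = 7L,
               engineered = 8L)
  if (!stream %in% names(offsets)) stop("unknown substream '", stream, "'")
  (as.integer(seed) %% 1000003L) * 2011L + offsets[[stream]] * 104729L
}

#' Draw a latent cohort
#'
#' Abilities are bivariate normal within each cluster with correlation
#' `rho`; cluster labels record the generating ground truth.
#'
#' @param config A `sim_config`.
#' @return Data.frame `participant_id`, `cluster` ("high"/"low"),
#'   `ability_pointing`, `ability_shortcut`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "cohort"))
  draw <- function(n, mu, sd, rho) {
    if (!n) return(NULL)
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    cbind(mu[1] + sd[1] * z1, mu[2] + sd[2] * z2)
  }
  hi <- draw(config$n_high, config$ability_mean_high, config$ability_sd_high,
             config$rho[1])
  lo <- draw(config$n_low, config$ability_mean_low, config$ability_sd_low,
             config$rho[2])
  ab <- rbind(hi, lo)
  n <- nrow(ab)
  data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    cluster = rep(c("high", "low"), c(config$n_high, config$n_low)),
    ability_pointing = ab[, 1],
    ability_shortcut = ab[, 2],
    stringsAsFactors = FALSE
  )
}

pointing_difficulties <- function(config) {
  if (!is.null(config$pointing_difficulty)) return(config$pointing_difficulty)
  set.seed(substream_seed(config$seed, "difficulty"))
  stats::rnorm(config$n_pointing_trials, 0, config$pointing_difficulty_sd)
}

shortcut_difficulties <- function(config) {
  if (!is.null(config$shortcut_difficulty)) return(config$shortcut_difficulty)
  set.seed(substream_seed(config$seed, "difficulty") + 1L)
  stats::rnorm(config$n_shortcut_trials, 0, config$shortcut_difficulty_sd)
}

#' Simulate pointing (direction estimation) trials
#'
#' Implements the guessing-mixture response model of [sim_config()]. Trial
#' landmark pairs may be supplied (e.g. from a maze fixture); by default
#' placeholder landmark names are used — true bearings are uniform either
#' way, so the maze geometry does not enter the pointing model.
#'
#' @param cohort From [generate_cohort()].
#' @param config The `sim_config`.
#' @param phase `"I"` or `"II"`; Phase II adds `phase2_bonus` to ability.
#' @param pairs Optional data.frame (`start_landmark`, `target_landmark`)
#'   with `n_pointing_trials` rows.
#' @return A pointing trial table (see [read_pointing_trials()]).
#' @export
generate_pointing_trials <- function(cohort, config, phase = c("I", "II"),
                                     pairs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  phase <- match.arg(phase)
  k <- config$n_pointing_trials
  b <- pointing_difficulties(config)
  if (is.null(pairs)) {
    pairs <- data.frame(start_landmark = sprintf("S%02d", seq_len(k)),
                        target_landmark = sprintf("T%02d", seq_len(k)))
  }
  stopifnot(nrow(pairs) == k)
  set.seed(substream_seed(config$seed,
                          if (phase == "I") "pointing_I" else "pointing_II"))
  n <- nrow(cohort)
  theta <- cohort$ability_pointing + if (phase == "II") config$phase2_bonus else 0

  id <- rep(cohort$participant_id, each = k)
  trial <- rep(seq_len(k), times = n)
  th <- rep(theta, each = k)
  bj <- rep(b, times = n)

  true_b <- stats::runif(n * k, 0, 360)
  g <- stats::plogis(config$guess_intercept - config$guess_slope * th)
  guess <- stats::runif(n * k) < g
  kappa <- exp(config$conc_intercept + config$conc_gain * th - bj)
  sd_deg <- (180 / pi) / sqrt(kappa)
  err <- stats::rnorm(n * k, 0, sd_deg)
  resp <- ifelse(guess, stats::runif(n * k, 0, 360), (true_b + err) %% 360)

  data.frame(
    participant_id = id, phase = phase,
    trial_id = sprintf("PT%02d", trial),
    start_landmark = pairs$start_landmark[trial],
    target_landmark = pairs$target_landmark[trial],
    response_bearing_deg = resp,
    true_bearing_deg = true_b,
    stringsAsFactors = FALSE
  )
}

#' Simulate shortcutting trials
#'
#' Implements the success/ceiling/excess model of [sim_config()]. Shortest
#' path lengths come from `shortest_lengths` (e.g. maze-derived); traveled
#' length is `efficiency * shortest_length` for successful trials and
#' absent for failures (timeouts are untracked).
#'
#' @param cohort From [generate_cohort()].
#' @param config The `sim_config`.
#' @param shortest_lengths Numeric vector of per-trial shortest path
#'   lengths in meters (recycled to `n_shortcut_trials`); default 8 m.
#' @param pairs Optional landmark pair data.frame as in
#'   [generate_pointing_trials()].
#' @return A shortcutting trial table (see [read_shortcut_trials()]).
#' @export
generate_shortcut_trials <- function(cohort, config, shortest_lengths = 8,
                                     pairs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$n_shortcut_trials
  d <- shortcut_difficulties(config)
  shortest_lengths <- rep_len(shortest_lengths, k)
  stopifnot(all(shortest_lengths > 0))
  if (is.null(pairs)) {
    pairs <- data.frame(start_landmark = sprintf("S%02d", seq_len(k)),
                        target_landmark = sprintf("T%02d", seq_len(k)))
  }
  stopifnot(nrow(pairs) == k)
  set.seed(substream_seed(config$seed, "shortcut"))
  n <- nrow(cohort)
  id <- rep(cohort$participant_id, each = k)
  trial <- rep(seq_len(k), times = n)
  th <- rep(cohort$ability_shortcut, each = k)
  dj <- rep(d, times = n)

  p_succ <- stats::plogis(config$success_intercept + config$success_slope * th - dj)
  success <- stats::runif(n * k) < p_succ
  p_ceil <- stats::plogis(config$ceiling_intercept + config$ceiling_slope * th)
  at_ceiling <- stats::runif(n * k) < p_ceil
  excess <- stats::rexp(n * k) * config$excess_scale * exp(dj - config$excess_gain * th)
  eff <- 1 + pmin(ifelse(at_ceiling, 0, excess), config$learned_route_eff - 1)
  shortest <- shortest_lengths[trial]

  data.frame(
    participant_id = id,
    trial_id = sprintf("ST%02d", trial),
    start_landmark = pairs$start_landmark[trial],
    target_landmark = pairs$target_landmark[trial],
    success = success,
    traveled_length_m = ifelse(success, eff * shortest, NA_real_),
    shortest_length_m = shortest,
    stringsAsFactors = FALSE
  )
}

#' Noisy goal-directed walk on a maze graph
#'
#' At each node the walker takes a shortest-path-reducing neighbor with
#' probability `fidelity`, otherwise a uniformly random neighbor; the walk
#' ends at the goal or after `max_steps` steps (a failure, mirroring a
#' trial timeout).
#'
#' @param maze A `maze_graph`.
#' @param start,goal Node ids.
#' @param fidelity Probability of a greedy (distance-reducing) step, in
#'   \code{[0, 1]}.
#' @param max_steps Step budget (default 200).
#' @param seed Optional seed.
#' @return A list of class `trajectory`: `nodes` (id sequence),
#'   `total_length` (meters), `reached` (logical).
#' @export
simulate_walk <- function(maze, start, goal, fidelity = 1, max_steps = 200,
                          seed = NULL) {
  stopifnot(inherits(maze, "maze_graph"), fidelity >= 0, fidelity <= 1)
  check_node(maze, start); check_node(maze, goal)
  if (!is.null(seed)) set.seed(seed)
  dist_to_goal <- igraph::distances(maze$graph, to = goal,
                                    weights = igraph::E(maze$graph)$length)[, 1]
  nbrs <- lapply(igraph::adjacent_vertices(maze$graph,
                                           igraph::V(maze$graph)), names)
  names(nbrs) <- igraph::V(maze$graph)$name
  key <- function(u, v) paste(pmin(u, v), pmax(u, v))
  elen <- stats::setNames(maze$edges$length, key(maze$edges$from, maze$edges$to))
  path <- start
  cur <- start
  for (step in seq_len(max_steps)) {
    if (cur == goal) break
    nb <- nbrs[[cur]]
    # a greedy step minimizes edge length plus remaining distance, i.e.
    # stays on a shortest path
    greedy <- nb[which.min(elen[key(cur, nb)] + dist_to_goal[nb])]
    cur <- if (stats::runif(1) < fidelity) greedy else sample(nb, 1)
    path <- c(path, cur)
  }
  structure(list(nodes = path,
                 total_length = route_length(maze, path),
                 reached = cur == goal),
            class = "trajectory")
}

#' Deterministic fixture maze
#'
#' A square grid maze with 12 landmarks in "alcoves" along the perimeter
#' and a closed perimeter loop as the learned route, so along-route travel
#' between landmarks is typically much longer than the interior shortcut.
#'
#' @param side Grid side (default 4, i.e. 16 nodes; the perimeter then has
#'   exactly 12 nodes, one per landmark).
#' @param extent Physical side length in meters (default 11).
#' @return A `maze_graph`.
#' @export
fixture_maze <- function(side = 4, extent = 11) {
  stopifnot(side >= 3)
  s <- extent / (side - 1)
  ids <- outer(seq_len(side) - 1, seq_len(side) - 1,
               function(r, c) sprintf("n%d_%d", r, c))
  nodes <- list()
  for (r in 0:(side - 1)) for (c in 0:(side - 1)) {
    nodes[[sprintf("n%d_%d", r, c)]] <- c(c * s, r * s)
  }
  edges <- list()
  for (r in 0:(side - 1)) for (c in 0:(side - 1)) {
    if (c < side - 1) edges[[length(edges) + 1]] <-
        c(sprintf("n%d_%d", r, c), sprintf("n%d_%d", r, c + 1))
    if (r < side - 1) edges[[length(edges) + 1]] <-
        c(sprintf("n%d_%d", r, c), sprintf("n%d_%d", r + 1, c))
  }
  # perimeter loop, counter-clockwise from the origin corner
  per <- c(sprintf("n0_%d", 0:(side - 1)),
           sprintf("n%d_%d", 1:(side - 1), side - 1),
           sprintf("n%d_%d", side - 1, (side - 2):0),
           sprintf("n%d_%d", (side - 2):1, 0))
  landmarks <- stats::setNames(per[seq_len(min(12, length(per)))],
                               sprintf("L%02d", seq_len(min(12, length(per)))))
  build_maze(list(nodes = nodes, edges = edges, landmarks = landmarks,
                  learned_route = c(per, per[1])))
}

# Landmark pairs whose learned-route detour is large enough to leave room
# for genuine shortcuts (along-route / shortest >= min_ratio).
shortcut_pairs <- function(maze, n_pairs, min_ratio = 1.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lms <- names(maze$landmarks)
  cand <- expand.grid(start_landmark = lms, target_landmark = lms,
                      stringsAsFactors = FALSE)
  cand <- cand[cand$start_landmark != cand$target_landmark, ]
  cand$shortest <- mapply(function(a, b) {
    shortest_path_length(maze, maze$landmarks[[a]], maze$landmarks[[b]])
  }, cand$start_landmark, cand$target_landmark)
  cand$along <- mapply(function(a, b) along_route_length(maze, a, b),
                       cand$start_landmark, cand$target_landmark)
  cand <- cand[cand$along / cand$shortest >= min_ratio, ]
  if (nrow(cand) < n_pairs) {
    stop("maze offers only ", nrow(cand), " pairs with ratio >= ", min_ratio,
         call. = FALSE)
  }
  cand[sample.int(nrow(cand), n_pairs), c("start_landmark", "target_landmark",
                                          "shortest")]
}

#' Generate a complete synthetic study
#'
#' Draws a latent cohort, builds the fixture maze, selects shortcutting
#' landmark pairs with real shortest-path denominators, and simulates both
#' pointing phases and the shortcutting task. Pointing pairs reuse the
#' shortcutting pairs (reversed) plus extra pairs when the pointing task
#' has more trials.
#'
#' @param config A `sim_config` (see [sim_preset()]).
#' @return A list of class `study_bundle`: `pointing_I`, `pointing_II`,
#'   `shortcut` (trial tables), `maze`, `cohort`, `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_high + config$n_low <= 0) stop("empty cohort", call. = FALSE)
  maze <- fixture_maze()
  sp <- shortcut_pairs(maze, config$n_shortcut_trials,
                       seed = substream_seed(config$seed, "pairs"))
  cohort <- generate_cohort(config)

  kp <- config$n_pointing_trials
  ppairs <- data.frame(start_landmark = sp$target_landmark,
                       target_landmark = sp$start_landmark)
  if (kp > nrow(ppairs)) {
    extra <- shortcut_pairs(maze, kp - nrow(ppairs), min_ratio = 1,
                            seed = substream_seed(config$seed, "pairs") + 1L)
    ppairs <- rbind(ppairs, extra[c("start_landmark", "target_landmark")])
  } else {
    ppairs <- ppairs[seq_len(kp), ]
  }

  structure(list(
    pointing_I = generate_pointing_trials(cohort, config, "I", ppairs),
    pointing_II = generate_pointing_trials(cohort, config, "II", ppairs),
    shortcut = generate_shortcut_trials(cohort, config, sp$shortest,
                                        sp[c("start_landmark", "target_landmark")]),
    maze = maze, cohort = cohort, config = config
  ), class = "study_bundle")
}

#' Write a study bundle to disk
#'
#' Emits the pipeline's interchange files: `pointing_phase1.csv`,
#' `pointing_phase2.csv`, `shortcut.csv` and `maze.json`.
#'
#' @param bundle From [generate_study()].
#' @param dir Output directory (created if needed).
#' @return The four file paths, invisibly.
#' @export
write_study <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("pointing_phase1.csv", "pointing_phase2.csv",
                            "shortcut.csv", "maze.json"))
  utils::write.csv(bundle$pointing_I, paths[1], row.names = FALSE)
  utils::write.csv(bundle$pointing_II, paths[2], row.names = FALSE)
  utils::write.csv(bundle$shortcut, paths[3], row.names = FALSE)
  write_maze(bundle$maze, paths[4])
  invisible(paths)
}

#' Trial matrix with an engineered reliability
#'
#' Linear-Gaussian trial model `X_ij = theta_i + e_ij` whose k-trial mean
#' has reliability exactly `reliability`: the noise SD is set to
#' `between_sd * sqrt(k (1 - R) / R)`. Used to study attenuation and
#' split-half recovery against analytic ground truth.
#'
#' @param n Participants (ignored when `theta` is given).
#' @param k Trials.
#' @param reliability Target reliability of the k-trial mean, in (0, 1).
#' @param theta Optional latent trait vector (unit-variance scale assumed
#'   unless `between_sd` says otherwise).
#' @param between_sd Between-person SD of the latent trait.
#' @param seed Optional seed.
#' @return An n x k numeric matrix with participant rownames.
#' @export
generate_trial_matrix <- function(n, k, reliability, theta = NULL,
                                  between_sd = 1, seed = NULL) {
  stopifnot(reliability > 0, reliability < 1, k >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(theta)) theta <- stats::rnorm(n, 0, between_sd)
  n <- length(theta)
  noise_sd <- between_sd * sqrt(k * (1 - reliability) / reliability)
  m <- matrix(theta, n, k) + matrix(stats::rnorm(n * k, 0, noise_sd), n, k)
  rownames(m) <- sprintf("P%03d", seq_len(n))
  m
}
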