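test_that("latent cohorts honor the configured correlation structure", {
  cfg <- sim_config(n_high = 5000, n_low = 0, rho = 0.75, seed = 17)
  co <- generate_cohort(cfg)
  expect_lt(abs(cor(co$ability_pointing, co$ability_shortcut) - 0.75), 0.03)

  cfg1 <- sim_config(n_high = 200, n_low = 0, rho = 1, seed = 2)
  co1 <- generate_cohort(cfg1)
  z1 <- scale(co1$ability_pointing); z2 <- scale(co1$ability_shortcut)
  expect_equal(as.numeric(z1), as.numeric(z2), tolerance = 1e-9)

  expect_identical(generate_cohort(cfg1), generate_cohort(cfg1))
})

test_that("pure guessing produces chance-level pointing", {
  cfg <- sim_config(n_high = 30, n_low = 0, n_pointing_trials = 200,
                    guess_intercept = 30, guess_slope = 0, seed = 5)
  co <- generate_cohort(cfg)
  pt <- generate_pointing_trials(co, cfg, "I")
  err <- absolute_angular_error(pt$response_bearing_deg, pt$true_bearing_deg)
  by_p <- tapply(err, pt$participant_id, mean)
  se <- sd(err) / sqrt(length(err))
  expect_lt(abs(mean(by_p) - 90), 3 * se * sqrt(length(by_p)))
  expect_lt(abs(mean(err) - 90), 3 * se)
})

test_that("infinite concentration without guessing gives zero error", {
  cfg <- sim_config(n_high = 10, n_low = 0, n_pointing_trials = 20,
                    guess_intercept = -30, guess_slope = 0,
                    conc_intercept = 30, conc_gain = 0,
                    pointing_difficulty = rep(0, 20), seed = 6)
  pt <- generate_pointing_trials(generate_cohort(cfg), cfg, "I")
  err <- absolute_angular_error(pt$response_bearing_deg, pt$true_bearing_deg)
  expect_lt(max(err), 1e-4)
})

test_that("shortcutting saturates at its floor and ceiling limits", {
  base <- list(n_high = 15, n_low = 0, n_shortcut_trials = 20, seed = 7)
  # very able: always succeed, always perfectly efficient
  cfg_hi <- do.call(sim_config, c(base, list(
    ability_mean_high = c(0, 30), success_slope = 1, ceiling_slope = 1)))
  sc_hi <- generate_shortcut_trials(generate_cohort(cfg_hi), cfg_hi)
  expect_true(all(sc_hi$success))
  expect_equal(sc_hi$traveled_length_m / sc_hi$shortest_length_m,
               rep(1, nrow(sc_hi)))
  # very unable: all failures; imputation then yields the learned-route value
  cfg_lo <- do.call(sim_config, c(base, list(ability_mean_high = c(0, -30))))
  sc_lo <- generate_shortcut_trials(generate_cohort(cfg_lo), cfg_lo)
  expect_true(!any(sc_lo$success))
  imp <- impute_failed(sc_lo, cfg_lo$learned_route_eff)
  expect_equal(unique(imp$efficiency), cfg_lo$learned_route_eff)
})

test_that("a heavy efficiency ceiling depresses split-half reliability", {
  # same latent variance, with vs without a large exact-1 point mass
  base <- list(n_high = 120, n_low = 0, n_shortcut_trials = 24,
               success_intercept = 30, ability_sd_high = c(0.6, 0.6),
               seed = 8)
  cfg_ceiling <- do.call(sim_config, c(base, list(
    ceiling_intercept = 1.4, ceiling_slope = 0)))   # ~80% exact-1 trials
  cfg_open <- do.call(sim_config, c(base, list(
    ceiling_intercept = -30, ceiling_slope = 0)))   # no point mass
  rel_of <- function(cfg) {
    sc <- generate_shortcut_trials(generate_cohort(cfg), cfg)
    m <- trial_matrix(impute_failed(sc, cfg$learned_route_eff), "efficiency")
    permutation_split_half(m, 300, seed = 1)$estimate
  }
  ceiling_share <- function(cfg) {
    sc <- generate_shortcut_trials(generate_cohort(cfg), cfg)
    mean(sc$traveled_length_m / sc$shortest_length_m == 1)
  }
  expect_gt(ceiling_share(cfg_ceiling), 0.7)
  expect_lt(rel_of(cfg_ceiling), rel_of(cfg_open))
})

test_that("simulated walks are shortest at full fidelity and reproducible", {
  m <- fixture_maze()
  w <- simulate_walk(m, "n0_0", "n3_3", fidelity = 1, seed = 1)
  expect_true(w$reached)
  expect_equal(w$total_length, shortest_path_length(m, "n0_0", "n3_3"))
  w2 <- simulate_walk(m, "n0_0", "n3_3", fidelity = 0.4, seed = 9)
  w3 <- simulate_walk(m, "n0_0", "n3_3", fidelity = 0.4, seed = 9)
  expect_identical(w2$nodes, w3$nodes)
})

test_that("zero-fidelity walks on a path graph are longer than the shortest path", {
  path5 <- build_maze(list(
    nodes = setNames(lapply(0:4, function(i) c(i, 0)), paste0("n", 0:4)),
    edges = lapply(1:4, function(i) c(paste0("n", i - 1), paste0("n", i))),
    landmarks = list(), learned_route = paste0("n", 0:4)
  ))
  set.seed(10)
  lens <- replicate(200, {
    w <- simulate_walk(path5, "n0", "n4", fidelity = 0, max_steps = 400)
    if (w$reached) w$total_length else NA
  })
  lens <- lens[is.finite(lens)]
  expect_gt(mean(lens), shortest_path_length(path5, "n0", "n4"))
  expect_gt(mean(lens > 4), 0.5)  # efficiency > 1 with high probability
})

test_that("generated trials satisfy all downstream type invariants", {
  cfg <- sim_preset("desktop-like", seed = 11)
  b <- generate_study(cfg)
  for (pt in list(b$pointing_I, b$pointing_II)) {
    expect_true(all(pt$response_bearing_deg >= 0 & pt$response_bearing_deg < 360))
    expect_true(all(pt$true_bearing_deg >= 0 & pt$true_bearing_deg < 360))
    err <- absolute_angular_error(pt$response_bearing_deg, pt$true_bearing_deg)
    expect_true(all(err >= 0 & err <= 180))
  }
  expect_type(b$shortcut$success, "logical")
  eff <- impute_failed(b$shortcut, cfg$learned_route_eff)
  expect_true(all(eff$efficiency >= 1 - 1e-9))
  expect_true(all(eff$efficiency <= cfg$learned_route_eff + 1e-9))
  # shortest lengths come from real maze geometry
  expect_true(all(b$shortcut$shortest_length_m > 0))
})

test_that("study bundles are reproducible by seed and differ across seeds", {
  cfg <- sim_preset("desktop-like", seed = 12)
  b1 <- generate_study(cfg)
  b2 <- generate_study(sim_preset("desktop-like", seed = 12))
  expect_identical(b1$pointing_I, b2$pointing_I)
  expect_identical(b1$shortcut, b2$shortcut)
  b3 <- generate_study(sim_preset("desktop-like", seed = 13))
  expect_identical(names(b3$pointing_I), names(b1$pointing_I))
  expect_false(identical(b3$pointing_I$response_bearing_deg,
                         b1$pointing_I$response_bearing_deg))
  expect_error(generate_study(sim_config(n_high = 0, n_low = 0)),
               "n_high")
})

test_that("written studies re-read into validated trial tables", {
  cfg <- sim_config(n_high = 6, n_low = 6, seed = 14)
  b <- generate_study(cfg)
  dir <- withr::local_tempdir()
  paths <- write_study(b, dir)
  expect_equal(read_pointing_trials(file.path(dir, "pointing_phase1.csv")),
               b$pointing_I, tolerance = 1e-12)
  expect_equal(read_shortcut_trials(file.path(dir, "shortcut.csv")),
               b$shortcut, tolerance = 1e-12)
  m <- build_maze(file.path(dir, "maze.json"))
  expect_equal(m$edges, b$maze$edges)
})

test_that("engineered trial matrices hit their target reliability analytically", {
  # split-half estimate of the engineered matrix matches the target, and the
  # empirical variance decomposition matches the design
  set.seed(15)
  R <- 0.7; k <- 12; n <- 4000
  theta <- rnorm(n)
  m <- generate_trial_matrix(n, k, R, theta = theta)
  noise_var <- mean(apply(m - theta, 1, var))
  expect_lt(abs(noise_var - k * (1 - R) / R), 0.5)
  est <- permutation_split_half(m, 100, seed = 1)$estimate
  expect_lt(abs(est - R), 0.03)
})
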