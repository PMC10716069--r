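test_that("absolute angular error takes the shortest arc", {
  expect_equal(absolute_angular_error(90, 90), 0)
  expect_equal(absolute_angular_error(350, 10), 20)
  expect_equal(absolute_angular_error(0, 180), 180)
})

test_that("angular error is symmetric and invariant to full turns", {
  set.seed(1)
  a <- runif(200, -720, 720); b <- runif(200, -720, 720)
  k <- sample(-3:3, 200, replace = TRUE)
  expect_equal(absolute_angular_error(a, b), absolute_angular_error(b, a))
  expect_equal(absolute_angular_error(a + 360 * k, b),
               absolute_angular_error(a, b))
  e <- absolute_angular_error(a, b)
  expect_true(all(e >= 0 & e <= 180))
})

test_that("true_bearing is clockwise from the facing direction", {
  expect_equal(true_bearing(c(0, 0), c(0, 1), c(0, 2)), 0)
  expect_equal(true_bearing(c(0, 0), c(0, 1), c(1, 0)), 90)
  expect_equal(true_bearing(c(0, 0), c(0, 1), c(-1, 0)), 270)
  expect_error(true_bearing(c(0, 0), c(0, 0), c(1, 0)), "facing point")
  expect_error(true_bearing(c(0, 0), c(0, 1), c(0, 0)), "target")
})

test_that("true_bearing agrees with a rotate-facing-to-north oracle", {
  set.seed(2)
  for (i in 1:50) {
    obs <- runif(2, -5, 5)
    fac <- obs + rnorm(2)
    tgt <- obs + rnorm(2)
    if (all(fac == obs) || all(tgt == obs)) next
    expect_equal(true_bearing(obs, fac, tgt),
                 rotation_bearing(obs, fac, tgt), tolerance = 1e-9)
  }
})

test_that("participants failing more than 30% of shortcut trials are removed", {
  ids <- sprintf("p%02d", 1:10)
  sc <- tiny_shortcut(ids, k = 10)
  # p01 fails 4/10 (removed, 0.4 > 0.3); p02 fails exactly 3/10 (retained)
  sc$success[sc$participant_id == "p01" & sc$trial_id %in%
               c("ST01", "ST02", "ST03", "ST04")] <- FALSE
  sc$success[sc$participant_id == "p02" & sc$trial_id %in%
               c("ST05", "ST06", "ST07")] <- FALSE
  sc$traveled_length_m[!sc$success] <- NA
  pt <- tiny_pointing(ids, k = 4)
  out <- apply_exclusions(pt, sc)
  expect_false("p01" %in% out$shortcut$participant_id)
  expect_false("p01" %in% out$pointing$participant_id)
  expect_true("p02" %in% out$shortcut$participant_id)
  expect_equal(out$log$id[out$log$type == "participant"], "p01")
  expect_equal(out$log$fail_fraction[out$log$type == "participant"], 0.4)
})

test_that("a trial failed by exactly 30% of remaining participants is excluded", {
  ids <- sprintf("p%02d", 1:10)
  sc <- tiny_shortcut(ids, k = 10)
  sc$success[sc$trial_id == "ST01" &
               sc$participant_id %in% c("p01", "p02", "p03")] <- FALSE
  sc$traveled_length_m[!sc$success] <- NA
  out <- apply_exclusions(tiny_pointing(ids), sc)
  expect_false("ST01" %in% out$shortcut$trial_id)
  expect_equal(out$log$fail_fraction[out$log$type == "trial"], 0.3)
})

test_that("exclusions are the identity on a failure-free dataset", {
  pt <- tiny_pointing(); sc <- tiny_shortcut()
  out <- apply_exclusions(pt, sc)
  expect_equal(out$pointing, pt)
  expect_equal(out$shortcut, sc)
  expect_equal(nrow(out$log), 0)
})

test_that("failed trials are imputed at the learned-route efficiency", {
  sc <- tiny_shortcut(k = 3)
  sc$success[1] <- FALSE
  sc$traveled_length_m[1] <- NA
  sc$traveled_length_m[2] <- 10; sc$shortest_length_m[2] <- 5
  out <- impute_failed(sc, 2.54)
  expect_equal(out$efficiency[1], 2.54)
  expect_equal(out$efficiency[2], 2)
  expect_true(out$imputed[1]); expect_false(out$imputed[2])

  all_ok <- tiny_shortcut(k = 5)
  out2 <- impute_failed(all_ok, 2.54)
  expect_equal(out2$efficiency,
               all_ok$traveled_length_m / all_ok$shortest_length_m)
  expect_error(impute_failed(all_ok, 0.9), "learned_route_eff > 1")
})

test_that("imputation never lowers a participant's mean efficiency", {
  set.seed(5)
  cfg <- sim_config(n_high = 8, n_low = 8, seed = 3)
  sc <- generate_shortcut_trials(generate_cohort(cfg), cfg)
  imp <- impute_failed(sc, cfg$learned_route_eff)
  with_imp <- tapply(imp$efficiency, imp$participant_id, mean)
  succ <- imp[imp$success, ]
  succ_only <- tapply(succ$efficiency, succ$participant_id, mean)
  common <- intersect(names(with_imp), names(succ_only))
  expect_true(all(with_imp[common] >= succ_only[common] - 1e-12))
})

test_that("participant scores are per-measure means, order-invariant", {
  pt <- tiny_pointing(ids = "p1", k = 3)
  pt$response_bearing_deg <- c(10, 20, 30)
  pt$true_bearing_deg <- 0
  sc <- tiny_shortcut(ids = "p1", k = 2)
  eff <- impute_failed(sc, 2.54)
  eff$efficiency <- 1
  s <- score_participants(pt, eff)
  expect_equal(s$pointing_error_I, 20)
  expect_equal(s$efficiency, 1)
  expect_equal(s$n_pointing_I, 3L)
  expect_true(is.na(s$pointing_error_II))

  shuffled <- score_participants(pt[sample.int(nrow(pt)), ], eff)
  expect_equal(shuffled, s)

  pt2 <- tiny_pointing(ids = c("p1", "p9"), k = 3)
  expect_warning(score_participants(pt2, eff), "only one measure")
})

test_that("uniform random responses score 90 degrees on average", {
  set.seed(8)
  n <- 10000
  pt <- data.frame(
    participant_id = "p1", phase = "I",
    trial_id = sprintf("T%05d", 1:n),
    start_landmark = "a", target_landmark = "b",
    response_bearing_deg = runif(n, 0, 360),
    true_bearing_deg = runif(n, 0, 360)
  )
  err <- absolute_angular_error(pt$response_bearing_deg, pt$true_bearing_deg)
  se <- sd(err) / sqrt(n)
  expect_lt(abs(mean(err) - 90), 3 * se)
  expect_lt(abs(mean(err) - 90), 1)
})

test_that("trial_matrix pivots long tables with missing cells as NA", {
  pt <- tiny_pointing(ids = c("p1", "p2"), k = 4)
  pt <- pt[-1, ]  # p1 misses trial 1
  m <- trial_matrix(pt, "pointing", phase = "I")
  expect_equal(dim(m), c(2, 4))
  expect_true(is.na(m["p1", "PT01"]))
  expect_false(anyNA(m["p2", ]))

  eff <- impute_failed(tiny_shortcut(), 2.54)
  me <- trial_matrix(eff, "efficiency")
  expect_equal(dim(me), c(2, 4))
  expect_false(anyNA(me))
})

test_that("matching-pairs restriction drops pointing trials without a shortcut twin", {
  pt <- tiny_pointing(ids = "p1", k = 4)
  pt$start_landmark <- c("L01", "L01", "L09", "L09")
  pt$target_landmark <- c("L02", "L03", "L10", "L02")
  sc <- tiny_shortcut(ids = "p1", k = 2)
  sc$start_landmark <- c("L02", "L03")  # reversed direction still matches
  sc$target_landmark <- c("L01", "L01")
  eff <- impute_failed(sc, 2.54)
  s <- score_participants(pt, eff, matching_pairs_only = TRUE)
  expect_equal(s$n_pointing_I, 2L)
})

test_that("trial tables survive a CSV round trip", {
  pt <- tiny_pointing(); sc <- tiny_shortcut()
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(pt, f1, row.names = FALSE)
  utils::write.csv(sc, f2, row.names = FALSE)
  expect_equal(read_pointing_trials(f1), pt)
  expect_equal(read_shortcut_trials(f2), sc)
  bad <- pt; names(bad)[2] <- "stage"
  f3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, f3, row.names = FALSE)
  expect_error(read_pointing_trials(f3), "phase")
})
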