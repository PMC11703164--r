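# synthetic cohort generator -------------------------------------------

quick_cfg <- function(...) {
  args <- list(n_syllables = 5, session_length = 30,
               n_animals_per_group = 2, seed = 7)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

test_that("velocity profile is log-spaced between its endpoints", {
  expect_equal(make_velocity_profile(quick_cfg(n_syllables = 2)), c(3, 17))
  v <- make_velocity_profile(quick_cfg(n_syllables = 21))
  expect_length(v, 21)
  expect_true(all(diff(v) > 0))
  expect_equal(v[c(1, 21)], c(3, 17))
  expect_equal(
    make_velocity_profile(quick_cfg(n_syllables = 4, v_min = 1, v_max = 8)),
    c(1, 2, 4, 8))
  expect_error(sim_config(n_syllables = 1), "n_syllables")
})

test_that("transition structure is row-stochastic, zero-diagonal, seeded", {
  cfg <- quick_cfg(n_syllables = 6)
  ts <- make_transition_structure(cfg)
  expect_equal(rowSums(ts$A), rep(1, 6), tolerance = 1e-12)
  expect_equal(diag(ts$A), rep(0, 6))
  expect_identical(ts, make_transition_structure(cfg))
  # infinite concentration: uniform over the other syllables
  tu <- make_transition_structure(quick_cfg(n_syllables = 3,
                                            transition_concentration = Inf))
  expect_equal(tu$A[1, ], c(0, 0.5, 0.5))
  expect_true(all(abs(tu$A[tu$A > 0] - 0.5) < 1e-12))
})

test_that("null group effect leaves the ground truth unchanged", {
  cfg <- quick_cfg(velocity_slope_beta = 0, usage_shift_delta = 0,
                   transition_damping = 1)
  ctl <- make_ground_truth(cfg)
  les <- apply_group_effect(ctl, cfg)
  expect_equal(les$speeds, ctl$speeds)
  expect_equal(les$A, ctl$A)
  expect_equal(les$dwell, ctl$dwell)
  expect_equal(les$usage, ctl$usage)
})

test_that("lesion velocity loss is exactly linear in control speed", {
  cfg <- quick_cfg(n_syllables = 12, velocity_slope_beta = 0.4)
  ctl <- make_ground_truth(cfg)
  les <- apply_group_effect(ctl, cfg)
  delta <- ctl$speeds - les$speeds
  fit <- lm(delta ~ ctl$speeds)
  expect_equal(unname(coef(fit)[2]), 0.4, tolerance = 1e-12)
  expect_equal(summary(fit)$r.squared, 1, tolerance = 1e-12)
  expect_true(all(les$speeds > 0))
})

test_that("usage shift moves expression toward the slow tercile", {
  cfg <- quick_cfg(n_syllables = 9, usage_shift_delta = 0.3,
                   velocity_slope_beta = 0, transition_damping = 1)
  ctl <- make_ground_truth(cfg)
  les <- apply_group_effect(ctl, cfg)
  terc <- syllable_terciles(ctl$speeds)
  expect_equal(sum(les$usage), 1, tolerance = 1e-12)
  expect_equal(rowSums(les$A), rep(1, 9), tolerance = 1e-12)
  expect_gt(sum(les$usage[terc == "slow"]), sum(ctl$usage[terc == "slow"]))
  expect_lt(sum(les$usage[terc == "fast"]), sum(ctl$usage[terc == "fast"]))
  expect_error(sim_config(usage_shift_delta = 1.2), "usage_shift_delta")
  expect_error(sim_config(velocity_slope_beta = 1), "velocity_slope_beta")
})

test_that("sessions are deterministic, in-arena, and noiseless speeds are exact", {
  cfg <- quick_cfg(step_noise_sigma = 0)
  truth <- make_ground_truth(cfg)
  s1 <- simulate_session(truth, cfg, animal_seed = 11)
  s2 <- simulate_session(truth, cfg, animal_seed = 11)
  expect_identical(s1, s2)
  expect_true(all(s1$x_cm >= 0 & s1$x_cm <= cfg$arena_side))
  expect_true(all(s1$y_cm >= 0 & s1$y_cm <= cfg$arena_side))
  expect_identical(s1$frame, seq_len(nrow(s1)) - 1L)
  v <- syllable_velocity(s1)
  expect_equal(as.numeric(v), truth$speeds[as.integer(names(v)) + 1],
               tolerance = 1e-12)
})

test_that("long-run frame usage matches dwell-weighted stationary usage", {
  cfg <- sim_config(n_syllables = 4, session_length = 2000, seed = 5,
                    n_animals_per_group = 1)
  truth <- make_ground_truth(cfg)
  s <- simulate_session(truth, cfg, animal_seed = 3)
  u <- syllable_usage(s)
  expect_equal(as.numeric(u), truth$usage, tolerance = 0.05)
})

test_that("keypoint simulation is rigid and template-faithful", {
  cfg <- quick_cfg(n_syllables = 3)
  truth <- make_ground_truth(cfg)
  s <- simulate_session(truth, cfg, animal_seed = 4)
  sk <- make_skeleton(3, K = 6)
  kp <- simulate_keypoints(s, sk, noise_sd = 0)
  xc <- grep("_x$", names(kp)[-1], value = TRUE)
  yc <- grep("_y$", names(kp)[-1], value = TRUE)
  # keypoint centroid equals the session centroid (templates are centered)
  expect_equal(rowMeans(as.matrix(kp[, xc])), s$x_cm, tolerance = 1e-10)
  expect_equal(rowMeans(as.matrix(kp[, yc])), s$y_cm, tolerance = 1e-10)
  # nose-centroid distance equals the template's nose radius, every frame
  r_template <- vapply(sk$templates, function(m) sqrt(sum(m[1, ]^2)),
                       numeric(1))
  r_obs <- sqrt((kp$kp1_x - s$x_cm)^2 + (kp$kp1_y - s$y_cm)^2)
  expect_equal(r_obs, r_template[s$syllable + 1], tolerance = 1e-10)
  # distinct syllables have distinct aligned poses
  al <- egocentric_align(kp)
  f1 <- which(s$syllable == 0)[1]; f2 <- which(s$syllable == 1)[1]
  expect_gt(max(abs(al$aligned[f1, ] - al$aligned[f2, ])), 0.01)
  expect_error(make_skeleton(3, K = 1), "at least 2 keypoints")
})

test_that("cohorts have per-group truths, distinct animals, and reproduce", {
  cfg <- quick_cfg(n_animals_per_group = 3)
  co <- simulate_cohort(cfg, treatment = TRUE)
  expect_length(co$sessions, 9)
  expect_length(unique(names(co$sessions)), 9)
  groups <- vapply(co$sessions, function(s) s$group[1], character(1))
  expect_equal(unname(table(groups)[c("control", "lesion", "lesion_ldopa")]),
               rep(3L, 3), ignore_attr = TRUE)
  # treated group: control speeds, lesion transitions/usage
  expect_equal(co$truth$lesion_ldopa$speeds, co$truth$control$speeds)
  expect_equal(co$truth$lesion_ldopa$A, co$truth$lesion$A)
  expect_equal(co$truth$lesion_ldopa$usage, co$truth$lesion$usage)
  co2 <- simulate_cohort(cfg, treatment = TRUE)
  expect_identical(serialize(co, NULL), serialize(co2, NULL))
})
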