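# transition matrices, steady state, entropy ---------------------------

test_that("transition estimation counts instance-level bigrams", {
  tm <- estimate_transition_matrix(c(0, 0, 1, 1, 0, 0, 2))
  expect_equal(tm$A[1, ], c(0, 0.5, 0.5), ignore_attr = TRUE)
  expect_equal(tm$A[2, ], c(1, 0, 0), ignore_attr = TRUE)
  expect_equal(tm$A[3, ], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(tm$absorbing, 2)
  # strict cycle gives the cyclic permutation matrix
  cyc <- estimate_transition_matrix(rep(c(0, 1, 2), 20))
  expect_equal(unname(cyc$A), rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)))
  expect_error(estimate_transition_matrix(rep(1, 5)), "2 syllable instances")
})

test_that("steady state matches hand and linear-solve oracles", {
  # doubly stochastic: uniform
  A <- matrix(1 / 3, 4, 4); diag(A) <- 0
  expect_equal(steady_state(A), rep(0.25, 4), tolerance = 1e-10)
  # 2x2 balance equation by hand: pi = (5/6, 1/6)
  A2 <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  expect_equal(steady_state(A2), c(5 / 6, 1 / 6), tolerance = 1e-10)
  # random chains against a direct linear solve
  set.seed(99)
  for (i in 1:25) {
    A6 <- random_chain(6)
    pi_pkg <- steady_state(A6)
    expect_equal(pi_pkg, solve_stationary(A6), tolerance = 1e-8)
    expect_lt(max(abs(pi_pkg %*% A6 - pi_pkg)), 1e-8)
  }
})

test_that("periodic and reducible chains are handled", {
  # period-2 chain: damped iteration still converges to (1/2, 1/2)
  P <- rbind(c(0, 1), c(1, 0))
  expect_equal(steady_state(P), c(0.5, 0.5), tolerance = 1e-10)
  # transient state 1 feeding a recurrent pair {2, 3}
  R <- rbind(c(0, 0.5, 0.5), c(0, 0, 1), c(0, 1, 0))
  pi_r <- steady_state(R)
  expect_equal(pi_r[1], 0)
  expect_equal(pi_r[2:3], c(0.5, 0.5), tolerance = 1e-10)
  expect_error(steady_state(matrix(0, 0, 0)), "empty")
})

test_that("entropy rate matches analytic values and the direct formula", {
  # deterministic cycle: no uncertainty
  cyc <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  expect_equal(entropy_rate(cyc)$H, 0)
  # uniform off-diagonal on 4 states: ln 3
  U <- matrix(1 / 3, 4, 4); diag(U) <- 0
  expect_equal(entropy_rate(U)$H, log(3), tolerance = 1e-12)
  expect_equal(entropy_rate(U)$row_entropy_sum, 4 * log(3),
               tolerance = 1e-12)
  expect_equal(entropy_rate(U, base = 2)$H, log2(3), tolerance = 1e-12)
  # random chain against brute-force summation with independent pi
  set.seed(123)
  A <- random_chain(3)
  pi_ind <- solve_stationary(A)
  H_brute <- 0
  for (i in 1:3) for (j in 1:3)
    if (A[i, j] > 0) H_brute <- H_brute - pi_ind[i] * A[i, j] * log(A[i, j])
  expect_equal(entropy_rate(A)$H, H_brute, tolerance = 1e-10)
})

test_that("transition frequency counts change-points per second", {
  expect_equal(transition_frequency(c(0, 0, 1, 1, 0, 0, 2), 30), 90 / 7)
  expect_equal(transition_frequency(rep(1, 50), 30), 0)
  expect_error(transition_frequency(1, 30), "2 frames")
  # renewal identity: frequency x duration = instances - 1, exactly
  set.seed(4)
  lab <- sample(0:3, 600, replace = TRUE)
  tf <- transition_frequency(lab, 30)
  expect_equal(tf * (length(lab) / 30), nrow(run_length_encode(lab)) - 1)
})

test_that("per-animal models satisfy the stationarity and entropy bounds", {
  cfg <- sim_config(n_syllables = 6, session_length = 120,
                    n_animals_per_group = 2, seed = 31)
  co <- simulate_cohort(cfg)
  for (s in co$sessions) {
    m <- transition_model(s)
    Srec <- sum(m$pi > 0)
    expect_lt(max(abs(m$pi %*% m$A - m$pi)), 1e-8)
    expect_gte(m$H, 0)
    expect_lte(m$H, log(max(Srec - 1, 1)) + 1e-9)
    expect_equal(sum(m$pi), 1, tolerance = 1e-9)
  }
})

test_that("group-averaged matrices and difference graphs behave", {
  cfg <- sim_config(n_syllables = 5, session_length = 120,
                    n_animals_per_group = 2, seed = 17)
  co <- simulate_cohort(cfg)
  syl <- 0:4
  models <- lapply(co$sessions, transition_model, syllables = syl)
  gs <- group_transition_summary(models, "control", "lesion")
  expect_equal(unname(rowSums(gs$group_means$control)), rep(1, 5),
               tolerance = 1e-9)
  # entrywise mean of the two control animals
  ctl <- models[vapply(models, function(m) m$group, "") == "control"]
  expect_equal(gs$group_means$control, (ctl[[1]]$A + ctl[[2]]$A) / 2)
  # swapping groups negates the difference exactly
  gs_swap <- group_transition_summary(models, "lesion", "control")
  expect_equal(gs$delta, -gs_swap$delta)
  # identical animals: group mean equals each animal's matrix
  dup <- list(ctl[[1]], ctl[[1]])
  dup[[2]]$animal_id <- "copy"
  gs_id <- group_transition_summary(c(dup, models[3]), "control", "lesion")
  expect_equal(gs_id$group_means$control, ctl[[1]]$A)
})
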