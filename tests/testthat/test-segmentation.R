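# egocentric alignment, PCA, AR-HMM, decoding --------------------------

test_that("egocentric alignment is invariant to planar rigid motions", {
  set.seed(12)
  base <- data.frame(frame = 0:19)
  tpl <- cbind(runif(5, -1, 1), runif(5, -1, 1))
  for (k in 1:5) {
    base[[paste0("kp", k, "_x")]] <- rep(tpl[k, 1], 20)
    base[[paste0("kp", k, "_y")]] <- rep(tpl[k, 2], 20)
  }
  a0 <- egocentric_align(base, anterior = 1, posterior = 5)
  for (rep in 1:10) {
    th <- runif(1, -pi, pi); tx <- runif(2, -50, 50)
    moved <- base
    for (k in 1:5) {
      xr <- cos(th) * tpl[k, 1] - sin(th) * tpl[k, 2] + tx[1]
      yr <- sin(th) * tpl[k, 1] + cos(th) * tpl[k, 2] + tx[2]
      moved[[paste0("kp", k, "_x")]] <- rep(xr, 20)
      moved[[paste0("kp", k, "_y")]] <- rep(yr, 20)
    }
    a1 <- egocentric_align(moved, anterior = 1, posterior = 5)
    expect_equal(a1$aligned, a0$aligned, tolerance = 1e-10)
  }
})

test_that("aligned poses have zero centroid and +x anterior on the axis", {
  # symmetric template whose centroid lies on the body axis
  kp <- data.frame(frame = 0:4,
                   kp1_x = 10 + c(1, 2, 0, 1, 1), kp1_y = 5 + c(0, 1, 1, 0, 2),
                   kp2_x = 10 + c(0, 1, -1, 0, 0), kp2_y = 5 + c(1, 2, 1, 1, 3),
                   kp3_x = 10 + c(0, 1, -1, 0, 0), kp3_y = 5 - c(1, 0, -1, 1, 1),
                   kp4_x = 10 - c(1, 0, 2, 1, 1), kp4_y = 5 + c(0, 1, 1, 0, 2))
  al <- egocentric_align(kp, anterior = 1, posterior = 4)
  cx <- rowMeans(al$aligned[, c(1, 3, 5, 7)])
  cy <- rowMeans(al$aligned[, c(2, 4, 6, 8)])
  expect_equal(cx, rep(0, 5), tolerance = 1e-10)
  expect_equal(cy, rep(0, 5), tolerance = 1e-10)
  # posterior->anterior axis along +x
  expect_true(all(al$aligned[, 1] - al$aligned[, 7] > 0))
  expect_equal(al$aligned[, 2] - al$aligned[, 8], rep(0, 5),
               tolerance = 1e-10)
})

test_that("noise-free keypoints align back to their syllable template", {
  cfg <- sim_config(n_syllables = 3, session_length = 20,
                    n_animals_per_group = 1, seed = 9)
  s <- simulate_session(make_ground_truth(cfg), cfg, animal_seed = 2)
  sk <- make_skeleton(3, K = 6)
  kp <- simulate_keypoints(s, sk, noise_sd = 0)
  al <- egocentric_align(kp)
  for (syl in 0:2) {
    f <- which(s$syllable == syl)[1]
    pose <- matrix(al$aligned[f, ], ncol = 2, byrow = TRUE)
    expect_equal(pose, unname(sk$templates[[syl + 1]]), tolerance = 1e-8)
  }
})

test_that("PCA contract: rank, reconstruction, SVD oracle, sign rule", {
  set.seed(5)
  # data in an exact 2-plane embedded in 6 dims
  B <- matrix(rnorm(12), 6, 2)
  X2 <- matrix(rnorm(200), 100, 2) %*% t(B)
  ps <- fit_pca(X2, n_components = 5)
  expect_lt(sum(ps$explained_variance[3:5]), 1e-10)
  expect_true(all(diff(ps$explained_variance) <= 1e-12))
  expect_lte(sum(ps$explained_variance), 1 + 1e-12)
  # orthonormal loadings and full reconstruction
  expect_equal(unname(crossprod(ps$loadings)), diag(5), tolerance = 1e-8)
  X6 <- matrix(rnorm(60), 10, 6)
  ps6 <- fit_pca(X6, n_components = 6)
  recon <- ps6$scores %*% t(ps6$loadings) +
    matrix(ps6$center, 10, 6, byrow = TRUE)
  expect_equal(recon, X6, tolerance = 1e-8)
  # scores agree with a direct SVD up to the declared sign convention
  Xc <- scale(X6, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  sc_svd <- sv$u %*% diag(sv$d)
  for (d in 1:3) {
    j <- which.max(abs(sv$v[, d]))
    sgn <- sign(sv$v[j, d])
    expect_equal(ps6$scores[, d], sgn * sc_svd[, d], tolerance = 1e-8)
  }
  expect_error(fit_pca(X6[1:3, ], n_components = 5), "fewer frames")
})

test_that("single-regime data collapses onto one dominant state", {
  z <- rep(1, 500)
  X <- gen_ar_regimes(z, list(c(0, 0)), seed = 3)
  m <- fit_arhmm(X, kappa = 100, max_states = 6, n_iter = 40, seed = 5)
  lab <- decode_labels(m, X)
  expect_gte(max(table(lab)) / length(lab), 0.95)
})

test_that("three separated AR regimes are recovered above 90% accuracy", {
  z <- rep(rep(1:3, 10), each = 40)
  X <- gen_ar_regimes(z, list(c(-4, 0), c(4, 0), c(0, 5)), seed = 7)
  m <- fit_arhmm(X, kappa = 100, max_states = 8, n_iter = 60, seed = 11)
  expect_identical(m, fit_arhmm(X, kappa = 100, max_states = 8,
                                n_iter = 60, seed = 11))
  lab <- decode_labels(m, X)
  expect_identical(lab, decode_labels(m, X))
  mm <- match_labels(z, lab)
  expect_gte(mm$accuracy, 0.9)
  # likelihood trace improves in expectation over the run
  tr <- m$loglik_trace
  expect_true(all(is.finite(tr)))
  expect_gte(mean(tail(tr, 10)), mean(head(tr, 10)))
})

test_that("degenerate constant scores yield a single-state model", {
  X <- matrix(1.5, 100, 3)
  expect_warning(m <- fit_arhmm(X, kappa = 10, max_states = 5, n_iter = 5,
                                seed = 1), "degenerate")
  expect_equal(m$S, 1L)
  expect_equal(unique(decode_labels(m, X)), 0L)
})

test_that("Viterbi is optimal against brute-force path enumeration", {
  set.seed(21)
  z <- c(1, 1, 1, 2, 2, 1, 1, 2)
  X <- gen_ar_regimes(z, list(c(-2, 0), c(2, 0)), noise = 0.5, seed = 13)
  m <- fit_arhmm(X, kappa = 5, max_states = 2, n_iter = 30, seed = 3)
  vit <- decode_labels(m, X) + 1L
  lp_vit <- path_logprob(m, X, vit)
  # enumerate all 2^8 paths
  grid <- as.matrix(expand.grid(rep(list(1:2), length(z))))
  lp_all <- apply(grid, 1, function(p) path_logprob(m, X, p))
  expect_equal(lp_vit, max(lp_all), tolerance = 1e-8)
  expect_gte(lp_vit, path_logprob(m, X, z) - 1e-8)
})

test_that("label matching equals the exhaustive-permutation optimum", {
  expect_equal(match_labels(c(0, 1, 2, 1), c(0, 1, 2, 1))$accuracy, 1)
  expect_equal(match_labels(c(0, 0, 1, 1, 2, 2),
                            c(2, 2, 0, 0, 1, 1))$accuracy, 1)
  set.seed(6)
  for (rep in 1:10) {
    k <- sample(3:5, 1)
    tl <- sample(0:(k - 1), 40, replace = TRUE)
    pl <- sample(0:(k - 1), 40, replace = TRUE)
    expect_equal(match_labels(tl, pl)$accuracy,
                 brute_match_accuracy(tl, pl))
  }
  expect_error(match_labels(1:3, 1:4), "equal length")
})

test_that("kappa selection picks nearest-to-target, ties toward larger", {
  sk <- syllabr:::select_kappa
  expect_equal(sk(c(200, 390, 800), c(1, 2, 3), 400), 2)
  expect_equal(sk(c(300, 500), c(10, 100), 400), 2)      # tie -> larger
  expect_equal(sk(c(NA, 390, 800), c(1, 2, 3), 400), 2)  # NA never chosen
})

test_that("kappa scan output contract holds on a small fit", {
  z <- rep(rep(1:2, 8), each = 12)
  X <- gen_ar_regimes(z, list(c(-2, 0), c(2, 0)), noise = 0.8, seed = 2)
  ks <- kappa_scan(X, kappa_grid = c(10, 1e3), fps = 30, max_states = 4,
                   n_iter = 25, seed = 5)
  expect_true(ks$selected_kappa %in% ks$table$kappa)
  expect_true(all(ks$table$median_duration_ms > 0, na.rm = TRUE))
  ks2 <- kappa_scan(X, kappa_grid = c(10, 1e3), fps = 30, max_states = 4,
                    n_iter = 25, seed = 5)
  expect_identical(ks$table, ks2$table)
  expect_error(kappa_scan(X, numeric(0), fps = 30), "empty")
})
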