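#' Fit a reduced sticky AR(1) hidden Markov model by blocked Gibbs sampling
#'
#' The segmentation workhorse: pose-score dynamics are modeled as
#' `x_t | z_t = s ~ N(A_s x_{t-1} + b_s, Sigma_s)` with a frame-level
#' Markov state sequence whose transition rows carry extra "sticky" prior
#' mass `kappa` on the diagonal, inflating self-transitions and thereby
#' controlling syllable duration. Inference is blocked Gibbs: the state
#' sequence is sampled by forward-filter backward-sampling, the per-state
#' AR parameters by their matrix-normal-inverse-Wishart conjugate
#' posterior, and the transition rows by Dirichlet posteriors
#' `Dir(alpha / max_states + kappa e_i + counts_i)` (a weak-limit
#' truncation at `max_states` states). The last Gibbs sample is returned
#' as the model.
#'
#' @param scores a [fit_pca()] `pose_scores` object or a numeric T x D
#'   matrix of score trajectories.
#' @param kappa sticky self-transition prior mass (larger = longer
#'   syllables).
#' @param alpha transition Dirichlet concentration (default 5.7).
#' @param gamma top-level concentration of the truncated construction;
#'   retained as metadata (the reduced model spreads `alpha` uniformly).
#' @param max_states weak-limit truncation level S (default 100).
#' @param n_iter Gibbs iterations (the last sample is the model).
#' @param seed RNG seed; identical seeds give identical models.
#' @return An `arhmm` object: per-state `A`, `b`, `Sigma`, frame-level
#'   transition matrix `P`, hyperparameters, `loglik_trace` (observed-data
#'   log-likelihood per iteration), final state sample `z` (1-based) and
#'   `active_states`.
#' @export
fit_arhmm <- function(scores, kappa, alpha = 5.7, gamma = 1e3,
                      max_states = 100, n_iter = 200, seed = 1) {
  X <- as_score_matrix(scores)
  if (!all(is.finite(X))) stop("scores must be finite", call. = FALSE)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  Tn <- nrow(X); D <- ncol(X)
  if (Tn < 3) stop("need at least 3 frames", call. = FALSE)
  if (all(apply(X, 2, var) < 1e-12)) {
    warning("degenerate (constant) scores: returning a single-state model")
    return(single_state_model(X, kappa, alpha, gamma, seed))
  }
  S <- as.integer(max_states)
  set.seed(seed)

  # priors: AR near identity (random-walk-like poses), residual scale from
  # one-step score increments
  M0 <- cbind(diag(D), 0)
  K0 <- diag(0.01, D + 1)
  nu0 <- D + 2
  Psi0 <- diag(pmax(apply(diff(X), 2, var), 1e-8), D)

  z <- init_states(X, S)
  Y <- X[-1, , drop = FALSE]
  Xl <- X[-Tn, , drop = FALSE]
  theta <- NULL
  P <- NULL
  loglik_trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    theta <- sample_ar_params(Y, Xl, z[-1], S, M0, K0, nu0, Psi0)
    P <- sample_transition_rows(z, S, alpha, kappa)
    ll <- emission_loglik(Y, Xl, theta)
    ffbs <- ffbs_sample(ll, P)
    z <- ffbs$z
    loglik_trace[it] <- ffbs$loglik
  }
  structure(list(D = D, S = S, A = theta$A, b = theta$b,
                 Sigma = theta$Sigma, P = P,
                 kappa = kappa, alpha = alpha, gamma = gamma,
                 max_states = S, n_iter = n_iter, seed = seed,
                 loglik_trace = loglik_trace, z = z,
                 active_states = sort(unique(z))),
            class = "arhmm")
}

as_score_matrix <- function(scores) {
  if (inherits(scores, "pose_scores")) return(scores$scores)
  as.matrix(scores)
}

single_state_model <- function(X, kappa, alpha, gamma, seed) {
  D <- ncol(X)
  structure(list(D = D, S = 1L, A = list(diag(D)),
                 b = list(numeric(D)), Sigma = list(diag(1e-8, D)),
                 P = matrix(1, 1, 1), kappa = kappa, alpha = alpha,
                 gamma = gamma, max_states = 1L, n_iter = 0L, seed = seed,
                 loglik_trace = numeric(0), z = rep(1L, nrow(X)),
                 active_states = 1L),
            class = "arhmm")
}

# initial state sequence: k-means on the scores when feasible, else random
init_states <- function(X, S) {
  Tn <- nrow(X)
  k <- min(S, max(2L, min(Tn %/% 10L, S)))
  centers_ok <- nrow(unique(X)) >= k
  if (centers_ok) {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers = k, iter.max = 20,
                                     nstart = 1)),
      error = function(e) NULL)
    if (!is.null(km)) return(as.integer(km$cluster))
  }
  sample.int(S, Tn, replace = TRUE)
}

# conjugate MNIW update of (A_s, b_s, Sigma_s) for every state
sample_ar_params <- function(Y, Xl, zt, S, M0, K0, nu0, Psi0) {
  D <- ncol(Y)
  A <- vector("list", S); b <- vector("list", S)
  Sigma <- vector("list", S)
  M0K0 <- M0 %*% K0
  M0K0M0 <- M0K0 %*% t(M0)
  for (s in seq_len(S)) {
    idx <- which(zt == s)
    if (length(idx)) {
      Ds <- cbind(Xl[idx, , drop = FALSE], 1)
      Ys <- Y[idx, , drop = FALSE]
      Kn <- crossprod(Ds) + K0
      Mn <- (crossprod(Ys, Ds) + M0K0) %*% solve(Kn)
      Sn <- Psi0 + crossprod(Ys) + M0K0M0 - Mn %*% Kn %*% t(Mn)
      nun <- nu0 + length(idx)
    } else {
      Kn <- K0; Mn <- M0
      Sn <- Psi0 + M0K0M0 - M0 %*% K0 %*% t(M0)
      nun <- nu0
    }
    Sn <- (Sn + t(Sn)) / 2 + diag(1e-10, D)
    Sig <- sample_inv_wishart(nun, Sn)
    AB <- sample_matrix_normal(Mn, Sig, Kn)
    A[[s]] <- AB[, seq_len(D), drop = FALSE]
    b[[s]] <- AB[, D + 1]
    Sigma[[s]] <- Sig
  }
  list(A = A, b = b, Sigma = Sigma)
}

sample_inv_wishart <- function(nu, S) {
  W <- rWishart(1, df = nu, Sigma = solve(S))[, , 1]
  Sig <- solve(W)
  (Sig + t(Sig)) / 2
}

# MN(M, Sigma (row cov), Kn^{-1} (column cov)) draw
sample_matrix_normal <- function(M, Sigma, Kn) {
  D <- nrow(M); Q <- ncol(M)
  Z <- matrix(rnorm(D * Q), D, Q)
  Lu <- t(chol(Sigma))
  Lv <- t(chol(solve(Kn)))
  M + Lu %*% Z %*% t(Lv)
}

# Dirichlet posterior rows with sticky diagonal mass
sample_transition_rows <- function(z, S, alpha, kappa) {
  Tn <- length(z)
  cnt <- matrix(tabulate((z[-Tn] - 1L) * S + z[-1], S * S), S, S,
                byrow = TRUE)
  P <- matrix(0, S, S)
  for (i in seq_len(S)) {
    shape <- alpha / S + cnt[i, ]
    shape[i] <- shape[i] + kappa
    g <- rgamma(S, shape = shape, rate = 1)
    if (sum(g) == 0) g[i] <- 1
    P[i, ] <- g / sum(g)
  }
  P
}

# T x S log-likelihood of each frame's emission under each state
# (row 1 is zero: the first frame is conditioned on)
emission_loglik <- function(Y, Xl, theta) {
  S <- length(theta$A); D <- ncol(Y)
  ll <- matrix(0, nrow(Y) + 1, S)
  for (s in seq_len(S)) {
    E <- Y - Xl %*% t(theta$A[[s]]) -
      matrix(theta$b[[s]], nrow(Y), D, byrow = TRUE)
    R <- chol(theta$Sigma[[s]])
    logdet <- 2 * sum(log(diag(R)))
    V <- backsolve(R, t(E), transpose = TRUE)
    quad <- colSums(V^2)
    ll[-1, s] <- -0.5 * (D * log(2 * pi) + logdet + quad)
  }
  ll
}

# forward filter, backward sample; uniform initial distribution
ffbs_sample <- function(ll, P) {
  Tn <- nrow(ll); S <- ncol(ll)
  a <- matrix(0, Tn, S)
  a[1, ] <- 1 / S
  loglik <- 0
  for (t in 2:Tn) {
    m <- max(ll[t, ])
    av <- as.vector(a[t - 1, ] %*% P) * exp(ll[t, ] - m)
    nrm <- sum(av)
    a[t, ] <- av / nrm
    loglik <- loglik + log(nrm) + m
  }
  z <- integer(Tn)
  z[Tn] <- sample.int(S, 1, prob = a[Tn, ])
  for (t in (Tn - 1):1) {
    pr <- a[t, ] * P[, z[t + 1]]
    z[t] <- sample.int(S, 1, prob = pr)
  }
  list(z = z, loglik = loglik)
}

#' Decode the most probable syllable sequence
#'
#' Viterbi decoding of the AR-HMM: deterministic given the model, so
#' downstream statistics are exactly reproducible (a posterior sample
#' would not be).
#'
#' @param model an [fit_arhmm()] object.
#' @param scores the `pose_scores` (or matrix) to decode; its dimension
#'   must match the model's.
#' @return Integer vector of 0-based per-frame syllable labels.
#' @export
decode_labels <- function(model, scores) {
  stopifnot(inherits(model, "arhmm"))
  X <- as_score_matrix(scores)
  if (ncol(X) != model$D)
    stop("score dimension does not match the model", call. = FALSE)
  Tn <- nrow(X); S <- model$S
  if (S == 1L) return(rep(0L, Tn))
  ll <- emission_loglik(X[-1, , drop = FALSE], X[-Tn, , drop = FALSE],
                        list(A = model$A, b = model$b, Sigma = model$Sigma))
  lp <- log(model$P)
  delta <- rep(-log(S), S)
  psi <- matrix(0L, Tn, S)
  for (t in 2:Tn) {
    M <- delta + lp                       # M[r, s] = delta[r] + lp[r, s]
    best <- max.col(t(M), ties.method = "first")
    delta <- M[cbind(best, seq_len(S))] + ll[t, ]
    psi[t, ] <- best
  }
  z <- integer(Tn)
  z[Tn] <- which.max(delta)
  for (t in (Tn - 1):1) z[t] <- psi[t + 1, z[t + 1]]
  z - 1L
}

#' Kappa scan: model selection against a target syllable duration
#'
#' Fits one model per candidate `kappa`, decodes the training data, and
#' selects the kappa whose median decoded syllable duration is closest to
#' `target_duration_ms` (400 ms, ~12 frames at 30 fps, by default). Ties
#' are broken toward the larger kappa: longer, more stable syllables.
#'
#' @param scores `pose_scores` or score matrix.
#' @param kappa_grid candidate kappa values (non-empty).
#' @param fps frame rate used to convert decoded durations to ms.
#' @param target_duration_ms duration criterion.
#' @param alpha,gamma,max_states,n_iter,seed passed to [fit_arhmm()]
#'   (every candidate uses the same seed, so the scan is reproducible).
#' @return A `kappa_scan_result`: `table` (kappa, median/mean duration ms,
#'   final log-likelihood, degenerate flag), `selected_kappa`, the selected
#'   `model` and its decoded `labels`.
#' @export
kappa_scan <- function(scores, kappa_grid, fps,
                       target_duration_ms = 400,
                       alpha = 5.7, gamma = 1e3, max_states = 100,
                       n_iter = 100, seed = 1) {
  if (!length(kappa_grid)) stop("empty kappa grid", call. = FALSE)
  kappa_grid <- sort(kappa_grid)
  models <- vector("list", length(kappa_grid))
  tab <- data.frame(kappa = kappa_grid, median_duration_ms = NA_real_,
                    mean_duration_ms = NA_real_, loglik = NA_real_,
                    degenerate = FALSE)
  labels_all <- vector("list", length(kappa_grid))
  for (i in seq_along(kappa_grid)) {
    m <- fit_arhmm(scores, kappa = kappa_grid[i], alpha = alpha,
                   gamma = gamma, max_states = max_states,
                   n_iter = n_iter, seed = seed)
    lab <- decode_labels(m, scores)
    rle_df <- run_length_encode(lab)
    if (nrow(rle_df) < 2) {
      tab$degenerate[i] <- TRUE
    } else {
      tab$median_duration_ms[i] <- median(rle_df$length) * 1000 / fps
      tab$mean_duration_ms[i] <- mean(rle_df$length) * 1000 / fps
    }
    tab$loglik[i] <- if (length(m$loglik_trace))
      tail(m$loglik_trace, 1) else NA_real_
    models[[i]] <- m
    labels_all[[i]] <- lab
  }
  if (all(tab$degenerate)) {
    stop("kappa scan failed: every fit degenerate; per-kappa outcomes: ",
         paste(sprintf("kappa=%g degenerate", tab$kappa), collapse = "; "),
         call. = FALSE)
  }
  sel <- select_kappa(tab$median_duration_ms, tab$kappa,
                      target_duration_ms)
  structure(list(table = tab, selected_kappa = tab$kappa[sel],
                 target_duration_ms = target_duration_ms,
                 model = models[[sel]], labels = labels_all[[sel]]),
            class = "kappa_scan_result")
}

# selection rule: kappa whose median decoded duration is closest to the
# target; exact ties broken toward the larger kappa (longer, more stable
# syllables). NA medians (degenerate fits) are never selected.
select_kappa <- function(median_ms, kappa, target_ms) {
  ok <- which(!is.na(median_ms))
  dist <- abs(median_ms[ok] - target_ms)
  cand <- ok[dist <= min(dist) + 1e-9]
  cand[which.max(kappa[cand])]
}

#' @export
print.kappa_scan_result <- function(x, ...) {
  cat("kappa scan (target", x$target_duration_ms, "ms):\n")
  print(x$table, row.names = FALSE)
  cat("selected kappa:", x$selected_kappa, "\n")
  invisible(x)
}
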