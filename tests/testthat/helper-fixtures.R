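# shared fixtures and independent oracles ------------------------------

# a hand-built session: straight-line track with given per-frame step and
# label sequence, at 30 fps
toy_session <- function(steps, labels, fps = 30) {
  x <- cumsum(c(0, steps))
  labeled_session(frame = seq_along(x) - 1L, x = x, y = rep(0, length(x)),
                  syllable = labels, fps = fps, arena_side = NA_real_)
}

# random row-stochastic matrix with zero diagonal
random_chain <- function(n, zero_diag = TRUE) {
  A <- matrix(runif(n * n), n, n)
  if (zero_diag) diag(A) <- 0
  A / rowSums(A)
}

# stationary distribution by solving the linear balance equations directly
# (independent of the package's power iteration)
solve_stationary <- function(A) {
  n <- nrow(A)
  M <- rbind(t(A) - diag(n), rep(1, n))
  qr.solve(M, c(rep(0, n), 1))
}

# piecewise AR(1) series with known regime sequence; regimes differ in mean
gen_ar_regimes <- function(z, mus, rho = 0.6, noise = 0.15, seed = 1) {
  set.seed(seed)
  d <- length(mus[[1]])
  X <- matrix(0, length(z), d)
  x <- mus[[z[1]]]
  for (t in seq_along(z)) {
    mu <- mus[[z[t]]]
    x <- mu + rho * (x - mu) + rnorm(d, 0, noise)
    X[t, ] <- x
  }
  X
}

# exhaustive-permutation Kruskal-Wallis p: fraction of group-label
# arrangements with H >= observed (H from kruskal.test, an independent path)
perm_kw <- function(values, groups) {
  H_of <- function(g) unname(kruskal.test(values, factor(g))$statistic)
  obs <- H_of(groups)
  perms <- all_label_arrangements(groups)
  H_all <- apply(perms, 2, H_of)
  mean(H_all >= obs - 1e-12)
}

# exhaustive-permutation p for the absolute difference in pooled rank means
# between two of the groups (Dunn's contrast)
perm_rankdiff <- function(values, groups, a, b) {
  r <- rank(values)
  d_of <- function(g) abs(mean(r[g == a]) - mean(r[g == b]))
  obs <- d_of(groups)
  perms <- all_label_arrangements(groups)
  mean(apply(perms, 2, d_of) >= obs - 1e-12)
}

# all distinct arrangements of a multiset of labels (columns)
all_label_arrangements <- function(groups) {
  recurse <- function(remaining) {
    if (length(remaining) == 1) return(matrix(remaining, nrow = 1))
    out <- list()
    for (g in unique(remaining)) {
      rest <- remaining[-match(g, remaining)]
      out[[length(out) + 1]] <- rbind(g, recurse(rest))
    }
    do.call(cbind, out)
  }
  recurse(sort(as.character(groups)))
}

# exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to the two groups
perm_mwu <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  U_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  obs <- U_of(seq_len(n))
  combos <- utils::combn(length(pooled), n)
  U_all <- apply(combos, 2, U_of)
  mu <- n * length(b) / 2
  mean(abs(U_all - mu) >= abs(obs - mu) - 1e-12)
}

# brute-force best label matching accuracy over all permutations
brute_match_accuracy <- function(true_labels, predicted_labels) {
  tl <- factor(true_labels); pl <- factor(predicted_labels)
  conf <- table(pl, tl)
  n <- max(nrow(conf), ncol(conf))
  C <- matrix(0, n, n)
  C[seq_len(nrow(conf)), seq_len(ncol(conf))] <- conf
  perms <- gtools_permutations(n)
  best <- 0
  for (i in seq_len(nrow(perms)))
    best <- max(best, sum(C[cbind(seq_len(n), perms[i, ])]))
  best / length(true_labels)
}

gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1, sub))
    out <- rbind(out, block)
  }
  out
}

# log-probability of a full state path under an AR-HMM (uniform initial,
# emissions from frame 2 on) -- used as the Viterbi brute-force oracle
path_logprob <- function(model, X, z1) {  # z1: 1-based path
  Tn <- nrow(X); D <- ncol(X)
  lp <- log(1 / model$S)
  for (t in 2:Tn) {
    lp <- lp + log(model$P[z1[t - 1], z1[t]])
    mu <- as.vector(model$A[[z1[t]]] %*% X[t - 1, ]) + model$b[[z1[t]]]
    e <- X[t, ] - mu
    S <- model$Sigma[[z1[t]]]
    lp <- lp - 0.5 * (D * log(2 * pi) + determinant(S)$modulus +
                        sum(e * solve(S, e)))
  }
  as.numeric(lp)
}
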