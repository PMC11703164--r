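#' Egocentric alignment of a keypoint session
#'
#' Removes location and heading from each frame, leaving postural shape:
#' the keypoint centroid is translated to the origin and the pose rotated
#' so the posterior-to-anterior body axis points along +x. The removed
#' (centroid, heading) series is returned alongside. Frames whose anterior
#' and posterior keypoints coincide have no defined heading; they carry the
#' previous frame's heading and are flagged.
#'
#' @param kp a `keypoint_session` data frame (columns `kp{i}_x`,
#'   `kp{i}_y`) as produced by [simulate_keypoints()] or
#'   [read_keypoint_table()].
#' @param anterior,posterior keypoint indices defining the body axis
#'   (default: the session's stored skeleton metadata, else 1 and K).
#' @return List: `aligned` (T x 2K matrix, columns `kp{i}_x`, `kp{i}_y`),
#'   `centroid` (T x 2), `heading` (radians), `flagged` (frame indices with
#'   undefined heading).
#' @export
egocentric_align <- function(kp, anterior = NULL, posterior = NULL) {
  xc <- grep("^kp[0-9]+_x$", names(kp), value = TRUE)
  yc <- grep("^kp[0-9]+_y$", names(kp), value = TRUE)
  K <- length(xc)
  if (K < 2 || length(yc) != K)
    stop("keypoint session needs >= 2 kp{i}_x / kp{i}_y column pairs",
         call. = FALSE)
  if (is.null(anterior))
    anterior <- if (!is.null(attr(kp, "anterior"))) attr(kp, "anterior") else 1L
  if (is.null(posterior))
    posterior <- if (!is.null(attr(kp, "posterior"))) attr(kp, "posterior") else K
  if (anterior == posterior || anterior > K || posterior > K ||
      anterior < 1 || posterior < 1)
    stop("anterior and posterior must be distinct valid keypoint indices",
         call. = FALSE)
  X <- as.matrix(kp[, xc, drop = FALSE])
  Y <- as.matrix(kp[, yc, drop = FALSE])
  cx <- rowMeans(X); cy <- rowMeans(Y)
  ax <- X[, anterior] - X[, posterior]
  ay <- Y[, anterior] - Y[, posterior]
  degenerate <- (ax == 0 & ay == 0)
  heading <- atan2(ay, ax)
  if (any(degenerate)) {
    heading[degenerate] <- NA
    if (is.na(heading[1])) heading[1] <- 0
    for (t in which(is.na(heading))) heading[t] <- heading[t - 1]
  }
  ch <- cos(heading); sh <- sin(heading)
  relx <- X - cx; rely <- Y - cy
  aligned <- matrix(0, nrow(kp), 2 * K)
  colnames(aligned) <- as.vector(rbind(xc, yc))
  for (k in seq_len(K)) {
    aligned[, 2 * k - 1] <- ch * relx[, k] + sh * rely[, k]
    aligned[, 2 * k]     <- -sh * relx[, k] + ch * rely[, k]
  }
  list(aligned = aligned, centroid = cbind(x = cx, y = cy),
       heading = heading, flagged = which(degenerate))
}

#' Principal-component scores of aligned poses
#'
#' Centers the aligned pose matrix and projects it on the top
#' `n_components` loadings by singular value. The sign of each loading is
#' fixed by making its largest-magnitude entry positive, so scores are
#' byte-stable across runs and platforms.
#'
#' @param aligned T x P matrix of aligned poses (or the list returned by
#'   [egocentric_align()]).
#' @param n_components number of components to keep (default 5).
#' @return A `pose_scores` list: `scores` (T x D), `loadings` (P x D,
#'   orthonormal), `center`, `explained_variance` (fractions, kept
#'   components).
#' @export
fit_pca <- function(aligned, n_components = 5) {
  if (is.list(aligned) && !is.null(aligned$aligned))
    aligned <- aligned$aligned
  X <- as.matrix(aligned)
  if (!all(is.finite(X))) stop("aligned poses must be finite", call. = FALSE)
  if (nrow(X) < n_components)
    stop("fewer frames than components", call. = FALSE)
  if (ncol(X) < n_components)
    stop("fewer pose dimensions than components", call. = FALSE)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  D <- n_components
  load <- pc$rotation[, seq_len(D), drop = FALSE]
  scores <- pc$x[, seq_len(D), drop = FALSE]
  for (d in seq_len(D)) {                     # deterministic sign convention
    j <- which.max(abs(load[, d]))
    if (load[j, d] < 0) {
      load[, d] <- -load[, d]
      scores[, d] <- -scores[, d]
    }
  }
  total_var <- sum(pc$sdev^2)
  structure(list(scores = scores, loadings = load, center = pc$center,
                 explained_variance = pc$sdev[seq_len(D)]^2 / total_var),
            class = "pose_scores")
}

#' Optimal state matching and frame accuracy
#'
#' Evaluation helper: finds the one-to-one mapping between predicted and
#' true state labels maximizing frame agreement (an assignment problem on
#' the confusion matrix, solved with the Hungarian algorithm) and reports
#' the matched-frame accuracy.
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @return List: `accuracy` in [0, 1], `mapping` (named vector:
#'   predicted label -> true label), `confusion` matrix.
#' @export
match_labels <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop("label sequences must have equal length", call. = FALSE)
  tl <- factor(true_labels)
  pl <- factor(predicted_labels)
  conf <- table(pred = pl, true = tl)
  n <- max(nrow(conf), ncol(conf))
  C <- matrix(0, n, n)                        # pad square with zeros
  C[seq_len(nrow(conf)), seq_len(ncol(conf))] <- conf
  assign <- hungarian_max(C)
  matched <- sum(C[cbind(seq_len(n), assign)])
  mapping <- setNames(rep(NA_character_, nrow(conf)), rownames(conf))
  for (i in seq_len(nrow(conf))) {
    if (assign[i] <= ncol(conf)) mapping[i] <- colnames(conf)[assign[i]]
  }
  list(accuracy = matched / length(true_labels), mapping = mapping,
       confusion = conf)
}

# maximum-weight perfect matching on a square matrix: returns, for each
# row, the assigned column. Hungarian algorithm with row/column potentials
# and shortest augmenting paths (O(n^3)); written here because no
# linear-assignment solver ships with the stack.
hungarian_max <- function(W) {
  n <- nrow(W)
  C <- max(W) - W                             # minimize cost
  n1 <- n + 1                                 # virtual start column
  u <- numeric(n1); v <- numeric(n1)
  p <- integer(n1)                            # p[j]: row matched to col j (0 = none)
  way <- integer(n1)
  for (i in seq_len(n)) {
    p[n1] <- i
    j0 <- n1
    minv <- rep(Inf, n1)
    used <- rep(FALSE, n1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- C[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {                                  # augment along way[]
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n1) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0) assign[p[j]] <- j
  assign
}
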