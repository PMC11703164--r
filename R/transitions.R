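#' Run-length encode a label sequence
#'
#' Shared primitive for durations and transition counts: collapses a
#' per-frame label sequence into syllable instances.
#'
#' @param labels integer (or factor) label vector; `NA` not allowed.
#' @return Data frame with columns `syllable`, `start_frame` (0-based),
#'   `length` (frames); concatenating the instances reproduces the input.
#' @export
run_length_encode <- function(labels) {
  if (length(labels) == 0) stop("empty label sequence", call. = FALSE)
  if (anyNA(labels)) stop("labels contain NA", call. = FALSE)
  r <- rle(as.vector(labels))
  data.frame(syllable = r$values,
             start_frame = cumsum(c(0L, r$lengths[-length(r$lengths)])),
             length = r$lengths)
}

#' Estimate the syllable-level transition matrix of one animal
#'
#' Transitions are counted between consecutive *instances* of the
#' run-length-encoded sequence (zero diagonal), not between frames:
#' multi-frame dwell makes the frame-level diagonal pure stickiness with no
#' information about sequencing. Rows are normalized to probabilities;
#' syllables never exited in-sample keep a zero row and are flagged.
#'
#' @param labels per-frame integer labels.
#' @param syllables syllable id universe defining the matrix rows/columns
#'   (defaults to the sorted ids present).
#' @return A `transition_model` list: `syllables`, `A`, `counts`,
#'   `absorbing` (ids with no outgoing transitions in-sample).
#' @export
estimate_transition_matrix <- function(labels, syllables = NULL) {
  rle_df <- run_length_encode(labels)
  if (nrow(rle_df) < 2)
    stop("need at least 2 syllable instances to estimate transitions",
         call. = FALSE)
  if (is.null(syllables)) syllables <- sort(unique(rle_df$syllable))
  n <- length(syllables)
  idx <- match(rle_df$syllable, syllables)
  if (anyNA(idx)) stop("labels outside the given syllable set", call. = FALSE)
  counts <- matrix(0, n, n, dimnames = list(syllables, syllables))
  from <- idx[-length(idx)]
  to <- idx[-1]
  for (k in seq_along(from)) counts[from[k], to[k]] <- counts[from[k], to[k]] + 1
  rs <- rowSums(counts)
  A <- counts
  nz <- rs > 0
  A[nz, ] <- A[nz, , drop = FALSE] / rs[nz]
  structure(list(syllables = syllables, A = A, counts = counts,
                 absorbing = syllables[!nz]),
            class = "transition_model")
}

#' Steady-state distribution of a syllable chain
#'
#' Restricts the chain to its largest recurrent communicating class (states
#' outside it, including zero rows, get probability 0), then runs damped
#' power iteration `x <- (x + xA) / 2` — the iterate averaging makes the
#' scheme converge on periodic chains — until the stationarity residual
#' drops below `tol`.
#'
#' @param A row-stochastic matrix (zero rows allowed; they are excluded).
#' @param tol convergence threshold on the max-norm residual.
#' @param max_iter iteration cap.
#' @return Stationary probability vector over all states of `A`.
#' @export
steady_state <- function(A, tol = 1e-12, max_iter = 1e6) {
  if (is.null(dim(A)) || nrow(A) == 0)
    stop("empty transition matrix", call. = FALSE)
  n <- nrow(A)
  rec <- largest_recurrent_class(A)
  if (!length(rec)) stop("no recurrent class in transition matrix",
                         call. = FALSE)
  B <- A[rec, rec, drop = FALSE]
  B <- B / rowSums(B)
  x <- rep(1 / length(rec), length(rec))
  for (it in seq_len(max_iter)) {
    xn <- (x + as.vector(x %*% B)) / 2
    xn <- xn / sum(xn)
    if (max(abs(as.vector(xn %*% B) - xn)) < tol) { x <- xn; break }
    x <- xn
  }
  pi_full <- numeric(n)
  pi_full[rec] <- x
  pi_full
}

# indices of the largest recurrent (closed) strongly connected class;
# zero rows are dropped up front
largest_recurrent_class <- function(A) {
  n <- nrow(A)
  keep <- which(rowSums(A) > 0)
  if (!length(keep)) return(integer(0))
  B <- A[keep, keep, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix((B > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  closed <- logical(comp$no)
  for (cl in seq_len(comp$no)) {
    members <- which(comp$membership == cl)
    outside <- setdiff(seq_along(keep), members)
    closed[cl] <- !length(outside) ||
      all(B[members, outside, drop = FALSE] == 0)
  }
  if (!any(closed)) return(integer(0))
  sizes <- tabulate(comp$membership, comp$no)
  sizes[!closed] <- -1L
  best <- which.max(sizes)
  keep[comp$membership == best]
}

#' Entropy rate of a syllable chain
#'
#' The conventional non-negative entropy rate
#' `H = -sum_ij pi_i A_ij log A_ij` (with `0 log 0 = 0`), plus the
#' unweighted variant `row_entropy_sum = sum_i (-sum_j A_ij log A_ij)`,
#' the "sum of local entropies per syllable". Natural log by default.
#'
#' @param A row-stochastic transition matrix.
#' @param pi steady-state distribution (computed from `A` if missing).
#' @param base logarithm base (`exp(1)` for nats, 2 for bits).
#' @return List `H` (entropy rate) and `row_entropy_sum`.
#' @export
entropy_rate <- function(A, pi = NULL, base = exp(1)) {
  if (is.null(pi)) pi <- steady_state(A)
  L <- A
  L[A > 0] <- log(A[A > 0], base = base)
  L[A == 0] <- 0
  row_h <- -rowSums(A * L)
  list(H = sum(pi * row_h), row_entropy_sum = sum(row_h))
}

#' Syllable change-points per second
#'
#' @param labels per-frame labels.
#' @param fps frame rate.
#' @return Transitions per second: count of frames whose label differs from
#'   the previous frame, divided by session duration `n_frames / fps`.
#' @export
transition_frequency <- function(labels, fps) {
  if (length(labels) < 2)
    stop("need at least 2 frames for transition frequency", call. = FALSE)
  changes <- sum(labels[-1] != labels[-length(labels)])
  changes / (length(labels) / fps)
}

#' Full per-animal transition model
#'
#' Convenience wrapper combining [estimate_transition_matrix()],
#' [steady_state()], [entropy_rate()] and [transition_frequency()] for one
#' labeled session.
#'
#' @param session a [labeled_session()] with labels.
#' @param syllables common syllable universe (see
#'   [estimate_transition_matrix()]).
#' @param base log base for the entropy.
#' @return A `transition_model` with fields `A`, `pi`, `H`,
#'   `row_entropy_sum`, `transition_frequency`, `animal_id`, `group`.
#' @export
transition_model <- function(session, syllables = NULL, base = exp(1)) {
  labels <- session$syllable
  if (anyNA(labels)) stop("session has unlabeled frames", call. = FALSE)
  tm <- estimate_transition_matrix(labels, syllables)
  tm$pi <- steady_state(tm$A)
  ent <- entropy_rate(tm$A, tm$pi, base = base)
  tm$H <- ent$H
  tm$row_entropy_sum <- ent$row_entropy_sum
  tm$transition_frequency <- transition_frequency(labels,
                                                  session_fps(session))
  tm$animal_id <- session$animal_id[1]
  tm$group <- session$group[1]
  tm
}

#' Group-averaged transition matrices and their difference
#'
#' Averages per-animal transition matrices entrywise within each group and
#' forms the difference matrix `mean(group2) - mean(group1)` whose sign
#' pattern is the transition-difference graph (edges strengthened or
#' weakened in group2 relative to group1).
#'
#' @param models list of [transition_model()] objects sharing a syllable set.
#' @param group1,group2 group labels to contrast (default: first two levels
#'   encountered, in order).
#' @param display_threshold |delta| below which edges are suppressed in the
#'   edge list.
#' @return List: `group_means` (named list of matrices), `delta`
#'   (group2 - group1), `edges` (data frame from, to, delta, sign).
#' @export
group_transition_summary <- function(models, group1 = NULL, group2 = NULL,
                                     display_threshold = 0.005) {
  groups <- vapply(models, function(m) m$group, character(1))
  syl <- models[[1]]$syllables
  same <- vapply(models, function(m) identical(m$syllables, syl), logical(1))
  if (!all(same))
    stop("all models must share a common syllable set; re-estimate with ",
         "an explicit `syllables` universe", call. = FALSE)
  lv <- unique(groups)
  if (is.null(group1)) group1 <- lv[1]
  if (is.null(group2)) group2 <- lv[2]
  group_means <- lapply(split(models, groups), function(ms) {
    Reduce(`+`, lapply(ms, function(m) m$A)) / length(ms)
  })
  delta <- group_means[[group2]] - group_means[[group1]]
  idx <- which(abs(delta) >= display_threshold, arr.ind = TRUE)
  edges <- data.frame(from = syl[idx[, 1]], to = syl[idx[, 2]],
                      delta = delta[idx],
                      sign = ifelse(delta[idx] > 0, "up", "down"))
  edges <- edges[order(-abs(edges$delta)), , drop = FALSE]
  rownames(edges) <- NULL
  list(group_means = group_means, delta = delta, edges = edges,
       group1 = group1, group2 = group2,
       display_threshold = display_threshold)
}
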