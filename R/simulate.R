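#' Construct a labeled session table
#'
#' The central per-animal record: one row per frame with centroid position
#' (cm), the syllable label (0-based integer, `NA` when unlabeled), animal
#' id and group. Frame rate, arena side and (when generated) the heading
#' series travel as attributes.
#'
#' @param frame 0-based consecutive frame indices.
#' @param x,y centroid coordinates (cm).
#' @param syllable integer syllable labels (0-based) or `NA`.
#' @param animal_id,group identifying tokens.
#' @param fps frame rate.
#' @param arena_side arena side (cm), or `NA` if unknown.
#' @param heading optional per-frame heading (radians).
#' @param validate_frames error on non-consecutive frame indices
#'   (`FALSE` only for permissive readers that have already warned).
#' @return A `labeled_session` data frame.
#' @export
labeled_session <- function(frame, x, y, syllable = NA_integer_,
                            animal_id = "animal", group = "control",
                            fps = 30, arena_side = NA_real_,
                            heading = NULL, validate_frames = TRUE) {
  stopifnot(length(x) == length(frame), length(y) == length(frame))
  df <- data.frame(frame = as.integer(frame), x_cm = x, y_cm = y,
                   syllable = as.integer(syllable),
                   animal_id = animal_id, group = group,
                   stringsAsFactors = FALSE)
  if (validate_frames && any(diff(df$frame) != 1L))
    stop("frame indices must be consecutive", call. = FALSE)
  attr(df, "fps") <- fps
  attr(df, "arena_side") <- arena_side
  if (!is.null(heading)) attr(df, "heading") <- heading
  class(df) <- c("labeled_session", "data.frame")
  df
}

session_fps <- function(session) {
  fps <- attr(session, "fps")
  if (is.null(fps)) stop("session has no fps attribute", call. = FALSE)
  fps
}

#' Simulate one open-field session from a ground truth
#'
#' Forward model: the syllable sequence is an inter-syllable Markov chain
#' with geometric dwell times (memoryless, matching the HMM assumption);
#' each frame's step length is the syllable's per-frame displacement
#' `speed_s / fps` plus truncated Gaussian noise; the heading performs a
#' persistent random walk; positions are reflected at the arena walls with
#' the step magnitude preserved exactly (so noiseless sessions reproduce
#' the generating speeds to machine precision).
#'
#' @param truth a [make_ground_truth()] / [apply_group_effect()] object.
#' @param config a [sim_config()].
#' @param animal_seed integer seed for this animal's RNG stream.
#' @param animal_id,group identifying tokens (group defaults to the truth's).
#' @return A [labeled_session()] with `heading` attribute.
#' @export
simulate_session <- function(truth, config, animal_seed,
                             animal_id = "animal",
                             group = truth$group) {
  stopifnot(inherits(truth, "ground_truth"))
  validate_sim_config(config)
  n_frames <- round(config$session_length * config$fps)
  if (n_frames < 2)
    stop("invalid config: session must span at least 2 frames",
         call. = FALSE)
  set.seed(animal_seed)
  labels <- sample_label_sequence(truth$A, truth$dwell, n_frames)

  step_mean <- truth$speeds[labels[-1] + 1L] / config$fps
  step <- step_mean + rnorm(n_frames - 1, 0, config$step_noise_sigma)
  step[step < 0] <- 0
  turn <- rnorm(n_frames - 1, 0, config$turn_sigma)
  x0 <- runif(1, 0.25, 0.75) * config$arena_side
  y0 <- runif(1, 0.25, 0.75) * config$arena_side
  h0 <- runif(1, -pi, pi)
  w <- .bounded_walk(step, turn, x0, y0, h0, config$arena_side)

  labeled_session(frame = seq_len(n_frames) - 1L, x = w$x, y = w$y,
                  syllable = labels, animal_id = animal_id, group = group,
                  fps = config$fps, arena_side = config$arena_side,
                  heading = w$heading)
}

# instance-level Markov chain with geometric dwell; returns 0-based labels
sample_label_sequence <- function(A, dwell, n_frames) {
  n <- nrow(A)
  start_p <- steady_state(A)
  labels <- integer(n_frames)
  s <- sample.int(n, 1, prob = start_p)
  t <- 0L
  while (t < n_frames) {
    len <- rgeom(1, prob = 1 / dwell[s]) + 1L
    len <- min(len, n_frames - t)
    labels[(t + 1L):(t + len)] <- s - 1L
    t <- t + len
    if (t < n_frames) s <- sample.int(n, 1, prob = A[s, ])
  }
  labels
}

#' Per-syllable postural templates for keypoint simulation
#'
#' Builds a rigid K-point body template (anterior keypoint first, posterior
#' last, centroid at the origin, body axis along +x) and derives one
#' deterministic variant per syllable by stretching the body axis and
#' flexing the lateral keypoints, so different syllables have distinct
#' postures recoverable after egocentric alignment.
#'
#' @param n_syllables number of syllable templates.
#' @param K keypoints per frame (>= 2).
#' @param body_length nose-to-tail extent of the base template (cm).
#' @return A `skeleton_spec` list: `K`, `anterior`, `posterior`,
#'   `templates` (list of K x 2 matrices).
#' @export
make_skeleton <- function(n_syllables, K = 6, body_length = 2.4) {
  if (K < 2) stop("invalid skeleton: need at least 2 keypoints",
                  call. = FALSE)
  ax <- seq(body_length / 2, -body_length / 2, length.out = K)
  lat <- rep(c(0.35, -0.35), length.out = K)
  lat[c(1, K)] <- 0                       # nose and tail on the body axis
  base <- cbind(x = ax, y = lat)
  templates <- vector("list", n_syllables)
  for (s in seq_len(n_syllables)) {
    f <- if (n_syllables > 1) (s - 1) / (n_syllables - 1) else 0
    tpl <- base
    tpl[, 1] <- tpl[, 1] * (0.7 + 0.6 * f)           # axial stretch
    tpl[, 2] <- tpl[, 2] * (1.2 - 0.8 * f)           # lateral flex
    tpl <- sweep(tpl, 2, colMeans(tpl))              # centroid at origin
    templates[[s]] <- tpl
  }
  structure(list(K = as.integer(K), anterior = 1L, posterior = as.integer(K),
                 templates = templates),
            class = "skeleton_spec")
}

#' Simulate keypoints around a session's centroid track
#'
#' Places each frame's syllable template rigidly: rotated to the frame
#' heading, translated to the centroid, plus isotropic Gaussian noise. The
#' keypoint centroid equals the session centroid up to noise because
#' templates are centered.
#'
#' @param session a [labeled_session()] with syllable labels; its `heading`
#'   attribute is used when present, otherwise headings are derived from
#'   frame-to-frame displacement (zero-displacement frames carry the
#'   previous heading).
#' @param skeleton a [make_skeleton()] spec.
#' @param noise_sd isotropic keypoint noise SD (cm).
#' @param seed optional RNG seed for the noise.
#' @return A `keypoint_session` data frame with columns `frame`,
#'   `kp{i}_x`, `kp{i}_y`; fps/animal metadata as attributes.
#' @export
simulate_keypoints <- function(session, skeleton, noise_sd = 0,
                               seed = NULL) {
  stopifnot(inherits(skeleton, "skeleton_spec"))
  if (skeleton$K < 2)
    stop("invalid skeleton: need at least 2 keypoints", call. = FALSE)
  if (anyNA(session$syllable))
    stop("session must be fully labeled to simulate keypoints",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(session)
  h <- attr(session, "heading")
  if (is.null(h)) h <- derive_headings(session$x_cm, session$y_cm)
  ch <- cos(h); sh <- sin(h)
  s1 <- session$syllable + 1L
  K <- skeleton$K
  Tx <- t(vapply(skeleton$templates, function(m) m[, 1], numeric(K)))
  Ty <- t(vapply(skeleton$templates, function(m) m[, 2], numeric(K)))
  out <- data.frame(frame = session$frame)
  for (k in seq_len(K)) {
    tx <- Tx[s1, k]; ty <- Ty[s1, k]
    kx <- session$x_cm + ch * tx - sh * ty
    ky <- session$y_cm + sh * tx + ch * ty
    if (noise_sd > 0) {
      kx <- kx + rnorm(n, 0, noise_sd)
      ky <- ky + rnorm(n, 0, noise_sd)
    }
    out[[paste0("kp", k, "_x")]] <- kx
    out[[paste0("kp", k, "_y")]] <- ky
  }
  attr(out, "fps") <- session_fps(session)
  attr(out, "animal_id") <- session$animal_id[1]
  attr(out, "anterior") <- skeleton$anterior
  attr(out, "posterior") <- skeleton$posterior
  class(out) <- c("keypoint_session", "data.frame")
  out
}

# headings from displacements; zero-displacement frames carry the previous
# heading; the first frame takes the first defined heading
derive_headings <- function(x, y) {
  dx <- diff(x); dy <- diff(y)
  h <- atan2(dy, dx)
  moved <- (dx != 0 | dy != 0)
  if (!any(moved)) return(rep(0, length(x)))
  h[!moved] <- NA
  first <- which(moved)[1]
  h[seq_len(first - 1)] <- h[first]
  for (t in seq_along(h)) if (is.na(h[t])) h[t] <- h[t - 1]
  c(h[1], h)
}

#' Simulate a whole multi-group cohort
#'
#' Generates `n_animals_per_group` sessions for a control group, a lesion
#' group (via [apply_group_effect()]), and optionally a treated group whose
#' speeds are restored to control values while usage and transition
#' structure stay at lesion values (dopaminergic medication rescues
#' kinematics but not sequencing). Per-animal seeds are derived
#' deterministically from the master seed, so the whole cohort is
#' bit-identical across runs.
#'
#' @param config a [sim_config()].
#' @param treatment include the `lesion_ldopa` third group?
#' @return A `cohort` list: `sessions` (list of [labeled_session()]),
#'   `truth` (named list of `ground_truth` per group), `config`.
#' @export
simulate_cohort <- function(config, treatment = FALSE) {
  validate_sim_config(config)
  control <- make_ground_truth(config, group = "control")
  lesion <- apply_group_effect(control, config)
  truth <- list(control = control, lesion = lesion)
  if (treatment)
    truth$lesion_ldopa <- make_treatment_truth(control, lesion)
  sessions <- list()
  for (gi in seq_along(truth)) {
    g <- names(truth)[gi]
    for (a in seq_len(config$n_animals_per_group)) {
      id <- sprintf("%s_%02d", g, a)
      seed_a <- derive_animal_seed(config$seed, gi, a)
      sessions[[id]] <- simulate_session(truth[[g]], config, seed_a,
                                         animal_id = id, group = g)
    }
  }
  structure(list(sessions = sessions, truth = truth, config = config),
            class = "cohort")
}
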