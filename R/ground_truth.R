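#' Log-spaced per-syllable speed profile
#'
#' Builds the generating speed of each syllable as a geometric sequence from
#' `v_min` to `v_max`, so the repertoire spans freezing-like to run-like
#' speeds with proportionally finer resolution at the slow end (speeds, like
#' most kinematic quantities, are naturally compared on a ratio scale).
#'
#' @param config a [sim_config()].
#' @return Numeric vector of length `n_syllables`, strictly increasing from
#'   `v_min` to `v_max` (cm/s).
#' @export
make_velocity_profile <- function(config) {
  validate_sim_config(config)
  exp(seq(log(config$v_min), log(config$v_max),
          length.out = config$n_syllables))
}

#' Random inter-syllable transition structure and dwell means
#'
#' Draws each row of the syllable-level (instance-level) transition matrix
#' from a symmetric Dirichlet over the other syllables (zero diagonal:
#' consecutive instances differ by construction).  Per-syllable mean dwell
#' times are spaced evenly across `mean_duration_frames`, slower syllables
#' dwelling longer, so the expected frame-level duration matches the
#' sub-second syllable regime (~400-600 ms at 30 fps by default).
#'
#' @param config a [sim_config()].
#' @param seed RNG seed for the Dirichlet draws (defaults to `config$seed`).
#' @return List with `A` (row-stochastic matrix, zero diagonal) and
#'   `dwell` (mean dwell in frames per syllable).
#' @export
make_transition_structure <- function(config, seed = config$seed) {
  validate_sim_config(config)
  n <- config$n_syllables
  set.seed(seed)
  A <- matrix(0, n, n)
  conc <- config$transition_concentration
  for (i in seq_len(n)) {
    if (is.infinite(conc)) {
      w <- rep(1, n - 1)
    } else {
      w <- rgamma(n - 1, shape = conc, rate = 1)
      if (all(w == 0)) w <- rep(1, n - 1)
    }
    A[i, -i] <- w / sum(w)
  }
  rng <- range(config$mean_duration_frames)
  # slow syllables (low index in the speed-ordered profile) dwell longest:
  # freezing/pauses are the long motifs, runs the brisk ones
  dwell <- seq(rng[2], rng[1], length.out = n)
  list(A = A, dwell = dwell)
}

#' Assemble the control-group ground truth
#'
#' Combines the speed profile, transition structure and dwell means into a
#' `ground_truth` object carrying the expected frame-level usage (the
#' dwell-weighted stationary distribution of the instance chain).
#'
#' @param config a [sim_config()].
#' @param group group label stored on the object.
#' @return A `ground_truth` list: `speeds`, `A`, `dwell`, `usage`, `group`.
#' @export
make_ground_truth <- function(config, group = "control") {
  ts <- make_transition_structure(config)
  gt <- list(speeds = make_velocity_profile(config),
             A = ts$A, dwell = ts$dwell, group = group)
  gt$usage <- expected_usage(gt$A, gt$dwell)
  structure(gt, class = "ground_truth")
}

# frame-level expected usage: stationary distribution of the instance-level
# chain, weighted by mean dwell and renormalized
expected_usage <- function(A, dwell) {
  pi_inst <- steady_state(A)
  u <- pi_inst * dwell
  u / sum(u)
}

#' Derive the lesion-group ground truth from the control truth
#'
#' Applies the three dopamine-depletion effects to a control `ground_truth`:
#' \itemize{
#'   \item \strong{Velocity}: lesion speed is `v - beta * (v - v_min)`,
#'     i.e. a multiplicative loss `(1 - beta * w_s) * v` with weight
#'     `w_s = 1 - v_min / v_s` growing monotonically with speed rank, so
#'     faster syllables lose proportionally more and the
#'     delta-velocity-versus-control-velocity relation is exactly linear
#'     with slope `beta`.
#'   \item \strong{Usage}: a fraction `delta` of each row's transition mass
#'     into the fastest speed tercile is rerouted to the slowest tercile
#'     (proportionally to existing mass), shifting expression from run-like
#'     to pause-like syllables while keeping rows stochastic.
#'   \item \strong{Transitions}: dwell means are divided by
#'     `transition_damping`, lengthening syllables and lowering the
#'     change-point rate.
#' }
#'
#' @param truth control-group [make_ground_truth()] object.
#' @param config a [sim_config()] supplying `velocity_slope_beta`,
#'   `usage_shift_delta` and `transition_damping`.
#' @return A `ground_truth` object for the lesion group.
#' @export
apply_group_effect <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"))
  validate_sim_config(config)
  beta <- config$velocity_slope_beta
  delta <- config$usage_shift_delta
  damping <- config$transition_damping

  v <- truth$speeds
  w <- 1 - min(v) / v
  lesion <- truth
  lesion$group <- "lesion"
  lesion$speeds <- (1 - beta * w) * v

  n <- length(v)
  terc <- syllable_terciles(v)
  A <- truth$A
  if (delta > 0 && any(terc == "fast") && any(terc == "slow")) {
    for (i in seq_len(n)) {
      fast_j <- which(terc == "fast" & seq_len(n) != i)
      slow_j <- which(terc == "slow" & seq_len(n) != i)
      if (!length(fast_j) || !length(slow_j)) next
      moved <- delta * sum(A[i, fast_j])
      A[i, fast_j] <- A[i, fast_j] * (1 - delta)
      slow_mass <- sum(A[i, slow_j])
      if (slow_mass > 0) {
        A[i, slow_j] <- A[i, slow_j] * (1 + moved / slow_mass)
      } else {
        A[i, slow_j] <- moved / length(slow_j)
      }
      A[i, ] <- A[i, ] / sum(A[i, ])
    }
  }
  lesion$A <- A
  lesion$dwell <- truth$dwell / damping
  lesion$usage <- expected_usage(lesion$A, lesion$dwell)
  lesion
}

#' Speed terciles of the syllable repertoire
#'
#' @param speeds per-syllable mean speeds.
#' @return Factor with levels `slow`, `mid`, `fast` (ties split by rank).
#' @export
syllable_terciles <- function(speeds) {
  n <- length(speeds)
  r <- rank(speeds, ties.method = "first")
  cut(r, breaks = c(0, n / 3, 2 * n / 3, n),
      labels = c("slow", "mid", "fast"))
}

# third experimental arm: dopaminergic medication restores syllable speeds
# but leaves usage and transition structure at lesion values
make_treatment_truth <- function(control, lesion) {
  tr <- lesion
  tr$group <- "lesion_ldopa"
  tr$speeds <- control$speeds
  tr
}
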