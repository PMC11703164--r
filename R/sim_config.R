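#' Configuration for the synthetic open-field cohort generator
#'
#' Bundles every knob of the forward model: arena geometry, frame rate,
#' session length, the syllable speed profile, dwell-time means, transition
#' structure, and the lesion-group effects (proportional velocity loss,
#' usage shift from fast to slow syllables, damped transition rate).
#' Defaults emulate the study conditions of a dopamine-depletion open-field
#' experiment: a 40 x 40 cm arena filmed at 30 fps for 20 minutes, about 20
#' expressed syllables spanning freezing-like (~3 cm/s) to run-like
#' (~17 cm/s) speeds, and mean syllable dwell around 500 ms.
#'
#' @param n_syllables number of syllables in the repertoire.
#' @param fps frame rate (frames/second).
#' @param arena_side arena side length (cm).
#' @param session_length session duration (seconds).
#' @param n_animals_per_group animals simulated per experimental group.
#' @param v_min,v_max slowest/fastest syllable mean speed (cm/s).
#' @param mean_duration_frames length-2 range of per-syllable expected dwell
#'   (frames); syllable dwell means are spaced evenly across it. A single
#'   value gives every syllable the same mean dwell.
#' @param transition_concentration Dirichlet concentration of the
#'   inter-syllable transition rows; `Inf` gives uniform rows.
#' @param velocity_slope_beta proportional velocity loss in the lesion group;
#'   the lesion speed is `v - beta * (v - v_min)` so the delta-velocity
#'   versus control-velocity relation is linear with slope `beta`.
#' @param usage_shift_delta fraction of transition mass into the fastest
#'   speed tercile rerouted to the slowest tercile in the lesion group.
#' @param transition_damping factor in (0, 1] dividing into dwell means of
#'   the lesion group (0.8 lengthens dwells by 25%, reducing the syllable
#'   change-point rate accordingly).
#' @param step_noise_sigma per-frame step-length noise (cm).
#' @param turn_sigma per-frame heading increment SD (radians) of the
#'   persistent random walk.
#' @param seed master seed; identical seeds give bit-identical cohorts.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_syllables = 5, session_length = 10, seed = 1)
#' cfg$fps
sim_config <- function(n_syllables = 20,
                       fps = 30,
                       arena_side = 40,
                       session_length = 1200,
                       n_animals_per_group = 8,
                       v_min = 3,
                       v_max = 17,
                       mean_duration_frames = c(12, 18),
                       transition_concentration = 5,
                       velocity_slope_beta = 0.4,
                       usage_shift_delta = 0.3,
                       transition_damping = 0.8,
                       step_noise_sigma = 0.02,
                       turn_sigma = 0.35,
                       seed = 1L) {
  cfg <- list(
    n_syllables = as.integer(n_syllables), fps = fps,
    arena_side = arena_side, session_length = session_length,
    n_animals_per_group = as.integer(n_animals_per_group),
    v_min = v_min, v_max = v_max,
    mean_duration_frames = as.numeric(mean_duration_frames),
    transition_concentration = transition_concentration,
    velocity_slope_beta = velocity_slope_beta,
    usage_shift_delta = usage_shift_delta,
    transition_damping = transition_damping,
    step_noise_sigma = step_noise_sigma,
    turn_sigma = turn_sigma,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)
  if (is.na(cfg$n_syllables) || cfg$n_syllables < 2)
    stop_cfg("n_syllables must be >= 2")
  if (cfg$fps <= 0) stop_cfg("fps must be positive")
  if (cfg$arena_side <= 0) stop_cfg("arena_side must be positive")
  if (!(cfg$v_min > 0 && cfg$v_max > cfg$v_min))
    stop_cfg("need 0 < v_min < v_max")
  if (any(cfg$mean_duration_frames < 1))
    stop_cfg("mean_duration_frames must be >= 1")
  if (cfg$velocity_slope_beta < 0 || cfg$velocity_slope_beta >= 1)
    stop_cfg("velocity_slope_beta must be in [0, 1)")
  if (cfg$usage_shift_delta < 0 || cfg$usage_shift_delta > 1)
    stop_cfg("usage_shift_delta must be in [0, 1]")
  if (cfg$transition_damping <= 0 || cfg$transition_damping > 1)
    stop_cfg("transition_damping must be in (0, 1]")
  if (cfg$step_noise_sigma < 0) stop_cfg("step_noise_sigma must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_syllables, "syllables,",
      x$session_length, "s at", x$fps, "fps,",
      x$arena_side, "cm arena,",
      x$n_animals_per_group, "animals/group\n")
  cat("  speeds", x$v_min, "-", x$v_max, "cm/s; lesion beta =",
      x$velocity_slope_beta, ", delta =", x$usage_shift_delta,
      ", damping =", x$transition_damping, "; seed", x$seed, "\n")
  invisible(x)
}

# deterministic per-animal seed from (master seed, group index, animal index),
# kept below 2^31 - 1 so set.seed() accepts it
derive_animal_seed <- function(master_seed, group_index, animal_index) {
  m <- 2147483563
  s <- (as.double(master_seed) * 1000003 +
          as.double(group_index) * 99991 +
          as.double(animal_index) * 101) %% m
  as.integer(s) + 1L
}
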