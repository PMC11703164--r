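#' Per-syllable velocity of one session
#'
#' The velocity of syllable s is the mean frame-to-frame Euclidean
#' displacement over all frames assigned to s, times the frame rate. The
#' displacement at frame t is `||pos(t) - pos(t-1)||`, so the first frame
#' contributes nothing; frames with missing coordinates are skipped and
#' counted in the QC attribute rather than interpolated.
#'
#' @param session a [labeled_session()] with labels.
#' @return Named numeric vector (cm/s) indexed by syllable id, with a
#'   `qc` attribute listing skipped-frame counts.
#' @export
syllable_velocity <- function(session) {
  if (nrow(session) < 2)
    stop("need at least 2 frames", call. = FALSE)
  if (all(is.na(session$syllable)))
    stop("session has no syllable labels", call. = FALSE)
  disp <- frame_displacements(session)
  lab <- session$syllable[-1]                 # displacement into frame t
  ok <- !is.na(disp) & !is.na(lab)
  v <- tapply(disp[ok], lab[ok], mean) * session_fps(session)
  out <- as.numeric(v)
  names(out) <- names(v)
  attr(out, "qc") <- list(skipped_frames = sum(!ok))
  out
}

frame_displacements <- function(session) {
  dx <- diff(session$x_cm)
  dy <- diff(session$y_cm)
  sqrt(dx^2 + dy^2)
}

#' Session-average speed
#'
#' Conventional locomotor measure: total distance traveled divided by the
#' session duration in seconds (`n_frames / fps`).
#'
#' @param session a [labeled_session()].
#' @return Speed in cm/s.
#' @export
session_speed <- function(session) {
  if (nrow(session) < 2)
    stop("need at least 2 frames for session speed", call. = FALSE)
  disp <- frame_displacements(session)
  sum(disp, na.rm = TRUE) / (nrow(session) / session_fps(session))
}

#' Per-syllable usage (fraction of frames)
#'
#' Usage is time-weighted: frames assigned to a syllable divided by all
#' labeled frames, so usages sum to 1 within an animal.
#'
#' @param session a [labeled_session()] with labels.
#' @return Named numeric vector of frame fractions.
#' @export
syllable_usage <- function(session) {
  lab <- session$syllable[!is.na(session$syllable)]
  if (!length(lab)) stop("session has no labeled frames", call. = FALSE)
  tab <- table(lab)
  u <- as.numeric(tab) / length(lab)
  names(u) <- names(tab)
  u
}

#' Per-syllable mean duration and instance counts
#'
#' @param session a [labeled_session()] with labels.
#' @return Data frame: `syllable`, `mean_duration_ms`, `n_instances`;
#'   overall mean instance duration (ms) as attribute `overall_mean_ms`.
#' @export
syllable_durations <- function(session) {
  lab <- session$syllable
  if (all(is.na(lab))) stop("session has no syllable labels", call. = FALSE)
  rle_df <- run_length_encode(lab[!is.na(lab)])
  fps <- session_fps(session)
  mean_len <- tapply(rle_df$length, rle_df$syllable, mean)
  out <- data.frame(syllable = as.integer(names(mean_len)),
                    mean_duration_ms = as.numeric(mean_len) * 1000 / fps,
                    n_instances = as.integer(
                      tapply(rle_df$length, rle_df$syllable, length)))
  rownames(out) <- NULL
  attr(out, "overall_mean_ms") <- mean(rle_df$length) * 1000 / fps
  out
}

#' Per-animal x syllable statistics for a set of sessions
#'
#' One row per animal and syllable: velocity (cm/s), usage (fraction of
#' frames), instance-fraction usage, mean duration (ms), instance count.
#'
#' @param sessions list of [labeled_session()] objects (e.g.
#'   `simulate_cohort(cfg)$sessions`).
#' @return A `syllable_stats` data frame.
#' @export
syllable_stats <- function(sessions) {
  rows <- lapply(sessions, function(s) {
    v <- syllable_velocity(s)
    u <- syllable_usage(s)
    d <- syllable_durations(s)
    syl <- d$syllable
    data.frame(animal_id = s$animal_id[1], group = s$group[1],
               syllable = syl,
               velocity = as.numeric(v[as.character(syl)]),
               usage = as.numeric(u[as.character(syl)]),
               usage_instances = d$n_instances / sum(d$n_instances),
               mean_duration_ms = d$mean_duration_ms,
               n_instances = d$n_instances,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("syllable_stats", "data.frame")
  out
}

#' Filter syllables by expression threshold
#'
#' Retains syllables whose group-mean usage exceeds `min_usage` in at least
#' one group — the "expressed more than 0.5% of the time" inclusion rule.
#'
#' @param stats a [syllable_stats()] table.
#' @param min_usage usage threshold (fraction of frames; default 0.005).
#' @return A `usage_filter` list: `retained` syllable ids, `min_usage`,
#'   `basis` (groups tested), `group_mean_usage` matrix.
#' @export
filter_by_usage <- function(stats, min_usage = 0.005) {
  stopifnot(nrow(stats) > 0)
  gm <- tapply(stats$usage, list(stats$syllable, stats$group), mean,
               default = 0)
  retained <- as.integer(rownames(gm)[apply(gm > min_usage, 1, any)])
  structure(list(retained = sort(retained), min_usage = min_usage,
                 basis = colnames(gm), group_mean_usage = gm),
            class = "usage_filter")
}

#' Rank syllables by control-group velocity
#'
#' Display order used throughout the group comparisons: descending
#' control-group mean velocity, ties broken by ascending syllable id.
#'
#' @param stats a [syllable_stats()] table.
#' @param control_group label of the reference group.
#' @return Integer vector of syllable ids, fastest first.
#' @export
rank_by_velocity <- function(stats, control_group = "control") {
  ctl <- stats[stats$group == control_group, , drop = FALSE]
  if (!nrow(ctl)) stop("no rows for control group '", control_group, "'",
                       call. = FALSE)
  mv <- tapply(ctl$velocity, ctl$syllable, mean)
  ids <- as.integer(names(mv))
  ids[order(-as.numeric(mv), ids)]
}
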