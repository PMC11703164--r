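#' Write labeled sessions to a frame-table CSV
#'
#' One row per frame, columns `frame, x_cm, y_cm, syllable, animal_id,
#' group` (UTF-8, '.' decimal, header mandatory); multiple sessions are
#' concatenated and distinguished by `animal_id`.
#'
#' @param sessions a [labeled_session()] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_frame_table <- function(sessions, path) {
  if (inherits(sessions, "labeled_session")) sessions <- list(sessions)
  df <- do.call(rbind, lapply(sessions, function(s)
    as.data.frame(s)[, c("frame", "x_cm", "y_cm", "syllable",
                         "animal_id", "group")]))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a frame-table CSV into labeled sessions
#'
#' Validates the schema (missing required columns are reported by name)
#' and per-animal frame continuity, then splits the table into one
#' [labeled_session()] per `animal_id`.
#'
#' @param path CSV path.
#' @param fps frame rate to attach (the CSV stores none).
#' @param arena_side arena side (cm) to attach.
#' @param strict error (`TRUE`) or warn (`FALSE`) on non-consecutive
#'   frames and out-of-arena coordinates.
#' @return Named list of [labeled_session()] objects.
#' @export
read_frame_table <- function(path, fps = 30, arena_side = NA_real_,
                             strict = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("frame", "x_cm", "y_cm", "animal_id", "group")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("frame table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"syllable" %in% names(df)) df$syllable <- NA_integer_
  complain <- if (strict) function(...) stop(..., call. = FALSE) else warning
  out <- list()
  for (id in unique(df$animal_id)) {
    sub <- df[df$animal_id == id, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    if (any(diff(sub$frame) != 1L) || sub$frame[1] != 0L)
      complain("frame continuity error for animal '", id,
               "': indices must run 0,1,2,...")
    if (!is.na(arena_side)) {
      bad <- sum(sub$x_cm < 0 | sub$x_cm > arena_side |
                   sub$y_cm < 0 | sub$y_cm > arena_side, na.rm = TRUE)
      if (bad > 0)
        complain(bad, " coordinates outside the arena for animal '", id, "'")
    }
    out[[id]] <- labeled_session(
      frame = sub$frame, x = sub$x_cm, y = sub$y_cm,
      syllable = sub$syllable, animal_id = id, group = sub$group[1],
      fps = fps, arena_side = arena_side, validate_frames = strict)
  }
  out
}

#' Write / read a keypoint-table CSV
#'
#' Columns `frame, kp{i}_x, kp{i}_y`; keypoint count is inferred from the
#' header on read.
#'
#' @param kp a `keypoint_session` data frame.
#' @param path CSV path.
#' @return `path` invisibly (write); a `keypoint_session` (read).
#' @export
write_keypoint_table <- function(kp, path) {
  write.csv(as.data.frame(kp), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_keypoint_table
#' @param fps frame rate to attach.
#' @param anterior,posterior body-axis keypoint indices to attach.
#' @export
read_keypoint_table <- function(path, fps = 30, anterior = 1L,
                                posterior = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  xc <- grep("^kp[0-9]+_x$", names(df), value = TRUE)
  if (!"frame" %in% names(df) || length(xc) < 2)
    stop("keypoint table schema error: need 'frame' and >= 2 kp{i}_x/_y ",
         "column pairs", call. = FALSE)
  if (is.null(posterior)) posterior <- length(xc)
  attr(df, "fps") <- fps
  attr(df, "anterior") <- as.integer(anterior)
  attr(df, "posterior") <- as.integer(posterior)
  class(df) <- c("keypoint_session", "data.frame")
  df
}

#' Analysis configuration
#'
#' The run configuration consumed by [run_pipeline()]: simulation settings,
#' analysis thresholds (usage filter, FDR level), AR-HMM hyperparameters
#' and kappa grid, and the master seed. Serializes losslessly through YAML.
#'
#' @param out_dir results directory.
#' @param sim a [sim_config()] (or list of its arguments) for the
#'   simulate stage.
#' @param treatment simulate the third (treated) group?
#' @param min_usage syllable inclusion threshold (fraction of time).
#' @param fdr_q FDR level for the syllable comparisons.
#' @param kappa_grid candidate kappas for [kappa_scan()].
#' @param alpha,gamma,max_states,n_iter AR-HMM hyperparameters.
#' @param target_duration_ms kappa-scan duration criterion.
#' @param seed master seed.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(out_dir = "results",
                            sim = sim_config(),
                            treatment = FALSE,
                            min_usage = 0.005,
                            fdr_q = 0.05,
                            kappa_grid = 10^seq(2, 6, by = 1),
                            alpha = 5.7, gamma = 1e3, max_states = 100,
                            n_iter = 100, target_duration_ms = 400,
                            seed = 1L) {
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  stopifnot(min_usage >= 0, min_usage < 1, fdr_q > 0, fdr_q < 1,
            target_duration_ms > 0)
  structure(list(out_dir = out_dir, sim = sim, treatment = treatment,
                 min_usage = min_usage, fdr_q = fdr_q,
                 kappa_grid = kappa_grid, alpha = alpha, gamma = gamma,
                 max_states = max_states, n_iter = n_iter,
                 target_duration_ms = target_duration_ms,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param config an `analysis_config`.
#' @param path YAML file path.
#' @export
write_analysis_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$sim <- unclass(cfg$sim)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname analysis_config
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sim_args <- cfg$sim
  cfg$sim <- NULL
  do.call(analysis_config, c(cfg, list(sim = do.call(sim_config, sim_args))))
}

#' Run the whole analysis pipeline
#'
#' Orchestrates simulate -> metrics -> transitions -> stats -> report on a
#' synthetic cohort (segmentation is exercised separately on keypoint
#' input; simulated sessions carry ground-truth labels). All outputs land
#' in `config$out_dir` with a JSON manifest recording the config snapshot,
#' seed and an MD5 checksum per file; reruns with the same config
#' reproduce the checksums bit for bit.
#'
#' @param config an [analysis_config()].
#' @return Invisible list with the in-memory stage results (`cohort`,
#'   `stats`, `usage_filter`, `models`, `comparisons`, `regressions`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  # -- simulate -------------------------------------------------------
  cohort <- simulate_cohort(config$sim, treatment = config$treatment)
  write_frame_table(cohort$sessions, out("sessions.csv"))

  # -- metrics --------------------------------------------------------
  stats_tab <- syllable_stats(cohort$sessions)
  write.csv(stats_tab, out("syllable_stats.csv"), row.names = FALSE)
  uf <- filter_by_usage(stats_tab, min_usage = config$min_usage)
  speeds <- vapply(cohort$sessions, session_speed, numeric(1))
  groups <- vapply(cohort$sessions, function(s) s$group[1], character(1))
  speed_tab <- summarize_groups(speeds, groups)
  write.csv(speed_tab, out("session_speed.csv"), row.names = FALSE)

  # -- transitions ----------------------------------------------------
  syl_universe <- sort(unique(stats_tab$syllable))
  models <- lapply(cohort$sessions, transition_model,
                   syllables = syl_universe)
  scalar_tab <- data.frame(
    animal_id = vapply(models, function(m) m$animal_id, character(1)),
    group = vapply(models, function(m) m$group, character(1)),
    entropy_rate = vapply(models, function(m) m$H, numeric(1)),
    row_entropy_sum = vapply(models, function(m) m$row_entropy_sum,
                             numeric(1)),
    transition_frequency = vapply(models, function(m)
      m$transition_frequency, numeric(1)))
  write.csv(scalar_tab, out("transition_scalars.csv"), row.names = FALSE)
  gts <- group_transition_summary(models)
  write.csv(gts$edges, out("transition_diff_edges.csv"), row.names = FALSE)

  # -- stats ----------------------------------------------------------
  comparisons <- list(
    velocity = compare_syllables(stats_tab, "velocity", q = config$fdr_q,
                                 syllables = uf$retained),
    usage = compare_syllables(stats_tab, "usage", q = config$fdr_q,
                              syllables = uf$retained))
  for (m in names(comparisons))
    write.csv(comparisons[[m]], out(paste0("comparison_", m, ".csv")),
              row.names = FALSE)
  regressions <- list(
    velocity = delta_regression(stats_tab, "velocity",
                                syllables = uf$retained),
    usage = delta_regression(stats_tab, "usage", syllables = uf$retained))
  reg_tab <- do.call(rbind, lapply(regressions, function(r)
    data.frame(metric = r$metric, slope = r$slope, intercept = r$intercept,
               r_squared = r$r_squared, p_value = r$p_value, n = r$n)))
  write.csv(reg_tab, out("delta_regressions.csv"), row.names = FALSE)

  # scalar group tests (conventional locomotor measures)
  mw <- list(
    session_speed = mann_whitney(speeds[groups == "control"],
                                 speeds[groups == "lesion"]),
    transition_frequency = mann_whitney(
      scalar_tab$transition_frequency[scalar_tab$group == "control"],
      scalar_tab$transition_frequency[scalar_tab$group == "lesion"]),
    entropy_rate = mann_whitney(
      scalar_tab$entropy_rate[scalar_tab$group == "control"],
      scalar_tab$entropy_rate[scalar_tab$group == "lesion"]))

  # -- report ---------------------------------------------------------
  write_report(out("report.md"), config, uf, speed_tab, scalar_tab,
               comparisons, regressions, mw)

  files <- c("sessions.csv", "syllable_stats.csv", "session_speed.csv",
             "transition_scalars.csv", "transition_diff_edges.csv",
             "comparison_velocity.csv", "comparison_usage.csv",
             "delta_regressions.csv", "report.md")
  manifest <- list(
    seed = config$sim$seed,
    config = unclass_deep(config),
    files = lapply(setNames(files, files), function(f)
      unname(tools::md5sum(out(f)))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, stats = stats_tab, usage_filter = uf,
                 models = models, comparisons = comparisons,
                 regressions = regressions, mann_whitney = mw,
                 manifest = manifest))
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

write_report <- function(path, config, uf, speed_tab, scalar_tab,
                         comparisons, regressions, mw) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Syllable analysis report")
  w("")
  w("Seed %d; %d syllables retained at usage > %.3f (basis: %s).",
    config$sim$seed, length(uf$retained), uf$min_usage,
    paste(uf$basis, collapse = ", "))
  w("")
  w("## Session speed (cm/s)")
  for (i in seq_len(nrow(speed_tab)))
    w("- %s: %.2f +/- %.2f (n = %d)", speed_tab$group[i],
      speed_tab$mean[i], speed_tab$sem[i], speed_tab$n[i])
  w("- Mann-Whitney control vs lesion: U = %g, p = %.4g",
    mw$session_speed$U, mw$session_speed$p)
  w("")
  w("## Temporal organization (per-animal, rank tests)")
  for (nm in c("transition_frequency", "entropy_rate")) {
    sg <- summarize_groups(scalar_tab[[nm]], scalar_tab$group)
    for (i in seq_len(nrow(sg)))
      w("- %s %s: %.3f +/- %.3f (n = %d)", nm, sg$group[i], sg$mean[i],
        sg$sem[i], sg$n[i])
    w("- Mann-Whitney control vs lesion: U = %g, p = %.4g",
      mw[[nm]]$U, mw[[nm]]$p)
  }
  w("")
  w("## Per-syllable comparisons (Kruskal-Wallis + Dunn, BH across")
  w("## syllables at q = %.2f; Dunn pairwise p uncorrected)", config$fdr_q)
  for (m in names(comparisons)) {
    cr <- comparisons[[m]]
    sig <- cr$syllable[cr$significant]
    w("- %s: %d/%d syllables significant%s", m, length(sig), nrow(cr),
      if (length(sig)) paste0(" (", paste(sig, collapse = ", "), ")")
      else "")
  }
  w("")
  w("## Delta regressions on control velocity")
  for (m in names(regressions)) {
    r <- regressions[[m]]
    w("- delta %s: slope = %.4f, R^2 = %.3f, p = %.3g, n = %d",
      m, r$slope, r$r_squared, r$p_value, r$n)
  }
  invisible(path)
}
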