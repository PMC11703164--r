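#!/usr/bin/env Rscript
# Stage 3: per-animal syllable kinematics and expression.
#
# Reads the stage-1 frame table, computes the per-animal x syllable
# velocity/usage/duration table, applies the 0.5%-of-time inclusion
# filter, and ranks syllables by control-group velocity.

suppressPackageStartupMessages(library(syllabr))

out_dir <- "results/analysis"
cfg <- read_analysis_config(file.path(out_dir, "config.yaml"))
sessions <- read_frame_table(file.path(out_dir, "sessions.csv"),
                             fps = cfg$sim$fps,
                             arena_side = cfg$sim$arena_side)

stats <- syllable_stats(sessions)
write.csv(stats, file.path(out_dir, "syllable_stats.csv"),
          row.names = FALSE)

uf <- filter_by_usage(stats, min_usage = cfg$min_usage)
cat(sprintf("%d of %d syllables expressed > %.1f%% of the time in some group\n",
            length(uf$retained), cfg$sim$n_syllables, 100 * uf$min_usage))

ranked <- rank_by_velocity(stats)
ctl <- stats[stats$group == "control", ]
mv <- tapply(ctl$velocity, ctl$syllable, mean)
cat("syllables ranked by control velocity (fastest first):\n")
cat(sprintf("  top: syllable %d at %.1f cm/s; bottom: syllable %d at %.1f cm/s\n",
            ranked[1], mv[as.character(ranked[1])],
            ranked[length(ranked)], mv[as.character(ranked[length(ranked)])]))

speeds <- vapply(sessions, session_speed, numeric(1))
groups <- vapply(sessions, function(s) s$group[1], character(1))
speed_tab <- summarize_groups(speeds, groups)
write.csv(speed_tab, file.path(out_dir, "session_speed.csv"),
          row.names = FALSE)
for (i in seq_len(nrow(speed_tab)))
  cat(sprintf("session speed, %s: %.2f +/- %.2f cm/s (n = %d)\n",
              speed_tab$group[i], speed_tab$mean[i], speed_tab$sem[i],
              speed_tab$n[i]))

dur <- vapply(sessions, function(s)
  attr(syllable_durations(s), "overall_mean_ms"), numeric(1))
dt <- summarize_groups(dur, groups)
for (i in seq_len(nrow(dt)))
  cat(sprintf("mean syllable duration, %s: %.0f +/- %.0f ms\n",
              dt$group[i], dt$mean[i], dt$sem[i]))
cat("wrote syllable_stats.csv, session_speed.csv under", out_dir, "\n")
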