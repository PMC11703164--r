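#!/usr/bin/env Rscript
# Stage 5: group comparisons.
#
# Per-syllable Kruskal-Wallis with Dunn's post hoc across the three
# groups, BH-corrected across syllables at q = 0.05; Mann-Whitney U on
# the scalar measures; and the delta-velocity / delta-usage regressions
# on control velocity that test whether dopamine depletion hits faster
# syllables harder.

suppressPackageStartupMessages(library(syllabr))

out_dir <- "results/analysis"
cfg <- read_analysis_config(file.path(out_dir, "config.yaml"))
stats <- read.csv(file.path(out_dir, "syllable_stats.csv"))
scalars <- read.csv(file.path(out_dir, "transition_scalars.csv"))

uf <- filter_by_usage(stats, min_usage = cfg$min_usage)

for (metric in c("velocity", "usage")) {
  cr <- compare_syllables(stats, metric, q = cfg$fdr_q,
                          syllables = uf$retained)
  write.csv(cr, file.path(out_dir, paste0("comparison_", metric, ".csv")),
            row.names = FALSE)
  write.csv(attr(cr, "pairwise"),
            file.path(out_dir, paste0("dunn_", metric, ".csv")),
            row.names = FALSE)
  sig <- cr$syllable[cr$significant]
  cat(sprintf("%s: %d/%d syllables differ across groups at q = %.2f\n",
              metric, length(sig), nrow(cr), cfg$fdr_q))
}

dr_v <- delta_regression(stats, "velocity", syllables = uf$retained)
dr_u <- delta_regression(stats, "usage", syllables = uf$retained)
print(dr_v)
print(dr_u)
reg <- do.call(rbind, lapply(list(dr_v, dr_u), function(r)
  data.frame(metric = r$metric, slope = r$slope, intercept = r$intercept,
             r_squared = r$r_squared, p_value = r$p_value, n = r$n)))
write.csv(reg, file.path(out_dir, "delta_regressions.csv"),
          row.names = FALSE)

# scalar measures: control vs lesion, and lesion vs treated
for (nm in c("transition_frequency", "entropy_rate")) {
  x <- scalars[[nm]]
  g <- scalars$group
  m1 <- mann_whitney(x[g == "control"], x[g == "lesion"])
  cat(sprintf("%s control vs lesion: U = %g, p = %.4g\n", nm, m1$U, m1$p))
  if ("lesion_ldopa" %in% g) {
    m2 <- mann_whitney(x[g == "lesion"], x[g == "lesion_ldopa"])
    cat(sprintf("%s lesion vs lesion+treatment: U = %g, p = %.4g\n",
                nm, m2$U, m2$p))
  }
}
cat("wrote comparison_*.csv, dunn_*.csv, delta_regressions.csv under",
    out_dir, "\n")
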