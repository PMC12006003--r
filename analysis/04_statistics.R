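#!/usr/bin/env Rscript
# Stage 4: the statistical battery. Shapiro-Wilk gated omnibus tests
# (one-way ANOVA or Kruskal-Wallis) with Dunn's post hoc comparisons of
# every illumination time against the 0 s baseline, for intensity, census
# and coverage; one-sample location tests of the per-cell morphometric
# changes against zero. Writes a flat CSV of all comparisons.

suppressMessages(library(photofade))

report <- readRDS("scratch/run_report.rds")

rows <- list()
for (arm in names(report$stats)) {
  st <- report$stats[[arm]]
  for (metric in c("intensity", "census", "coverage")) {
    res <- st[[metric]]
    cat(sprintf("%s / %s: gate=%s, %s p=%.3g %s\n", arm, metric, res$gate,
                res$omnibus$test, res$omnibus$p, res$omnibus$stars))
    ph <- res$posthoc
    if (!is.null(ph))
      rows[[length(rows) + 1L]] <- data.frame(
        fluorophore = arm, metric = metric, comparison = ph$comparison,
        statistic = ph$z, p_raw = ph$p_raw, p_adj = ph$p_adj,
        stars = ph$stars)
  }
  if (!is.null(st$fractal)) {
    for (p in names(st$fractal)) {
      fr <- st$fractal[[p]]
      cat(sprintf("%s / fractal %s: %s p=%.3g %s\n", arm, p, fr$test, fr$p,
                  fr$stars))
      rows[[length(rows) + 1L]] <- data.frame(
        fluorophore = arm, metric = paste0("fractal_", p),
        comparison = "endpoint vs 0", statistic = fr$statistic,
        p_raw = fr$p, p_adj = fr$p, stars = fr$stars)
    }
  }
}
flat <- do.call(rbind, rows)
utils::write.csv(flat, "results/statistics.csv", row.names = FALSE)
cat("\nwrote results/statistics.csv (", nrow(flat), "comparisons )\n")
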