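#!/usr/bin/env Rscript
# Stage 3 — cohort statistics.
#
# Jury-score selection (inclusive cutoff 8.5 on the 1-10 Phillips scale),
# per-judge test-retest Pearson repeatability, per-gender per-region
# Shapiro-Wilk normality, and the gender-stratified summary: mean region
# volumes, percentage shares derived from the mean volumes, and the
# maxilla/mandible ratio.
#
# Input:  scratch/cohort/{manifest.csv,scores.csv} (stage 1)
# Output: scratch/cohort_summary.{json,csv}, results/judge_repeatability.csv,
#         results/normality.csv

suppressPackageStartupMessages(library(volcephalo))

summary <- run_cohort("scratch/cohort/manifest.csv", "scratch/cohort/scores.csv",
                      run_config(cutoff = 8.5),
                      out_prefix = "scratch/cohort_summary")

message("selected ", length(summary$selected), " of ", summary$n_measured,
        " subjects at cutoff 8.5")

rep_tab <- summary$repeatability$per_judge
write.csv(rep_tab, "results/judge_repeatability.csv", row.names = FALSE)
message(sprintf("judge repeatability: mean r = %.3f (range %.3f - %.3f)",
                summary$repeatability$mean_r, min(rep_tab$r), max(rep_tab$r)))

norm_rows <- list()
for (g in names(summary$normality)) {
  for (r in names(summary$normality[[g]])) {
    nr <- summary$normality[[g]][[r]]
    norm_rows[[length(norm_rows) + 1L]] <-
      data.frame(gender = g, region = r, W = nr$W, p = nr$p)
  }
}
norm_tab <- do.call(rbind, norm_rows)
write.csv(norm_tab, "results/normality.csv", row.names = FALSE)
message(sprintf("Shapiro-Wilk W range: %.3f - %.3f (all p > 0.05: %s)",
                min(norm_tab$W), max(norm_tab$W), all(norm_tab$p > 0.05)))

for (g in names(summary$gender_summary)) {
  s <- summary$gender_summary[[g]]
  message(sprintf(
    "%s (n = %d): shares %s, maxilla/mandible ratio %.2f", g, s$n,
    paste(sprintf("%.1f", round_half_away(s$shares, 1)), collapse = " / "),
    round_half_away(s$mm_ratio, 2)))
}
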