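#!/usr/bin/env Rscript
# Stage 4 — the normative "aesthetic guide" comparison.
#
# Reproduces the published normative distributions from their mean volumes
# (the female set is self-consistent; the printed male malar/maxillary
# percentages conflict with their own volumes and are flagged), then
# demonstrates the intended preoperative use: compare one subject's
# measured distribution to the gender reference and report per-region
# deviations and the volume changes that would equalise each share.
#
# Input:  results/per_subject_volumes.csv (stage 2)
# Output: results/normative_check.csv, results/example_deviation.csv

suppressPackageStartupMessages(library(volcephalo))

rows <- list()
for (g in c("female", "male")) {
  ref <- normative_reference(g, "printed")
  dec <- if (g == "female") 1 else 0
  computed <- percentage_distribution(ref$mean_volumes, decimals = dec)
  rows[[g]] <- data.frame(
    gender = g, region = names(computed),
    printed_share = unname(ref$shares[names(computed)]),
    share_from_volumes = unname(computed),
    consistent = unname(ref$shares[names(computed)] == computed)
  )
}
check <- do.call(rbind, rows)
write.csv(check, "results/normative_check.csv", row.names = FALSE)
print(check, row.names = FALSE)
fem <- normative_reference("female", "printed")
message(sprintf(
  "maxilla/mandible ratio of the female means: %.2f",
  maxillomandibular_ratio(fem$mean_volumes[["maxillary"]],
                          fem$mean_volumes[["mandibular"]])))

per_subject <- read.csv("results/per_subject_volumes.csv", stringsAsFactors = FALSE)
subj <- per_subject[1, ]
prof <- volume_profile(subj$v_malar, subj$v_maxillary, subj$v_mandibular,
                       subj$v_chin)
cmp <- compare_to_reference(prof, normative_reference(subj$gender,
                                                      "volume_consistent"))
write.csv(cmp, "results/example_deviation.csv", row.names = FALSE)
message("example preoperative comparison (subject ", subj$subject_id, ", ",
        subj$gender, "):")
print(cmp, row.names = FALSE)
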