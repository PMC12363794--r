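#!/usr/bin/env Rscript
# Stage 4: Bliss-independence synergy landscape for the simulated
# dose-response plate (three replicates, planted +10-point interaction).

library(plastichrom)

dir.create("results/synergy", showWarnings = FALSE, recursive = TRUE)
plate <- read_plate_csv("results/data/plate_demo.csv")
surf <- synergy_surface(normalize_plate(plate))

long <- as.data.frame(as.table(surf$delta))
names(long) <- c("dose_a", "dose_b", "delta")
write_tsv(long[!is.na(long$delta), ], "results/synergy/surface.tsv")
write_tsv(data.frame(summary_score = surf$summary_score,
                     replicate_sd = surf$replicate_sd,
                     n_wells = surf$n_wells),
          "results/synergy/summary.tsv")

print(surf)
cat("Per-well synergy (percentage points over the Bliss expectation):\n")
print(round(surf$delta, 1))
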