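#!/usr/bin/env Rscript
# Stage 3: build the three pairwise experiments (A: BM vs disruptive,
# B: BM vs distractive, C: disruptive vs distractive), each with 6 treatment
# arms x 20 participants x 64 slides, and check every sequencing invariant.

suppressPackageStartupMessages(library(camosearch))
dir.create("results", showWarnings = FALSE)

master_seed <- 1L
pool_ids <- sprintf("bg%02d", 1:8)

total <- 0L
for (ex in c("A", "B", "C")) {
  design <- build_experiment(ex, n_per_arm = 20,
                             seed = derive_seed(master_seed, "design", ex),
                             background_ids = pool_ids)
  validate_design(design)
  write_design(design, sprintf("results/design_%s.csv", ex))
  total <- total + nrow(design)
  message(sprintf("experiment %s: %d participants, %d encounters, arms: %s",
                  ex, length(unique(design$participant_id)), nrow(design),
                  paste(sort(unique(design$arm)), collapse = " ")))
}
message("total prey presentations across experiments: ", total)
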