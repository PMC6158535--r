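#!/usr/bin/env Rscript
# Stage 4: simulate observers over the three designs under the paperlike
# scenario (search-image gain absent for disruptive prey, largest for
# distractive; a positive distractive-to-disruptive switch penalty) and
# write the censored trial tables.

suppressPackageStartupMessages(library(camosearch))
dir.create("results", showWarnings = FALSE)

master_seed <- 1L
params <- default_params("paperlike")

for (ex in c("A", "B", "C")) {
  design <- read_design(sprintf("results/design_%s.csv", ex))
  trials <- simulate_trials(design, params,
                            derive_seed(master_seed, "simulate", ex))
  write_trials(trials, sprintf("results/trials_%s.csv", ex))
  ok <- !trials$timed_out
  message(sprintf(
    "experiment %s: %d trials, %d timed out (%.1f%%); median capture %.2f s",
    ex, nrow(trials), sum(!ok), 100 * mean(!ok),
    median(trials$capture_time_ms[ok]) / 1000))
}
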