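#!/usr/bin/env Rscript
# Stage 5: the statistical pipeline per experiment: mixed linear model on
# logged capture times (quadratic screen position with interaction,
# inversion flag, slide-within-phase, 10-level phase treatment, two-way
# interactions; participant and background random intercepts),
# likelihood-ratio simplification, and the planned phase-treatment
# contrasts.

suppressPackageStartupMessages(library(camosearch))
dir.create("results", showWarnings = FALSE)

for (ex in c("A", "B", "C")) {
  trials <- read_trials(sprintf("results/trials_%s.csv", ex))
  report <- analyze_experiment(trials, ex)
  write_report(report, sprintf("results/report_%s.json", ex))
  print(report)
  headline <- report$contrasts[report$contrasts$comparison_class ==
                                 "among_participant", ]
  sig <- headline[headline$p < 0.05, "label"]
  message(sprintf("experiment %s significant among-participant contrasts: %s",
                  ex, if (length(sig)) paste(sig, collapse = "; ")
                      else "(none)"))
}
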