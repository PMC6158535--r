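#!/usr/bin/env Rscript
# Stage 2: generate prey targets under the three camouflage constraints and
# re-verify every one (background matching: interior markings only;
# disruptive: markings crossing the outline; distractive: an interior
# high-contrast spot). Writes the sweep table and one rendered example slide
# per treatment.

suppressPackageStartupMessages(library(camosearch))
dir.create("results", showWarnings = FALSE)

master_seed <- 1L
pool <- make_background_pool(8, seed = derive_seed(master_seed, "backgrounds"))

sweep <- stimulus_sweep(pool, n_per_treatment = 50,
                        seed = derive_seed(master_seed, "sweep"))
write.csv(sweep, "results/stimulus_sweep.csv", row.names = FALSE)

message("constraint re-verification pass rate: ",
        sprintf("%.1f%%", 100 * mean(sweep$verified)))
print(aggregate(edge_intersections ~ treatment, sweep, function(x)
  c(min = min(x), max = max(x))))

for (tr in PREY_TYPES) {
  tg <- make_target(pool[[1]], tr, seed = derive_seed(master_seed, "demo", tr))
  slide <- render_slide(pool[[1]], tg, x = 300, y = 200)
  crop <- structure(list(id = tr, pixels = slide[1:384, 1:512],
                         width = 512L, height = 384L),
                    class = "background_image")
  write_background(crop, sprintf("results/example_slide_%s.png", tr))
}
message("example slides written to results/")
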