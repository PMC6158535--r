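#!/usr/bin/env Rscript
# Stage 1: build the background pool.
#
# Synthesizes the bark-like background scenes the prey are sampled from and
# shown against, and records the pool manifest. A small preview crop is
# written so the texture can be inspected without shipping full-canvas PNGs.

suppressPackageStartupMessages(library(camosearch))
dir.create("results", showWarnings = FALSE)

master_seed <- 1L
pool <- make_background_pool(8, seed = derive_seed(master_seed, "backgrounds"))

manifest <- data.frame(
  id = names(pool),
  width = vapply(pool, `[[`, 0L, "width"),
  height = vapply(pool, `[[`, 0L, "height"),
  luminance_spread = vapply(pool, luminance_spread, 0)
)
write.csv(manifest, "results/background_pool.csv", row.names = FALSE)

preview <- pool[[1]]
preview$pixels <- preview$pixels[1:256, 1:256]
preview$width <- preview$height <- 256L
write_background(preview, "results/background_preview.png")

message(sprintf("pool of %d backgrounds; luminance spreads %.0f-%.0f levels",
                length(pool), min(manifest$luminance_spread),
                max(manifest$luminance_spread)))
message("every image satisfies the 40-level spread floor: ",
        all(manifest$luminance_spread >= 40))
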