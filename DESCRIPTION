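Package: camosearch
Title: Camouflage Strategies and Search-Image Formation in Serial Detection Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses serial visual-search experiments on
    camouflaged prey. Generates triangular prey stimuli from bark-like
    background textures under three camouflage-strategy constraints
    (background matching, disruptive, distractive), builds the three-phase
    learning / search-image / test experimental design with constrained
    pseudorandom trial sequences, simulates observers with learning,
    search-image and switch-interference dynamics producing right-censored
    capture times, and fits the associated linear mixed models with
    likelihood-ratio simplification and planned phase-treatment contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    EBImage,
    png,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    optparse,
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
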