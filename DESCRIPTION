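Package: callcat
Title: Feature-Based Categorization of Animal Vocalizations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling auditory categorization of animal
    vocalizations with contrastive spectrotemporal features. Generates
    synthetic multi-syllable call corpora, computes gammatone-filterbank
    cochleagrams, trains sets of maximally informative features (MIFs) by
    greedy mutual-information selection, and simulates Go/No-go decisions
    through a winner-take-all stage with guess and lapse rates. Includes a
    long-term-spectrum linear classifier baseline, a battery of stimulus
    manipulations (noise mixing at fixed SNR, truncation, tempo and
    fundamental-frequency shifts, reversal, low-pass filtering,
    inter-syllable-interval rearrangement and chimeric calls), and
    signal-detection, psychometric and trial-level regression analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
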