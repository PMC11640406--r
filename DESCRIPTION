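Package: cardioish
Title: Explainable Lead-Transition Feature Engineering for 12-Lead ECG Beats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Feature engineering and explainable classification for 12-lead
    electrocardiogram (ECG) beats. Each beat is encoded by ranking the 12
    leads by descending amplitude at every sample, producing a lead-index
    sequence whose 12x12 transition table yields 144 row-normalised
    features. Features are ranked by neighbourhood component analysis (NCA)
    and selected by iterative prefix evaluation with a 1-nearest-neighbour
    loss (INCA); classification uses k-nearest neighbours with cityblock
    distance under stratified cross-validation. Selected feature indexes
    decode into a 12-symbol lead alphabet ("Cardioish"), forming symbol
    sentences with frequency distributions, Shannon entropies, and directed
    weighted connectome graphs over the leads. Includes a synthetic 12-lead
    beat generator with class-specific per-lead gain structure, readers and
    writers for beat sets, feature tables, selection reports, sentences and
    graphs, and tidy/broom-style accessors for all fitted objects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
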