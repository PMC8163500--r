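Package: hftag
Title: Hierarchical Frequency-Tagging Analysis of Concurrent Speech
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for dichotic-listening experiments
    that probe linguistic processing of task-irrelevant speech with
    hierarchical frequency tagging. Builds isochronous syllable sequences in
    which words, phrases and sentences are tagged at 2, 1 and 0.5 Hz on top of
    a 4 Hz syllable rate; simulates multi-channel neural recordings with
    phase-locked tag responses, speech-tracking responses and 1/f background
    noise; computes inter-trial phase coherence (Rayleigh z) spectra and
    frequency-of-interest peak statistics; runs label-switch, ROI sum-of-t and
    spatio-temporal cluster permutation tests; and estimates temporal response
    functions by normalized reverse correlation with jackknife
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
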