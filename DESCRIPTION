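Package: neurovasc
Title: Neurovascular Analysis of Line-Scan Velocimetry and DC-Coupled Field Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-photon line-scan recordings of cortical
    microvessels and simultaneous DC-coupled local field potentials in focal
    ischemia experiments. Implements line-scanning particle image velocimetry
    (LS-PIV) for red-blood-cell velocity estimation from kymographs, detection
    of spreading depolarizations and post-ischemic theta/alpha-band potentials
    in the LFP, segmentation of the experiment into baseline, ischemia and
    partial-recovery periods with derived neurovascular metrics, synthesis of
    band-limited optogenetic stimulation waveforms, and a synthetic-data
    generator with machine-readable ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
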