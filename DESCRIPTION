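Package: qccircos
Title: Circular Quality-Control Plots for Affymetrix-Style Probe-Level
    Microarray Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Per-array quality control for probe-level (PM/MM) expression
    microarray batches and a condensed circular visualization of the
    results. Computes zonal average background and noise, MAS5-style
    Wilcoxon detection calls, housekeeping 3'/5' degradation ratios,
    spike-in and poly-A control signals, the 5'->3' RNA degradation slope,
    quantile normalization with median-polish summarization, and
    mean-centred principal component scores. Condenses the measurements to
    per-array outlier flags and draws every array of a dataset as a sector
    of a six-rim circular SVG plot; also emits Circos-compatible
    karyotype, data-track and configuration files. Includes a synthetic
    probe-level data generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
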