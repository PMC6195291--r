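Package: arspl
Title: Adaptive Region Segmentation Piecewise Linear Synthesis of 12-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the standard 12-lead electrocardiogram from the reduced
    3-lead subset {I, II, V2} using adaptive region segmentation based piecewise
    linear (ARSPL) regression. Each cardiac cycle is split into ST-T, R-P, QRS and
    head-tail regions anchored on wavelet-detected R peaks, a personalized
    least-squares model is fitted per region, and the synthesized regions are
    reassembled into full-length signals. Includes wavelet detrending/denoising,
    adaptive-threshold R-peak detection, the plain linear-regression baseline, an
    evaluation suite (correlation, RMSE, ST-level denivelation ratios, detection
    sensitivity/precision, inter-region amplitude gaps), a synthetic 12-lead ECG
    generator with ground truth, and readers/writers for WFDB and CSV waveforms.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
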