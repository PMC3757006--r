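Package: ramanredox
Title: Resonance Raman Analysis of Mitochondrial Cytochrome Redox State
    and Myoglobin Oxygenation in Heart Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying 532 nm resonance Raman spectra of perfused
    heart tissue: reading and writing one-dimensional spectra (two-column text
    and JCAMP-DX), asymmetric-least-squares fluorescence baseline correction,
    band quantification by windowed peak height or non-negative least-squares
    decomposition into fixed-center Lorentzians, sum-normalized band
    intensities, the c-type/b-type cytochrome redox ratio I750/I1127,
    calibration of the nu4 oxy/deoxymyoglobin scattering-efficiency ratio, and
    a calibrated deoxymyoglobin-fraction estimator. Includes a seeded
    synthetic-spectrum generator with ground truth emulating control, FCCP
    uncoupling, stop-flow ischemia/reperfusion and dithionite full-reduction
    experiments, plus an end-to-end analysis pipeline with a command-line
    entry point, nonparametric group comparisons (Kruskal-Wallis with Dunn's
    post hoc) and reproducible CSV/JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    pracma,
    signal,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
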