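Package: ringnps
Title: Ring-Sampled Noise Power Spectrum Analysis for CT Image Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the two-dimensional noise power spectrum (NPS) of
    repeated axial CT phantom scans from square regions of interest sampled
    along concentric rings, using consecutive-scan subtraction with ratio
    detrending to isolate stochastic noise, ensemble periodogram averaging,
    and one-sided horizontal/vertical marginal NPS curves. Includes scalar
    texture summaries (peak frequency, integrated power, an anisotropy
    index), multi-condition comparison tables, a thin-to-thick slice
    reformat, readers for DICOM series, TIFF stacks and plain-text array
    stacks, and a synthetic phantom/noise generator with prescribed power
    spectra, radial noise profiles and inverse-dose variance scaling so the
    whole pipeline is verifiable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
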