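Package: ndfenton
Title: Nanodiamond Relaxometry Analysis of a Copper Fenton-Like Reaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the Cu(II)/H2O2 Fenton-like reaction network with a
    mass-action kinetic model and generates mutually consistent synthetic data
    for five measurement channels: nitrogen-vacancy (NV) center T1 relaxometry
    photon-count decays, UV-Vis absorbance at 800 nm, terephthalate/HTA
    hydroxyl-radical dosimetry fluorescence, the 876 cm-1 Raman band of H2O2,
    and a dissolved-oxygen sensor trace. Provides the full analysis chain used
    to recover time-resolved species concentrations from those channels:
    constrained bi-exponential relaxation fitting, moving-window time-resolved
    T1 estimation with interquartile-range outlier rejection, particle quality
    control, T1 and fluorescence calibration curves with inversion and limit of
    detection, Beer-Lambert quantification, multipoint Raman baseline
    correction, and a combined normalized reaction timeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
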