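Package: conconnmr
Title: Simulation and Sequential Assignment for High-Dimensional CON-CON
    NMR of Intrinsically Disordered Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the carbonyl-nitrogen ("CON-CON") strategy of backbone
    resonance assignment of intrinsically disordered proteins by
    high-dimensionality NMR. Provides a closed-form pulse calculator for
    MOCCA-XY16 carbonyl mixing trains and CA/CO band-selective pulses, a
    quantum-walk model of CO-CO isotropic (TOCSY) magnetization transfer with
    field-dependent chemical-shift-anisotropy relaxation, a synthetic
    random-coil chemical-shift generator with IDP-like dispersion, exact peak
    enumeration for HNCO-anchored 3D/4D/5D experiments (including proline
    cross-peaks), non-uniformly sampled time-domain synthesis, sparse
    multidimensional Fourier transform cross-sections with peak picking, and
    assembly and scoring of sequential CO(i-1)-N(i) links including proline
    bridging. All user-facing functions take and return tidy data frames.
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
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
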