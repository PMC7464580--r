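Package: polyfrag
Title: Rule-Based Fragment Ion Prediction and Identification of Acylpolyamine Toxins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the mass-spectrometric identification and structure
    elucidation of acylpolyamine spider-venom toxins. Implements exact
    molecular-formula algebra with electron-mass-corrected ion m/z, a parser
    and formatter for the generic acylpolyamine nomenclature, a registry of
    structural building blocks (acyl heads, polyamine backbone units,
    N-substituents, tails and amino-acid linkers), rule-based prediction of
    precursor species and MS/MS fragment ions (a-, b-, c-, y-, z- and t-type),
    hydrogen/deuterium-exchange (HDX) proton accounting, peak-list I/O
    (MGF/TSV) with ppm-tolerance annotation and spectral similarity, a local
    compound registry with formula/precursor search and retention-time
    filtering, and a stepwise identification workflow that proposes structures
    for unknown toxins from their fragment spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
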