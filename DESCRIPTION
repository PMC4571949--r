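Package: rhospec
Title: Spectral Tuning Analysis of Invertebrate Visual Pigments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating visual-pigment absorbance peaks from
    photoreceptor recordings. Fits a log-normal rhodopsin alpha-band
    template to spectral-sensitivity spectra to estimate the rhodopsin
    (R-form) lambda-max, decomposes rhodopsin/metarhodopsin difference
    spectra from microspectrophotometry to estimate the metarhodopsin
    (M-form) lambda-max with the R-form fixed, and reports signed
    red/blue spectral shifts of mutant pigments against a wild-type
    reference. Includes companion stages for small opsin phylogenies
    (p-distance, neighbor joining, UPGMA, bootstrap supports) and for
    chromophore binding-pocket distance reports from protein coordinate
    files, plus synthetic-data generators that emulate the structure of
    fly photoreceptor measurements for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    jsonlite,
    seqinr,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
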