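Package: collagenQ
Title: Collagen Lysine Modification, Cross-Link and Nanomechanics Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of collagen post-translational
    chemistry and tissue micromechanics. Provides monoisotopic mass arithmetic
    for molecular formulas and modified collagen peptides; enumeration of
    lysine hydroxylation and O-glycosylation variants (Lys, Hyl, G-Hyl,
    GG-Hyl) with theoretical m/z targets for extracted-ion-chromatogram
    quantification of site occupancy; assembly and MS/MS fragment enumeration
    of lysyl-oxidase-derived cross-links (LNL, HLNL, HHMD, d-HHMD and their
    glycoforms); quantification of cross-link levels in mol per mol collagen
    from radiolabelled HPLC traces; stable-isotope-dilution collagen type
    ratios and extractability; and fitting of AFM force-indentation curves
    with the finite-thickness-corrected Hertz (Dimitriadis) contact model.
    A seed-deterministic synthetic-data generator emulates each instrument
    stream so the whole pipeline is testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
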