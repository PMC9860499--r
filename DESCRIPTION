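Package: parse2
Title: Window-Based Classification of Phase-Separating Intrinsically
    Disordered Protein Regions
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the ParSe v2 sliding-window classifier that labels
    protein regions as folded (F), intrinsically disordered (D), or
    phase-separating intrinsically disordered (P) from amino-acid property
    scales: a hydrophobicity cutoff separates folded windows, and a linear
    boundary in the (helix propensity, v_model) plane separates disordered
    from phase-separating windows, where v_model is a composition-based
    stand-in for the polymer scaling exponent derived from a hydrodynamic
    radius model for disordered chains. Provides classifier-distance
    scoring, contiguous region calling, whole-protein phase-separation
    potentials, pairwise-interaction corrections (pi-contact and charge
    potentials) with parameter fitting against experimental saturation
    concentrations or phase-separation thermodynamics, van't Hoff analysis
    of c_sat(T) series, amino-acid scale screening statistics (Welch and
    Mann-Whitney one-tail tests, windowed PCA, recall/AUC), an AAindex1
    flat-file reader, and deterministic synthetic-sequence generators for
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
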