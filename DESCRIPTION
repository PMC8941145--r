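Package: sisca
Title: Stable Isotope Cluster Analysis for Protein-SIP Metaproteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies 13C incorporation into microbial peptides from
    protein stable isotope probing (protein-SIP) mass spectrometry data.
    Predicts peptide isotopologue patterns at arbitrary 13C relative
    isotope abundance (RIA), locates and validates measured patterns in
    centroided peak lists, compares them against a grid of predicted
    patterns with a coefficient of determination, clusters genome bins
    (MAGs) by their carbon-utilization profiles via ordination of the
    R-squared vectors, classifies trophic lifestyles, and estimates
    doublings, generation times, and community-level carbon replacement.
    Also includes a single-cell Raman deuterium-labeling pipeline
    (despiking, asymmetric least-squares baseline correction, vector
    normalization, C-D ratio quantification, PCA-LDA classification) and
    a ground-truth simulator for both data types.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    Matrix,
    Biostrings,
    pracma,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
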