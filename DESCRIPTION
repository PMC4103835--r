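Package: itraqde
Title: Differential Protein Inference for iTRAQ 4-plex Reporter-Ion Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers differentially abundant proteins from iTRAQ 4-plex
    reporter-ion quantification of pooled samples run in duplicate, as used
    for epithelial lining fluid proteomics. Peptide-level reporter-ion
    ratios are log-transformed and a null model of random technical ratio
    variation is estimated by histogramming the ln-ratios on [-1, 1] in 200
    bins, smoothing with a Savitzky-Golay filter and fitting a Gaussian;
    peptides deviating from the fitted centre by at least 2.5 standard
    deviations are called discriminatory, protein-level results are the
    median discriminatory-peptide ratio, and candidates must be concordant
    across duplicate experiments with at least two significant peptides.
    Includes identification-confidence filtering, a synthetic-data generator
    with known ground truth for calibration, and exact and
    normal-approximation Wilcoxon signed-rank and Mann-Whitney U tests for
    validation-arm concentration data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    signal,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
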