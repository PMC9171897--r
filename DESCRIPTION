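Package: mosquant
Title: Methionine Oxidation Stoichiometry from 16O/18O-Labeled MS1 Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies in vivo methionine sulfoxide oxidation stoichiometries
    (MOS) from paired 16O/18O-labeled peptide species in centroided MS1
    spectra. Extracts per-isotopologue chromatographic traces at predicted
    m/z and retention time, links them by cosine similarity, estimates
    light/heavy ratios as regression slopes of summed channel intensities,
    and corrects for the overlap of isotope envelopes separated by the
    ~2 Da label offset. Per-peptide in vivo stoichiometries are obtained by
    extrapolating carrier-proteome titration responses to zero carrier
    fraction, and oxidation-prone methionines and age-group contrasts are
    identified with an empirical-Bayes adaptive-shrinkage model and
    Holm-Bonferroni corrected t-tests. Includes a fully ground-truthed
    synthetic-data generator (peptides, MS1 runs, complete titration
    experiments) so the entire workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mzR,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
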