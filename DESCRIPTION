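Package: contourvar
Title: Inter-Observer Contour Variability, Dosimetry and Radiobiological
    Prognosis for Radiotherapy Structure Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies inter-observer variability in radiotherapy target and
    organ-at-risk delineation on voxelized structure sets (volume difference,
    max-to-min ratio, coefficient of variation, Dice similarity coefficient,
    95th-percentile Hausdorff distance, STAPLE consensus), evaluates its
    dosimetric consequences by mapping per-observer dose grids onto a
    gold-standard structure set (dose-volume histograms, prescription dose
    coverage, Dmax/Dmean/D1cc summaries), converts doses to radiobiological
    endpoints (equivalent uniform dose, logistic tumor control probability,
    modified linear-quadratic normal tissue complication probability), and
    selects geometric risk predictors of coverage and control loss through
    Spearman correlation. A synthetic-cohort generator produces gold-standard
    anatomies, biased and noisy simulated observers, and conformal dose
    surrogates so the full pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
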