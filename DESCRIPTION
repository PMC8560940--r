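Package: gmaxff
Title: Gluteus Maximus Fat-Fraction Quantification from Dixon MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated quantification of gluteus maximus intramuscular fat
    from two-point Dixon MRI. Computes voxelwise fat-fraction maps from
    water and fat images, extracts landmark-delimited muscle-bulk metrics
    (mean fat fraction, volume, lean volume) from 3D label maps, and
    normalizes volumes by Boer lean body mass. Includes a synthetic Dixon
    phantom and cohort generator with known ground truth, and the cohort
    statistics used in activity-group studies of muscle fat infiltration:
    descriptive tables, Kruskal-Wallis omnibus tests with exact small-sample
    p-values, rank-based Tukey HSD post hocs, paired Wilcoxon signed-rank
    tests, hierarchical linear regression with sequential R-squared change,
    logistic models with Wald odds-ratio intervals, and power calculators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
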