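Package: cpetscore
Title: Composite Cardiopulmonary Exercise Testing Score for Pulmonary
    Arterial Hypertension Screening in Connective Tissue Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating cardiopulmonary exercise testing (CPET)
    as a screening instrument for pulmonary arterial hypertension (PAH)
    in connective tissue disease (CTD) populations. Implements a
    three-point composite score over peak oxygen uptake, the VE/VCO2
    slope and resting end-tidal CO2 pressure; diagnostic test accuracy
    with exact Clopper-Pearson intervals, likelihood ratios with
    log-method intervals, and prevalence-adjusted predictive values;
    empirical ROC curves with DeLong confidence intervals and
    Youden-optimal thresholds; the Cochran-Armitage trend test,
    Kruskal-Wallis and Pearson chi-squared group comparisons;
    breath-by-breath feature derivation (VE/VCO2 slope, V-slope
    ventilatory threshold, maximal-effort check); and a quartile-calibrated
    synthetic cohort generator for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
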