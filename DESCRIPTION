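Package: renaltwin
Title: Virtual Trials on a 1D-0D Model of the Systemic and Renal Circulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multidimensional haemodynamic modelling framework for in silico
    renal studies. Couples a one-dimensional pulse-wave model of the systemic
    arterial tree and bilateral renal arterial trees (main, segmental,
    interlobar and arcuate generations) to a lumped-parameter equivalent
    circuit of the renal microcirculation (interlobular arterioles, afferent
    and efferent arterioles, glomerular capillaries and filter, tubules,
    reabsorption and peritubular pathways), from which glomerular filtration
    is estimated by nodal analysis. Virtual subjects are generated by sex-,
    age- and disease-specific scaling of vascular properties with Gaussian
    inter-individual variation and a physiological blood-pressure and
    resistive-index inclusion filter. Doppler-style waveform biomarkers
    (phase values, acceleration and deceleration slopes, resistive and
    pulsatility indices) are extracted along the renal tree and ranked,
    singly and in combination, by logistic-regression classification
    performance (AUC) for separating diabetic from hypertensive kidney
    disease.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
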