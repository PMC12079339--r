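Package: painsig
Title: Multivariate Pattern Signatures for Pain-Empathy fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Development and evaluation of whole-brain multivariate pattern
    signatures for pain empathy evoked in social contexts. Provides a
    synthetic beta-map generator with known ground truth, first-level GLM
    estimation with canonical-HRF regressors and discrete-cosine high-pass
    filtering, linear support-vector-machine signature training with
    forced-choice cross-validated evaluation, bootstrap weight thresholding
    and Haufe forward-model encoding maps with FDR-corrected conjunction
    ("core system") identification, atlas-based cosine-similarity
    decomposition, rating-stratified decoding, and multilevel two-path
    bootstrap mediation between signature responses and trial ratings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
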