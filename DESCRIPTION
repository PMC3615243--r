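Package: tlecad
Title: Computer-Aided Diagnosis and Lateralization of Temporal Lobe
    Epilepsy from Interictal FDG-PET Regional Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing and lateralizing temporal lobe epilepsy
    from interictal FDG-PET region-of-interest metabolism tables.
    Implements histogram-quantized mutual information and
    minimum-redundancy-maximum-relevance (mRMR) feature ranking,
    cost-sensitive multilayer-perceptron classification with a
    one-against-one trinary ensemble, cyclical leave-one-out
    cross-validation with fold-internal feature selection, selection of
    the mRMR feature-count and quantal-level parameters by a random-field
    -theory corrected search over the (F, Q) accuracy map, and
    likelihood-ratio fusion of automated and manual analysis streams with
    exact-binomial chance intervals.  A synthetic-cohort generator
    emulating the clinical covariate structure and lateralized temporal
    hypometabolism of such studies makes the whole pipeline testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
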