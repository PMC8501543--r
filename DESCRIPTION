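Package: ginsengAD
Title: Applicability-Domain-Gated Prediction of American Ginseng Cultivation Age
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for authenticating the cultivation age of
    American ginseng (Panax quinquefolium L.) roots from nine physicochemical
    features: HPLC-quantified contents of five ginsenosides (Rg1, Re, Rb1, Rd,
    pseudo-F11), ethanol and aqueous extractive percentages, root length and
    weight. Provides standard-curve calibration for saponin quantification,
    region-based train/test splitting, PCA distribution diagnostics, per-age
    trend summaries with pairwise Student's t-tests, grid-search
    cross-validated training of four regressors (elastic net, k-nearest
    neighbours, RBF support-vector regression, multi-layer perceptron), and a
    k-NN Euclidean-distance applicability domain that flags out-of-domain
    queries via the TAD/TS threshold rule, including the k-by-Z threshold
    scan and the inside/outside-domain error decomposition. A synthetic
    cohort generator reproduces the statistical structure of the study design
    so the full pipeline is testable without the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
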