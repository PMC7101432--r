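Package: petmodnet
Title: PET Radiomics Module Networks for Radiogenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline radiogenomics pipeline linking 18F-FDG PET radiomic
    features to tumor transcriptomics. Provides tumor delineation on SUV
    volumes (fixed-fraction thresholding and a fuzzy Gaussian-mixture
    segmenter), a 28-feature IBSI-style radiomics battery (intensity, shape,
    merged 13-direction co-occurrence and 26-connected size-zone textures),
    paired tumor-versus-normal microarray differential expression (normexp
    background correction, quantile normalization, replicate averaging,
    moderated paired t-statistics, Benjamini-Hochberg control), a
    module-network learner that groups genes into modules explained by
    threshold trees over normalized radiomic features (EM with a conjugate
    normal-gamma Bayesian score), and pathway over-representation with
    roll-up to top-level pathways. A synthetic-cohort generator (digital
    tumor phantoms plus planted expression modules) makes every stage
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    fgsea,
    RNifti,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
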