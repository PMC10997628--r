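Package: udip
Title: Unsupervised Deep-Learning Imaging Phenotypes for Brain-Image GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives latent imaging phenotypes (UDIPs) from 3D brain volumes
    with a background-masked 3D convolutional autoencoder, interprets each
    latent dimension by perturbation-based decoder interpretation (PerDI)
    with ranked-voxel Kolmogorov-Smirnov atlas enrichment, and runs the
    downstream genetic-association post-processing: covariate-adjusted
    association scans, minP aggregation across dimensions, genomic inflation
    factor, two-step LD clumping into loci, replication testing and
    sample-size-weighted meta-analysis. Ships a seeded synthetic-cohort
    generator (brain-like phantoms driven by known anatomical factors, a
    matching region atlas, and LD-structured genotypes with planted effects)
    so the whole pipeline is exercisable without external data. SVD-based
    CCA variance explained and cross-validated trait prediction quantify
    what the latents capture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    glmnet,
    pROC,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
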