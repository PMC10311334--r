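Package: transaug
Title: GAN-Based Data Augmentation and Generative-Quality Assessment for
    Transcriptomic Expression Data
Version: 0.1.0
Authors@R:
    person("transaug", "developers", email = "transaug@example.org",
           role = c("aut", "cre"))
Description: Tools for augmenting bulk gene-expression training sets with
    samples drawn from generative adversarial networks (plain GAN,
    conditional GAN, WGAN-GP, and a sparse attention GAN with softmin/L1
    attention restricted to masked gene pairs), together with a battery of
    generative-quality indicators (Frechet distance on classifier
    embeddings, k-NN manifold precision and recall, adversarial accuracy,
    correlation score, PCA cumulative-variance spectra), supervised
    augmentation-gain and reverse-validation harnesses, and a synthetic
    transcriptome simulator with tissue clusters, block-correlated gene
    groups and per-sample covariates so that every component is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
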