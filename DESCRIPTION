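Package: mirdiva
Title: Interpretable Pre-miRNA Descriptions via a Disentangled Variational Autoencoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes RNA hairpin sequences and their secondary structures as
    structured bar images and bond-strength vectors, learns a three-part
    disentangled latent representation with a DIVA-style variational
    autoencoder (conditional priors, inverse autoregressive flows and
    auxiliary classifiers), and grows a decision tree over the shape latent
    space using per-feature linear SVM splits to produce human-readable
    structural descriptions of the precursor-microRNA class. Includes a
    synthetic hairpin generator with planted structural features, an exact
    invertible image codec, reconstruction and classification metrics, and
    an end-to-end pipeline with latent-space visualisation helpers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    yaml,
    jsonlite,
    ggplot2,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
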