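Package: synthehr
Title: Synthetic Electronic Health Record Generation with Latent-Space
    Adversarial Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates privacy-preserving synthetic electronic health record
    (EHR) cohorts with a two-stage generative model: a masked sequential
    encoder-decoder compresses heterogeneous, variable-length, partially
    missing patient records into fixed-width latent states, and a Wasserstein
    GAN with gradient penalty is trained over those states. Numeric features
    are mapped to the unit interval by an exactly invertible
    frequency-proportional ("stochastic") normalization that is robust to
    skewed and discrete-jump distributions; categorical features pass through
    learned one-hot encoder/multi-head-decoder codecs; missingness masks and
    sequence lengths are modeled jointly with the values. The package also
    ships the matching evaluation suite (per-feature statistical similarity
    and Kolmogorov-Smirnov statistics, train-on-synthetic/test-on-real
    utility, random-feature-subset hypothesis tests, and membership-inference,
    re-identification and attribute-inference privacy attacks), a
    bucket-matching post-processor, and a seeded simulator of EHR-like
    cohorts for end-to-end testing without access to credentialed data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
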