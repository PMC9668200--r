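Package: g2phinet
Title: Genotype-Conditioned Operator Learning for Soft-Tissue Constitutive Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns class-conditioned biaxial stress-stretch constitutive
    relations of soft tissue with a two-stage encoder/decoder-operator
    architecture (branch encoder, branch decoder and trunk net), then infers
    both the full stress surface and the source genotype class of an unseen
    specimen from a handful of scattered stress measurements.  Includes a
    synthetic constitutive-data simulator built on a neo-Hookean plus
    four-fiber-family Fung-exponential strain-energy law, a physics-constrained
    (convexity-penalised) strain-energy surface fit that resamples scattered
    biaxial measurements onto a structured stretch grid, mixup regularisation
    over genotype labels, seeded multi-run training with late-stage
    checkpointing into ensembles, and simplex-constrained class-feature
    inference with ensemble averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
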