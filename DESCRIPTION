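Package: discordsig
Title: Decentralized Multi-Cohort Survival Gene Signatures via Hinge
    Discordance Loss
Version: 0.1.0
Authors@R:
    person("discordsig", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Trains multigene linear prognostic signatures across several
    gene-expression cohorts without pooling patients. Expression profiles
    are converted to intra-sample normalized percentile ranks so that any
    rank-preserving platform distortion leaves the features unchanged;
    candidate genes are prioritized by combining per-cohort concordance
    z-scores with Stouffer's meta-z method and a Benjamini-Hochberg cut;
    coefficients are estimated by minimizing a hinge-approximated survival
    discordance loss evaluated separately within each cohort (no patient is
    ever compared across cohorts) with a ridge penalty whose strength is
    chosen by leave-one-dataset-out cross-validation. Includes a synthetic
    multi-cohort survival data generator with known ground truth and a
    command-line interface covering simulation, transformation,
    prioritization, training and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
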