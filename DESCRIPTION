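Package: multikappa
Title: Chance-Corrected Agreement for Raters Selecting Multiple Categories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures inter-rater agreement when several raters may classify
    each subject into one or more nominal categories. Implements a
    generalization of Fleiss' kappa built from per-category observed and
    expected pairwise agreement, with optional category weights, hierarchical
    category dependencies expressed as boolean selectability rules, varying
    numbers of raters per subject, and an opt-in correction for the
    always-selected-category paradox. Includes bootstrap Interval Membership
    Probability (IMP) benchmarking against the Landis-Koch (or any custom)
    agreement scale, four comparator methods from the literature (averaged and
    pooled Cohen's kappa, proportional overlap, chance-corrected intraclass
    correlation, chance-corrected rank correlation), packaged worked-example
    datasets, a synthetic ratings generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
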