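Package: vacompare
Title: Probabilistic Verbal Autopsy Interpretation and Method Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpreting verbal autopsy (VA) records with an
    InterVA-style Bayesian cause-of-death engine, harmonizing physician and
    model cause assignments into broad cause groups, and quantifying
    agreement between interpretation methods via percent agreement, Cohen's
    kappa, and cause-specific mortality fraction (CSMF) comparisons.
    Includes a synthetic-cohort generator with known true CSMF, Bernoulli
    indicator emission, structured missingness, and a three-physician
    coding panel reconciled by a two-of-three/consensus rule, so the whole
    pipeline can be exercised and validated without access to confidential
    surveillance data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
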