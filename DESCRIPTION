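Package: metaborank
Title: Consensus Metabolite Ranking, Pathway Over-Representation and
    Time-Course ANOVA for Factorial Plasma Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for untargeted plasma metabolomics studies with a
    factorial (group x intervention x time) design. Implements a consensus
    feature-selection workflow that aggregates four per-metabolite
    importance rankings (PCA variance-weighted loadings, PLS-DA variable
    importance in projection, empirical Bayes moderated-z posteriors, and
    random-forest permutation importance) by median rank, selects the
    top-K metabolites, tests the selected set's superfamily distribution
    against the annotated universe, and performs hypergeometric pathway
    over-representation analysis with Benjamini-Hochberg control.
    Per-metabolite two-way ANOVA over group and time with Tukey-corrected
    post-hoc contrasts supports time-course interrogation of candidate
    pathways. A synthetic peak-area generator emulating a two-age-group
    cecal-ligation-and-puncture study design, with known active pathways
    and attrition, makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
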