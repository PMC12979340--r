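Package: oatepisodes
Title: Constructing Opioid Agonist Therapy Episodes from Dispensation Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds opioid agonist therapy (OAT) treatment episodes from
    pharmacy dispensation records. Classifies the temporal relation between
    consecutive dispensation coverage intervals with Allen's interval algebra,
    resolves short overlaps with temporal margins, applies drug-specific
    permissible gaps to detect discontinuation, and emits typed episodes
    (monotherapy, transition, multitherapy, transition-multitherapy) together
    with dose segments and co-dispensation patterns. Includes logic-based
    cleaning rules for raw dispensation tables (split-dose consolidation,
    quantity-per-day repair, days-supply capping), hospitalization bridging,
    a seeded synthetic claims generator with ground-truth episodes, and
    reporting helpers for relation frequencies, episode-type distributions,
    and temporal-margin sensitivity.
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
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
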