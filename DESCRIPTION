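Package: nshldx
Title: Molecular Diagnosis Pipeline for Sporadic Non-Syndromic Hearing Loss Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variant prioritization and molecular diagnosis for simplex
    (sporadic) severe-to-profound non-syndromic hearing loss. Implements a
    six-step rare-variant filter cascade with a per-step audit trail,
    pedigree-aware inheritance mechanics (bi-allelic detection, trans/cis
    phase resolution from trios, de novo and hemizygous calls, dominant
    segregation checks), exome capture coverage-gap auditing over a deafness
    gene panel, consensus calling over paired read-depth CNV call sets, and
    per-subject diagnostic classification with cohort-level yield summaries.
    Includes a synthetic cohort generator (Hardy-Weinberg backgrounds,
    Mendelian trios, planted causal and decoy genotypes) so the whole
    pipeline is testable without any sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
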