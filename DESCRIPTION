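Package: tpprank
Title: Target Product Profile Matching and Ranking for Drug Pipeline Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritising candidate medicines in a research and
    development pipeline against target product profiles (TPPs). Screens a
    candidate registry with six exclusion rules, reconciles dual-reviewer TPP
    assessments with third-reviewer adjudication, computes weighted match
    scores over nine critical TPP criteria, assigns phase-specific
    high/medium/low potential ranks, and produces traffic-light matrices and
    pipeline landscape summaries. Includes a seeded synthetic registry
    generator with planted ground truth for end-to-end validation, bundled
    example registries for the pre-eclampsia pipeline, and a command-line
    interface.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
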