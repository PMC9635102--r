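#' Bundled example registries: the pre-eclampsia R&D pipeline
#'
#' Two small registries shipped with the package, covering the publicly
#' posted AIM (Accelerating Innovation for Mothers) pre-eclampsia pipeline
#' after eligibility screening:
#'
#' * `example_preclinical_registry()` — the 40 preclinical candidates
#'   retained for descriptive analysis, with name, medicine subclass,
#'   archetype and proposed indication(s) as printed in the published
#'   candidate tables. Five candidates are proposed for both prevention and
#'   treatment and appear once with both indications.
#' * `example_clinical_registry()` — the 32 unique candidates in clinical
#'   development retained for TPP matching: prevention candidates at phase
#'   III (10), II (5) and I (2), treatment candidates at phase III (4),
#'   II (9) and I (6); four candidates (esomeprazole, pravastatin, metformin,
#'   ozagrel) are under investigation for both indications.
#'
#' Product type, activity years, trial settings, cold-chain and WHO EML
#' annotations are illustrative editorial additions — the published tables
#' print only name, subclass, archetype, indication and phase. Preclinical
#' activity years are set so that 32/40 candidates are active at a 2021
#' reference (the published 80%/20% split); which candidates are inactive is
#' an arbitrary illustrative choice.
#'
#' The preclinical registry carries a `source_notes` attribute recording a
#' known discrepancy: the candidate tables yield 21 unique repurposed
#' candidates, while the accompanying summary text prints 20 (50%). The
#' fixture transcribes the table archetypes verbatim;
#' [categorize_preclinical()] propagates the note.
#'
#' @return A validated registry tibble.
#' @examples
#' nrow(example_preclinical_registry())
#' @export
example_preclinical_registry <- function() {
  path <- system.file("extdata", "preclinical_registry.csv", package = "tpprank",
                      mustWork = TRUE)
  reg <- read_registry(path)
  attr(reg, "source_notes") <- paste(
    "archetype column yields 21 unique repurposed candidates;",
    "the published summary text prints 20 (50%)"
  )
  reg
}

#' @rdname example_preclinical_registry
#' @export
example_clinical_registry <- function() {
  path <- system.file("extdata", "clinical_registry.csv", package = "tpprank",
                      mustWork = TRUE)
  read_registry(path)
}

#' Clinical candidate name lists by indication and phase
#'
#' The per-phase candidate lists used for TPP matching, split by indication,
#' as derived from [example_clinical_registry()]. Dual-indication candidates
#' appear in both indication lists, so
#' `unique_candidate_count(clinical_phase_lists())` is smaller than the sum
#' of list lengths.
#'
#' @return A named list of character vectors:
#'   `prevention_III`, `prevention_II`, `prevention_I`,
#'   `treatment_III`, `treatment_II`, `treatment_I`.
#' @examples
#' lengths(clinical_phase_lists())
#' @export
clinical_phase_lists <- function() {
  reg <- example_clinical_registry()
  pairs <- reg %>%
    select("name", "phase", "indications") %>%
    tidyr::unnest_longer("indications", values_to = "indication")
  out <- list()
  for (ind in c("prevention", "treatment")) {
    for (ph in c("III", "II", "I")) {
      out[[paste0(ind, "_", ph)]] <-
        pairs$name[pairs$indication == ind & pairs$phase == ph]
    }
  }
  out
}
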