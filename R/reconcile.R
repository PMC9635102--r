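#' Reconcile dual-reviewer assessments into match profiles
#'
#' TPP matching is performed by two reviewers (A and B) independently; where
#' they differ on a criterion, a third reviewer (the adjudicator) determines
#' the final level. `reconcile_assessments()` applies that rule per
#' candidate-indication-criterion: agreement takes the shared level
#' (provenance `"agreement"`); disagreement takes the adjudicator's level
#' (provenance `"adjudicated"`); disagreement with no adjudicator level is an
#' unresolved-conflict error naming the candidate and criterion. The rule is
#' symmetric in A and B.
#'
#' Criteria assessed by only one reviewer are also unresolved (the design
#' requires two independent reads); criteria assessed by neither reviewer are
#' simply absent from the profile and may be filled downstream (see
#' [rank_registry()]).
#'
#' @param assessments Long assessments tibble with reviewers `A`, `B` and
#'   optionally `adjudicator` (see [read_assessments()]).
#' @param criteria Criterion set; assessment rows outside it are rejected.
#' @return A long profile tibble: `candidate_id`, `indication`,
#'   `criterion_id`, `level`, `provenance`.
#' @examples
#' a <- tibble::tibble(
#'   candidate_id = "c1", indication = "prevention",
#'   reviewer_id = c("A", "B"), criterion_id = "efficacy",
#'   level = c("met_minimum", "met_minimum")
#' )
#' reconcile_assessments(a)
#' @export
reconcile_assessments <- function(assessments, criteria = tpp_criteria()) {
  assessments <- as_assessments(assessments)
  extra <- setdiff(unique(assessments$criterion_id), criteria$criterion_id)
  if (length(extra) > 0) {
    abort_tpp(paste0("Assessment criterion outside the configured set: ",
                     paste(extra, collapse = ", ")), "value")
  }
  wide <- assessments %>%
    tidyr::pivot_wider(names_from = "reviewer_id", values_from = "level")
  for (col in c("A", "B", "adjudicator")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_character_
  }
  unresolved <- wide %>%
    filter(is.na(.data$A) | is.na(.data$B) |
             (.data$A != .data$B & is.na(.data$adjudicator)))
  if (nrow(unresolved) > 0) {
    u <- unresolved[1, ]
    why <- if (is.na(u$A) || is.na(u$B)) {
      sprintf("only reviewer %s assessed it", if (is.na(u$A)) "B" else "A")
    } else {
      sprintf("reviewers disagree (%s vs %s) and no adjudicator level is given", u$A, u$B)
    }
    abort_tpp(sprintf(
      "Unresolved conflict for candidate '%s' (%s), criterion '%s': %s.",
      u$candidate_id, u$indication, u$criterion_id, why
    ), "conflict", conflicts = unresolved)
  }
  wide %>%
    mutate(
      level = if_else(.data$A == .data$B, .data$A, .data$adjudicator),
      provenance = if_else(.data$A == .data$B, "agreement", "adjudicated")
    ) %>%
    select("candidate_id", "indication", "criterion_id", "level", "provenance") %>%
    arrange(.data$candidate_id, .data$indication,
            match(.data$criterion_id, criteria$criterion_id))
}

#' Derive categorical criterion levels from registry attributes
#'
#' Three of the nine criteria can be read directly off registry attributes
#' rather than trial evidence: **setting** — trials in both HIC and LMIC is
#' met preferred, exactly one of the two is partially met, no stated setting
#' is unknown; **stability** — no cold-chain requirement is met preferred, a
#' cold-chain requirement is not met, unsure is unknown; **who_eml** — listed
#' on the WHO Essential Medicines List is met preferred, not listed is not
#' met.
#'
#' @param registry A registry tibble.
#' @return A long tibble: `candidate_id`, `criterion_id`, `level`
#'   (independent of indication).
#' @examples
#' reg <- as_registry(data.frame(
#'   candidate_id = "c1", name = "X", indications = "prevention",
#'   product_type = "drug", archetype = "new", phase = "I",
#'   trial_settings = "HIC;LMIC", requires_cold_chain = "no",
#'   on_who_eml = TRUE
#' ))
#' derive_categorical_levels(reg)
#' @export
derive_categorical_levels <- function(registry) {
  registry <- as_registry(registry)
  setting <- vapply(registry$trial_settings, function(ts) {
    n <- length(intersect(ts, c("HIC", "LMIC")))
    if (n == 2) "met_preferred" else if (n == 1) "partially_met" else "unknown"
  }, character(1))
  stability <- dplyr::case_match(
    registry$requires_cold_chain,
    "no" ~ "met_preferred",
    "yes" ~ "not_met",
    "unknown" ~ "unknown"
  )
  who_eml <- if_else(registry$on_who_eml, "met_preferred", "not_met")
  tibble(
    candidate_id = rep(registry$candidate_id, 3),
    criterion_id = rep(c("setting", "stability", "who_eml"),
                       each = nrow(registry)),
    level = c(setting, stability, who_eml)
  ) %>%
    arrange(match(.data$candidate_id, registry$candidate_id))
}
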