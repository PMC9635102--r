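#' Run the full candidate-prioritisation pipeline
#'
#' Orchestrates the end-to-end flow: screen the registry with the six
#' exclusion rules; for every retained candidate in clinical development
#' (phases I-IV), reconcile the dual-reviewer assessments per indication;
#' fill criteria with no reviewer record from registry attributes
#' ([derive_categorical_levels()]) and mark any remaining gaps `unknown`;
#' score each profile and assign the phase-specific rank. Reviewer-reconciled
#' levels always take precedence over derived levels — reviewers saw the
#' trial evidence the registry attributes only summarise. Dual-indication
#' candidates are ranked once per indication, so the ranked list can exceed
#' the number of unique candidates.
#'
#' @param registry A registry tibble (or data frame coercible via
#'   [as_registry()]).
#' @param assessments Long reviewer assessments ([read_assessments()]).
#' @param scheme A [tpp_scheme()].
#' @param reference_year Reference year for the activity classification
#'   carried in the ranked output.
#' @return A `tpp_ranking` object: list with `ranked` (one row per retained
#'   clinical candidate-indication pair: scores, completeness, rank),
#'   `profiles` (long reconciled levels with provenance), `screening`
#'   (the [apply_exclusions()] result), `scheme` and `reference_year`.
#'   `tidy()` returns the ranked tibble, `glance()` a one-row summary,
#'   `autoplot()` the traffic-light matrix.
#' @examples
#' reg <- as_registry(data.frame(
#'   candidate_id = "c1", name = "Metformin", indications = "prevention",
#'   product_type = "drug", archetype = "repurposed", phase = "II"
#' ))
#' asmt <- tidyr::crossing(
#'   candidate_id = "c1", indication = "prevention",
#'   reviewer_id = c("A", "B"), criterion_id = tpp_criteria()$criterion_id
#' )
#' asmt$level <- "met_preferred"
#' rk <- rank_registry(reg, asmt, reference_year = 2021)
#' tidy(rk)
#' @export
rank_registry <- function(registry, assessments, scheme = default_scheme(),
                          reference_year = as.integer(format(Sys.Date(), "%Y"))) {
  registry <- as_registry(registry)
  validate_scheme(scheme)
  screening <- apply_exclusions(registry)
  retained <- retained_candidates(screening)
  clinical <- retained %>% filter(.data$phase != "preclinical")

  pairs <- clinical %>%
    select("candidate_id", "name", "phase", "indications") %>%
    tidyr::unnest_longer("indications", values_to = "indication")

  if (nrow(pairs) == 0) {
    empty <- tibble(
      candidate_id = character(), name = character(), indication = character(),
      phase = character(), activity = character(), total_score = numeric(),
      max_attainable = numeric(), completeness = numeric(), rank = character()
    )
    return(new_tpp_ranking(empty, tibble(
      candidate_id = character(), indication = character(),
      criterion_id = character(), level = character(), provenance = character()
    ), screening, scheme, reference_year))
  }

  assessments <- as_assessments(assessments)
  relevant <- assessments %>%
    semi_join(pairs, by = c("candidate_id", "indication"))
  reviewed <- if (nrow(relevant) > 0) {
    tryCatch(
      reconcile_assessments(relevant, scheme$criteria),
      tpprank_conflict_error = function(e) {
        abort_tpp(paste0("rank_registry: ", conditionMessage(e)), "conflict")
      }
    )
  } else {
    tibble(candidate_id = character(), indication = character(),
           criterion_id = character(), level = character(), provenance = character())
  }

  derived <- derive_categorical_levels(clinical) %>%
    mutate(provenance = "derived")

  grid <- pairs %>%
    select("candidate_id", "indication") %>%
    tidyr::crossing(criterion_id = scheme$criteria$criterion_id)
  profiles <- grid %>%
    left_join(reviewed, by = c("candidate_id", "indication", "criterion_id")) %>%
    left_join(derived, by = c("candidate_id", "criterion_id"),
              suffix = c("", ".derived")) %>%
    mutate(
      provenance = dplyr::coalesce(.data$provenance,
                                   if_else(!is.na(.data$level.derived),
                                           .data$provenance.derived, "unassessed")),
      level = dplyr::coalesce(.data$level, .data$level.derived, "unknown")
    ) %>%
    select("candidate_id", "indication", "criterion_id", "level", "provenance")

  scored <- score_profiles(profiles, scheme)
  ranked <- pairs %>%
    left_join(scored, by = c("candidate_id", "indication")) %>%
    left_join(clinical %>% select("candidate_id", "last_activity_year"),
              by = "candidate_id") %>%
    mutate(
      activity = classify_activity(.data$last_activity_year, reference_year),
      rank = assign_rank(.data$total_score, .data$max_attainable, .data$phase, scheme)
    ) %>%
    select("candidate_id", "name", "indication", "phase", "activity",
           "total_score", "max_attainable", "completeness", "rank") %>%
    arrange(desc(match(.data$phase, c("I", "II", "III", "IV"))),
            desc(.data$total_score), .data$name, .data$indication)

  new_tpp_ranking(ranked, profiles, screening, scheme, reference_year)
}

new_tpp_ranking <- function(ranked, profiles, screening, scheme, reference_year) {
  structure(
    list(ranked = ranked, profiles = profiles, screening = screening,
         scheme = scheme, reference_year = reference_year),
    class = "tpp_ranking"
  )
}

#' @export
print.tpp_ranking <- function(x, ...) {
  fc <- screening_flowchart(x$screening)
  cnt <- function(stage) fc$count[fc$stage == stage]
  cat("<tpp_ranking>\n")
  cat(sprintf("  screened: %d input, %d excluded, %d retained\n",
              cnt("input"), cnt("excluded_total"), cnt("retained")))
  cat(sprintf("  ranked: %d candidate-indication pair(s): %d high, %d medium, %d low\n",
              nrow(x$ranked), sum(x$ranked$rank == "high"),
              sum(x$ranked$rank == "medium"), sum(x$ranked$rank == "low")))
  if (nrow(x$ranked) > 0) print(head(x$ranked, 10))
  invisible(x)
}

#' @export
tidy.tpp_ranking <- function(x, ...) x$ranked

#' @export
glance.tpp_ranking <- function(x, ...) {
  fc <- screening_flowchart(x$screening)
  cnt <- function(stage) fc$count[fc$stage == stage]
  tibble(
    n_input = cnt("input"),
    n_excluded = cnt("excluded_total"),
    n_retained = cnt("retained"),
    n_ranked = nrow(x$ranked),
    n_unique_ranked = dplyr::n_distinct(tolower(trimws(x$ranked$name))),
    n_high = sum(x$ranked$rank == "high"),
    n_medium = sum(x$ranked$rank == "medium"),
    n_low = sum(x$ranked$rank == "low"),
    mean_completeness = if (nrow(x$ranked) > 0) mean(x$ranked$completeness) else NA_real_
  )
}

#' @export
autoplot.tpp_ranking <- function(object, ...) {
  autoplot(build_matrix(object$profiles, object$ranked), ...)
}

#' Write ranked candidates to CSV
#'
#' One row per candidate-indication pair with per-criterion reconciled
#' levels (wide), total and maximum attainable scores, completeness and
#' rank.
#'
#' @param ranking A `tpp_ranking` from [rank_registry()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_ranked <- function(ranking, path) {
  stopifnot(inherits(ranking, "tpp_ranking"))
  wide <- ranking$profiles %>%
    select("candidate_id", "indication", "criterion_id", "level") %>%
    tidyr::pivot_wider(names_from = "criterion_id", values_from = "level")
  out <- ranking$ranked %>%
    left_join(wide, by = c("candidate_id", "indication"))
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
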