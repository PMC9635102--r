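#' Score match profiles against a scoring scheme
#'
#' For one candidate-indication profile the total score is the weighted sum
#' over criteria of the numeric score of its match level,
#' `sum_c weight(c) * level_scores(level(c))`; the maximum attainable score
#' is the same sum with every level at `met_preferred`; completeness is the
#' fraction of criteria with an informative (non-unknown) level. Every
#' criterion of the scheme must be present in the profile.
#'
#' @param profiles Long profile tibble (`candidate_id`, `indication`,
#'   `criterion_id`, `level`), e.g. from [reconcile_assessments()].
#' @param scheme A [tpp_scheme()].
#' @return A tibble with one row per candidate-indication pair:
#'   `candidate_id`, `indication`, `total_score`, `max_attainable`,
#'   `completeness`.
#' @examples
#' prof <- tidyr::crossing(
#'   candidate_id = "c1", indication = "treatment",
#'   criterion_id = tpp_criteria()$criterion_id
#' )
#' prof$level <- "met_preferred"
#' score_profiles(prof, default_scheme())
#' @export
score_profiles <- function(profiles, scheme = default_scheme()) {
  # structural checks only: full invariant validation happens at scheme
  # construction, and hand-built schemes (e.g. uniform weights) may
  # deliberately relax the default up-weighting
  if (!inherits(scheme, "tpp_scheme")) {
    abort_tpp("`scheme` must be a tpp_scheme object.", "value")
  }
  if (!all(match_levels() %in% names(scheme$level_scores))) {
    abort_tpp("scheme$level_scores must cover all five match levels.", "schema")
  }
  profiles <- as_tibble(profiles)
  need <- c("candidate_id", "indication", "criterion_id", "level")
  miss <- setdiff(need, names(profiles))
  if (length(miss) > 0) {
    abort_tpp(paste0("Profiles missing column(s): ", paste(miss, collapse = ", ")), "schema")
  }
  bad_lv <- setdiff(unique(profiles$level), match_levels())
  if (length(bad_lv) > 0) {
    abort_tpp(paste0("Invalid match level(s): ", paste(bad_lv, collapse = ", ")), "value")
  }
  bad_cr <- setdiff(unique(profiles$criterion_id), scheme$criteria$criterion_id)
  if (length(bad_cr) > 0) {
    abort_tpp(paste0("Profile criterion outside the scheme: ",
                     paste(bad_cr, collapse = ", ")), "value")
  }
  coverage <- profiles %>%
    distinct(.data$candidate_id, .data$indication, .data$criterion_id) %>%
    count(.data$candidate_id, .data$indication)
  gaps <- coverage %>% filter(.data$n < nrow(scheme$criteria))
  if (nrow(gaps) > 0) {
    have <- profiles %>%
      filter(.data$candidate_id == gaps$candidate_id[1],
             .data$indication == gaps$indication[1]) %>%
      pull("criterion_id")
    abort_tpp(sprintf(
      "Profile for candidate '%s' (%s) does not cover criterion: %s.",
      gaps$candidate_id[1], gaps$indication[1],
      paste(setdiff(scheme$criteria$criterion_id, have), collapse = ", ")
    ), "coverage")
  }
  max_att <- sum(scheme$criteria$weight) * scheme$level_scores[["met_preferred"]]
  profiles %>%
    left_join(scheme$criteria %>% select("criterion_id", "weight"), by = "criterion_id") %>%
    mutate(score = .data$weight * unname(scheme$level_scores[.data$level])) %>%
    group_by(.data$candidate_id, .data$indication) %>%
    summarise(
      total_score = sum(.data$score),
      max_attainable = max_att,
      completeness = mean(.data$level != "unknown"),
      .groups = "drop"
    )
}

#' Assign a high/medium/low potential rank
#'
#' The rank is a pure function of the normalised score
#' `r = total_score / max_attainable` and the phase-specific thresholds:
#' high when `r >= high(phase)`, medium when `medium(phase) <= r <
#' high(phase)`, low otherwise. Both cutoffs are inclusive at the lower edge,
#' so a score landing exactly on a cutoff takes the better rank.
#' Preclinical candidates are described, not ranked, and raise an error.
#'
#' @param total_score,max_attainable Numeric vectors (recycled to a common
#'   length); `max_attainable` must be positive.
#' @param phase Character vector of phases in `I`, `II`, `III`, `IV`.
#' @param scheme A [tpp_scheme()] providing the thresholds.
#' @return Character vector of ranks: `"high"`, `"medium"` or `"low"`.
#' @examples
#' assign_rank(c(33, 10, 0), 33, "II")
#' @export
assign_rank <- function(total_score, max_attainable, phase, scheme = default_scheme()) {
  validate_scheme(scheme)
  n <- max(length(total_score), length(max_attainable), length(phase))
  total_score <- rep_len(total_score, n)
  max_attainable <- rep_len(max_attainable, n)
  phase <- rep_len(phase, n)
  if (any(phase == "preclinical")) {
    abort_tpp("Preclinical candidates are not rankable against the TPP criteria.", "not_rankable")
  }
  bad <- setdiff(unique(phase), scheme$thresholds$phase)
  if (length(bad) > 0) {
    abort_tpp(paste0("No thresholds configured for phase: ", paste(bad, collapse = ", ")), "value")
  }
  if (any(!is.finite(max_attainable)) || any(max_attainable <= 0)) {
    abort_tpp("max_attainable must be positive.", "value")
  }
  r <- total_score / max_attainable
  idx <- match(phase, scheme$thresholds$phase)
  hi <- scheme$thresholds$high[idx]
  med <- scheme$thresholds$medium[idx]
  dplyr::case_when(r >= hi ~ "high", r >= med ~ "medium", .default = "low")
}
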