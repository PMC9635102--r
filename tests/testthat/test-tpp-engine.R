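full_profile <- function(level, candidate_id = "c1", indication = "treatment") {
  tidyr::crossing(candidate_id = candidate_id, indication = indication,
                  criterion_id = tpp_criteria()$criterion_id) |>
    dplyr::mutate(level = level)
}

test_that("reviewer agreement and adjudication reconcile as specified", {
  pair <- function(a, b, adj = NULL, criterion = "efficacy") {
    rows <- tibble::tibble(
      candidate_id = "c1", indication = "treatment",
      reviewer_id = c("A", "B"), criterion_id = criterion, level = c(a, b)
    )
    if (!is.null(adj)) {
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        candidate_id = "c1", indication = "treatment",
        reviewer_id = "adjudicator", criterion_id = criterion, level = adj
      ))
    }
    rows
  }
  # agreement
  out <- reconcile_assessments(pair("met_minimum", "met_minimum"))
  expect_equal(out$level, "met_minimum")
  expect_equal(out$provenance, "agreement")
  # adjudicator decides a disagreement
  out <- reconcile_assessments(pair("met_preferred", "partially_met", "met_minimum",
                                    criterion = "safety"))
  expect_equal(out$level, "met_minimum")
  expect_equal(out$provenance, "adjudicated")
  # disagreement without adjudicator names the criterion
  expect_error(
    reconcile_assessments(pair("met_preferred", "not_met")),
    regexp = "efficacy", class = "tpprank_conflict_error"
  )
})

test_that("reconciliation is symmetric in the two reviewers", {
  a <- random_profiles(5, seed = 31) |> dplyr::mutate(reviewer_id = "A")
  b <- random_profiles(5, seed = 32) |> dplyr::mutate(reviewer_id = "B")
  adj <- random_profiles(5, seed = 33) |> dplyr::mutate(reviewer_id = "adjudicator")
  asmt <- dplyr::bind_rows(a, b, adj)
  swapped <- asmt |>
    dplyr::mutate(reviewer_id = dplyr::case_match(reviewer_id,
                                                  "A" ~ "B", "B" ~ "A",
                                                  .default = reviewer_id))
  expect_equal(reconcile_assessments(asmt), reconcile_assessments(swapped))
})

test_that("categorical levels derive from registry attributes", {
  reg <- make_registry(
    5,
    trial_settings = c("HIC;LMIC", "HIC", "LMIC", "", "HIC"),
    requires_cold_chain = c("no", "yes", "unknown", "no", "unknown"),
    on_who_eml = c(TRUE, FALSE, FALSE, TRUE, FALSE)
  )
  lv <- derive_categorical_levels(reg) |>
    tidyr::pivot_wider(names_from = "criterion_id", values_from = "level")
  expect_equal(lv$setting, c("met_preferred", "partially_met", "partially_met",
                             "unknown", "partially_met"))
  expect_equal(lv$stability, c("met_preferred", "not_met", "unknown",
                               "met_preferred", "unknown"))
  expect_equal(lv$who_eml, c("met_preferred", "not_met", "not_met",
                             "met_preferred", "not_met"))
})

test_that("profile scoring matches the hand-summed fixtures", {
  sc <- default_scheme()
  # all nine not met: zero
  out <- score_profiles(full_profile("not_met"), sc)
  expect_equal(out$total_score, 0)
  # all nine met preferred: 3 * (2 + 2 + 7) = 33, completeness 1
  out <- score_profiles(full_profile("met_preferred"), sc)
  expect_equal(out$total_score, 33)
  expect_equal(out$max_attainable, 33)
  expect_equal(out$completeness, 1)
  # only efficacy met minimum (weight 2 x score 2 = 4), rest unknown
  prof <- full_profile("unknown") |>
    dplyr::mutate(level = ifelse(criterion_id == "efficacy", "met_minimum", level))
  out <- score_profiles(prof, sc)
  expect_equal(out$total_score, 4)
  expect_equal(out$completeness, 1 / 9)
})

test_that("a profile missing a criterion raises a coverage error", {
  prof <- full_profile("met_minimum") |> dplyr::filter(criterion_id != "stability")
  expect_error(score_profiles(prof, default_scheme()),
               regexp = "stability", class = "tpprank_coverage_error")
})

test_that("scoring equals the brute-force oracle on random profiles", {
  sc <- default_scheme()
  profiles <- random_profiles(200, seed = 41)
  got <- score_profiles(profiles, sc) |> dplyr::arrange(candidate_id)
  want <- profiles |>
    dplyr::group_by(candidate_id) |>
    dplyr::group_map(function(d, key) {
      lv <- stats::setNames(d$level, d$criterion_id)
      tibble::tibble(candidate_id = key$candidate_id, oracle = oracle_score(lv, sc))
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(candidate_id)
  expect_equal(got$total_score, want$oracle)
})

test_that("raising any single criterion level never decreases the score", {
  sc <- default_scheme()
  profiles <- random_profiles(50, seed = 42)
  base <- score_profiles(profiles, sc)
  ladder <- informative_levels()
  for (cid in tpp_criteria()$criterion_id) {
    upgraded <- profiles |>
      dplyr::mutate(level = ifelse(
        criterion_id == cid & level %in% ladder[-length(ladder)],
        ladder[match(level, ladder) + 1], level
      ))
    up <- score_profiles(upgraded, sc)
    expect_true(all(up$total_score >= base$total_score))
  }
})

test_that("with equal weights and a uniform level, score is 9 * w * level score", {
  w <- 1.5
  crit <- tpp_criteria() |> dplyr::mutate(weight = w)
  # equal weights violate the efficacy/safety up-weight invariant, so build
  # the scheme without that constraint by construction
  sc <- default_scheme()
  sc$criteria <- crit
  for (lv in informative_levels()) {
    out <- score_profiles(full_profile(lv), sc)
    expect_equal(out$total_score, 9 * w * sc$level_scores[[lv]])
  }
})

test_that("rank thresholds are inclusive and phase-specific", {
  sc <- default_scheme()
  expect_equal(assign_rank(33, 33, "II", sc), "high")
  expect_equal(assign_rank(0, 33, "I", sc), "low")
  # exactly at the high cutoff: 0.6 * 33 = 19.8
  expect_equal(assign_rank(19.8, 33, "III", sc), "high")
  # exactly at the medium cutoff
  expect_equal(assign_rank(0.4 * 33, 33, "IV", sc), "medium")
  # just below medium
  expect_equal(assign_rank(0.4 * 33 - 1e-9, 33, "IV", sc), "low")
  # rank is non-decreasing in the score at fixed phase
  scores <- seq(0, 33, by = 0.5)
  ranks <- assign_rank(scores, 33, "II", sc)
  ord <- c(low = 1, medium = 2, high = 3)
  expect_true(all(diff(ord[ranks]) >= 0))
})

test_that("preclinical candidates are not rankable", {
  expect_error(assign_rank(10, 33, "preclinical"),
               class = "tpprank_not_rankable_error")
})

test_that("scheme invariants are enforced", {
  # non-monotone level scores
  expect_error(
    tpp_scheme(level_scores = c(not_met = 3, partially_met = 1, met_minimum = 2,
                                met_preferred = 3, unknown = 0)),
    class = "tpprank_value_error"
  )
  # efficacy/safety must outweigh the rest
  expect_error(
    tpp_scheme(criteria = dplyr::mutate(tpp_criteria(), weight = 1)),
    class = "tpprank_value_error"
  )
  # thresholds must satisfy medium < high
  expect_error(
    tpp_scheme(thresholds = tibble::tibble(phase = c("I", "II", "III", "IV"),
                                           high = 0.4, medium = 0.6)),
    class = "tpprank_value_error"
  )
})

test_that("scheme configurations round-trip through YAML and JSON", {
  sc <- tpp_scheme(
    level_scores = c(not_met = 0, partially_met = 2, met_minimum = 3,
                     met_preferred = 5, unknown = 0),
    criteria = dplyr::mutate(tpp_criteria(),
                             weight = ifelse(criterion_id %in% c("efficacy", "safety"), 3, 1)),
    thresholds = tibble::tibble(phase = c("I", "II", "III", "IV"),
                                high = c(0.5, 0.55, 0.6, 0.6),
                                medium = c(0.3, 0.35, 0.4, 0.4))
  )
  for (fmt in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = fmt)
    write_scheme(sc, path)
    back <- read_scheme(path)
    expect_equal(back$level_scores, sc$level_scores)
    expect_equal(as.data.frame(back$criteria), as.data.frame(sc$criteria))
    expect_equal(dplyr::arrange(back$thresholds, phase),
                 dplyr::arrange(sc$thresholds, phase))
  }
})
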