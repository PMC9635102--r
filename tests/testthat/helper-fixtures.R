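# Shared in-code fixtures and independent oracles.

# Minimal valid registry rows; override any column via ...
make_registry <- function(n = 3, phase = "II", indications = "treatment", ...) {
  df <- tibble::tibble(
    candidate_id = sprintf("c%02d", seq_len(n)),
    name = sprintf("Candidate %02d", seq_len(n)),
    indications = rep_len(indications, n),
    product_type = "drug",
    archetype = "repurposed",
    phase = rep_len(phase, n)
  )
  extra <- list(...)
  for (col in names(extra)) df[[col]] <- rep_len(extra[[col]], n)
  as_registry(df)
}

# Full dual-reviewer assessment set for given pairs, all at one level.
make_assessments <- function(candidate_id, indication = "treatment",
                             level = "met_preferred",
                             reviewers = c("A", "B"),
                             criteria = tpp_criteria()$criterion_id) {
  tidyr::crossing(
    candidate_id = candidate_id, indication = indication,
    reviewer_id = reviewers, criterion_id = criteria
  ) |>
    dplyr::mutate(level = rep_len(level, dplyr::n()))
}

# Random registry with random screening flags, for property tests.
random_registry <- function(n, seed) {
  withr::with_seed(seed, {
    df <- tibble::tibble(
      candidate_id = sprintf("r%03d", seq_len(n)),
      name = sprintf("Rand %03d", seq_len(n)),
      indications = sample(c("prevention", "treatment", "prevention;treatment"),
                           n, replace = TRUE),
      product_type = sample(c("drug", "dietary", "biological"), n, replace = TRUE),
      archetype = sample(c("new", "repurposed"), n, replace = TRUE),
      phase = sample(c("I", "II", "III", "IV"), n, replace = TRUE)
    )
    for (fl in c("approved_for_indication", "recommended_or_routine_use",
                 "recommended_for_subgroup_only", "inactive_negative_outcome",
                 "targets_symptom_only", "inferior_to_current")) {
      df[[fl]] <- runif(n) < 0.2
    }
    as_registry(df)
  })
}

# Random long profiles over the full criterion set.
random_profiles <- function(n_profiles, seed, unknown_rate = 0.15) {
  withr::with_seed(seed, {
    crit <- tpp_criteria()$criterion_id
    tidyr::crossing(
      candidate_id = sprintf("p%04d", seq_len(n_profiles)),
      indication = "treatment",
      criterion_id = crit
    ) |>
      dplyr::mutate(level = ifelse(
        runif(dplyr::n()) < unknown_rate, "unknown",
        sample(informative_levels(), dplyr::n(), replace = TRUE)
      ))
  })
}

# Independent brute-force scoring oracle: plain loop, no dplyr, no shared
# code path with score_profiles().
oracle_score <- function(levels_named, scheme = default_scheme()) {
  total <- 0
  for (cid in scheme$criteria$criterion_id) {
    w <- scheme$criteria$weight[scheme$criteria$criterion_id == cid]
    total <- total + w * scheme$level_scores[[levels_named[[cid]]]]
  }
  total
}
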