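test_that("generation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_candidates = 60, seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_registry(cfg), d1)
  write_simulation(simulate_registry(cfg), d2)
  for (f in c("registry.csv", "assessments.csv", "truth.json")) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))))
  }
  # and a different seed gives different data
  other <- simulate_registry(synthetic_config(n_candidates = 60, seed = 100))
  expect_false(identical(other$registry$phase,
                         simulate_registry(cfg)$registry$phase))
})

test_that("zero disagreement makes reviewers A and B identical", {
  sim <- simulate_registry(synthetic_config(
    n_candidates = 50, reviewer_disagreement_rate = 0, seed = 5
  ))
  wide <- sim$assessments |>
    tidyr::pivot_wider(names_from = "reviewer_id", values_from = "level")
  expect_equal(wide$A, wide$B)
  expect_equal(wide$A, wide$adjudicator)
})

test_that("planted profiles land strictly inside their rank band", {
  sc <- default_scheme()
  sim <- simulate_registry(synthetic_config(n_candidates = 120, seed = 8), sc)
  scored <- score_profiles(sim$truth$profiles, sc)
  joined <- dplyr::inner_join(scored, sim$truth$ranks,
                              by = c("candidate_id", "indication"))
  got <- assign_rank(joined$total_score, joined$max_attainable, joined$phase, sc)
  expect_equal(got, joined$planted_rank)
})

test_that("noiseless generation is recovered exactly by the pipeline", {
  cfg <- synthetic_config(n_candidates = 80, reviewer_disagreement_rate = 0,
                          unknown_rate = 0, seed = 17)
  sim <- simulate_registry(cfg)
  rk <- rank_registry(sim$registry, sim$assessments, reference_year = 2021)
  m <- dplyr::inner_join(tidy(rk), sim$truth$ranks,
                         by = c("candidate_id", "indication"))
  expect_equal(nrow(m), nrow(sim$truth$ranks))
  expect_equal(m$rank, m$planted_rank)
  expect_true(all(tidy(rk)$completeness == 1))
})

test_that("reviewer disagreement with a truthful adjudicator still recovers ranks", {
  cfg <- synthetic_config(n_candidates = 80, reviewer_disagreement_rate = 0.3,
                          seed = 18)
  sim <- simulate_registry(cfg)
  rk <- rank_registry(sim$registry, sim$assessments, reference_year = 2021)
  m <- dplyr::inner_join(tidy(rk), sim$truth$ranks,
                         by = c("candidate_id", "indication"))
  expect_equal(mean(m$rank == m$planted_rank), 1)
})

test_that("empirical mixes concentrate around the configured ones", {
  # a registry-only config large enough for tight binomial concentration;
  # all mass clinical so no preclinical rejection work is wasted
  cfg <- synthetic_config(
    n_candidates = 10000,
    phase_mix = c(preclinical = 0.3, I = 0.1, II = 0.2, III = 0.35, IV = 0.05),
    exclusion_trigger_rate = 1, # everything excluded: no profiles to sample
    seed = 23
  )
  sim <- simulate_registry(cfg)
  expect_lt(empirical_mix_check(sim$registry, cfg), 0.03)

  # degenerate mix puts all mass on one phase with zero deviation on that axis
  cfg2 <- synthetic_config(
    n_candidates = 60,
    phase_mix = c(preclinical = 0, I = 0, II = 0, III = 1, IV = 0),
    exclusion_trigger_rate = 1, seed = 24
  )
  sim2 <- simulate_registry(cfg2)
  expect_true(all(sim2$registry$phase == "III"))

  # single-candidate registries are trivially bounded by 1
  cfg3 <- synthetic_config(n_candidates = 1, exclusion_trigger_rate = 1, seed = 25)
  expect_lte(empirical_mix_check(simulate_registry(cfg3)$registry, cfg3), 1)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_candidates = 0), class = "tpprank_value_error")
  expect_error(synthetic_config(phase_mix = c(preclinical = 0.5, I = 0.2, II = 0.2,
                                              III = 0.2, IV = 0.2)),
               class = "tpprank_value_error")
  expect_error(synthetic_config(reviewer_disagreement_rate = 1.2),
               class = "tpprank_value_error")
  expect_error(synthetic_config(planted_rank_mix = c(high = 1)),
               class = "tpprank_schema_error")
})

test_that("an empty threshold band raises an infeasible-config error", {
  # high band [0.999, 1] is unreachable with unknowns forced everywhere
  sc <- tpp_scheme(thresholds = tibble::tibble(
    phase = c("I", "II", "III", "IV"), high = 0.999, medium = 0.99
  ))
  cfg <- synthetic_config(
    n_candidates = 30,
    phase_mix = c(preclinical = 0, I = 0, II = 1, III = 0, IV = 0),
    exclusion_trigger_rate = 0,
    planted_rank_mix = c(high = 1, medium = 0, low = 0),
    unknown_rate = 1, seed = 31
  )
  expect_error(simulate_registry(cfg, sc),
               class = "tpprank_infeasible_config_error")
})
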