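test_that("phase percentages follow hand arithmetic", {
  reg <- make_registry(4, phase = c("preclinical", "I", "III", "III"),
                       preclinical_subclass = c("herbal", NA, NA, NA))
  sm <- summarize_pipeline(reg, 2021)
  ph <- dplyr::filter(sm, axis == "phase")
  expect_equal(ph$percent[ph$category == "preclinical"], 25.0)
  expect_equal(ph$percent[ph$category == "I"], 25.0)
  expect_equal(ph$percent[ph$category == "III"], 50.0)
  expect_equal(sum(ph$count), attr(sm, "denominator"))
})

test_that("degenerate axes give 100 percent and empty input errors", {
  reg <- make_registry(3, phase = "II")
  sm <- summarize_pipeline(reg, 2021)
  pt <- dplyr::filter(sm, axis == "product_type")
  expect_equal(pt$percent[pt$category == "drug"], 100.0)
  expect_true(all(pt$count[pt$category != "drug"] == 0))

  one <- summarize_pipeline(make_registry(1), 2021)
  nonzero <- dplyr::filter(one, count > 0)
  expect_true(all(nonzero$percent == 100.0))

  expect_error(summarize_pipeline(make_registry(1)[0, ], 2021),
               class = "tpprank_empty_input_error")
})

test_that("each summary axis conserves counts and rounded percentages", {
  reg <- random_registry(37, seed = 51)
  sm <- summarize_pipeline(reg, 2021)
  for (ax in unique(sm$axis)) {
    d <- dplyr::filter(sm, axis == ax)
    expect_equal(sum(d$count), nrow(reg))
    expect_lt(abs(sum(d$percent) - 100), 0.3)
    # rounding never turns a zero count nonzero or vice versa
    expect_equal(d$count == 0, d$percent == 0)
  }
})

test_that("preclinical taxonomy counts dual-indication candidates once", {
  reg <- make_registry(1, phase = "preclinical",
                       indications = "prevention;treatment",
                       preclinical_subclass = "polyphenol")
  tx <- categorize_preclinical(reg)
  expect_equal(tx$denominator, 1)
  ind <- stats::setNames(tx$indication$count, tx$indication$membership)
  expect_equal(unname(ind["prevention_only"]), 0)
  expect_equal(unname(ind["treatment_only"]), 0)
  expect_equal(unname(ind["both"]), 1)
})

test_that("non-preclinical candidates are a scope error", {
  reg <- make_registry(2, phase = c("preclinical", "II"),
                       preclinical_subclass = c("herbal", NA))
  expect_error(categorize_preclinical(reg), class = "tpprank_scope_error")
})

test_that("bundled preclinical registry reproduces the published taxonomy", {
  tx <- categorize_preclinical(example_preclinical_registry())
  expect_equal(tx$denominator, 40)
  ind <- stats::setNames(tx$indication$count, tx$indication$membership)
  expect_equal(unname(ind[c("prevention_only", "treatment_only", "both")]),
               c(11, 24, 5))
  sub <- stats::setNames(tx$subclass$count, tx$subclass$subclass)
  expect_equal(unname(sub["amino acid-peptide"]), 7)
  expect_equal(unname(sub["polyphenol"]), 7)
  expect_equal(unname(sub["DNA/siRNA/mRNA"]), 5)
  expect_equal(sum(tx$subclass$count), 40)
  # table-derived archetype count, with the discrepancy noted in metadata
  arch <- stats::setNames(tx$archetype$count, tx$archetype$archetype)
  expect_equal(unname(arch["repurposed"]), 21)
  expect_match(tx$notes, "21 unique repurposed")
})

test_that("unique candidate counting is a normalised set union", {
  # case and whitespace are normalised; no fuzzy merging
  expect_equal(unique_candidate_count(c("Metformin", "Ozagrel"),
                                      c(" metformin", "Tadalafil")), 3)
  expect_equal(unique_candidate_count(c("a", "b", "c"), c("d", "e", "f", "g")), 7)
  expect_equal(unique_candidate_count(c("a", "b"), c("a", "b")), 2)
  expect_equal(unique_candidate_count(list()), 0)
  expect_equal(unique_candidate_count(c("chloroquine"), c("hydroxychloroquine")), 2)

  # |A union B| = |A| + |B| - |A intersect B| against brute-force sets
  withr::with_seed(61, {
    for (i in 1:20) {
      a <- sample(letters, sample(1:15, 1))
      b <- sample(letters, sample(1:15, 1))
      expect_equal(unique_candidate_count(a, b),
                   length(a) + length(b) - length(intersect(a, b)))
    }
  })
})

test_that("the six clinical phase lists have the published sizes", {
  lists <- clinical_phase_lists()
  expect_equal(unname(lengths(lists)),
               c(10L, 5L, 2L, 4L, 9L, 6L))
  expect_equal(unique_candidate_count(lists), 32)
})

test_that("summary exports to tidy CSV and nested JSON", {
  reg <- make_registry(4, phase = c("I", "II", "III", "IV"))
  sm <- summarize_pipeline(reg, 2021)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_summary(sm, csv)
  write_summary(sm, js)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(sm))
  nested <- jsonlite::fromJSON(js)
  expect_equal(nested$denominator, 4)
  expect_equal(nested$phase$II$count, 1)
})
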