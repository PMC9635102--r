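#' Configuration for the synthetic registry generator
#'
#' Defines the statistical shape of a simulated candidate registry. Defaults
#' mirror the published pre-eclampsia pipeline margins: phases 66/11/32/43/1
#' of 153 (preclinical through IV), product types 90 drug / 38 dietary / 25
#' biological, archetypes 38 new / 115 repurposed, planted rank mix 7 high /
#' 8 medium / 21 low of 36 ranked pairs, a per-rule exclusion trigger of
#' 0.15 (six independent rules give roughly the observed 63% clinical
#' exclusion rate), reviewer disagreement 0.1 per criterion and unknown
#' evidence 0.1 per criterion.
#'
#' @param n_candidates Number of candidates (>= 1).
#' @param phase_mix,product_type_mix,archetype_mix Named probability vectors
#'   over the respective category sets; must sum to 1.
#' @param exclusion_trigger_rate Probability that each of the six exclusion
#'   flags is set, independently per rule and candidate.
#' @param planted_rank_mix Named probability vector over
#'   `high`/`medium`/`low`.
#' @param reviewer_disagreement_rate Probability, per criterion, that
#'   reviewer B's level differs from the truth.
#' @param unknown_rate Probability, per criterion, that the true level is
#'   `unknown`.
#' @param p_both_indications Probability a candidate is proposed for both
#'   prevention and treatment.
#' @param seed Integer seed; the generator is fully reproducible from it
#'   (Mersenne-Twister, inversion normals, rejection sampling).
#' @return A validated `tpp_synth_config` list.
#' @export
synthetic_config <- function(n_candidates = 153,
                             phase_mix = c(preclinical = 66, I = 11, II = 32,
                                           III = 43, IV = 1) / 153,
                             product_type_mix = c(drug = 90, dietary = 38,
                                                  biological = 25) / 153,
                             archetype_mix = c(new = 38, repurposed = 115) / 153,
                             exclusion_trigger_rate = 0.15,
                             planted_rank_mix = c(high = 7, medium = 8, low = 21) / 36,
                             reviewer_disagreement_rate = 0.1,
                             unknown_rate = 0.1,
                             p_both_indications = 0.12,
                             seed = 1L) {
  cfg <- list(
    n_candidates = as.integer(n_candidates), phase_mix = phase_mix,
    product_type_mix = product_type_mix, archetype_mix = archetype_mix,
    exclusion_trigger_rate = exclusion_trigger_rate,
    planted_rank_mix = planted_rank_mix,
    reviewer_disagreement_rate = reviewer_disagreement_rate,
    unknown_rate = unknown_rate, p_both_indications = p_both_indications,
    seed = as.integer(seed)
  )
  if (is.na(cfg$n_candidates) || cfg$n_candidates < 1) {
    abort_tpp("n_candidates must be >= 1.", "value")
  }
  mixes <- list(phase_mix = c("preclinical", "I", "II", "III", "IV"),
                product_type_mix = registry_enum$product_type,
                archetype_mix = registry_enum$archetype,
                planted_rank_mix = c("high", "medium", "low"))
  for (nm in names(mixes)) {
    v <- cfg[[nm]]
    if (!setequal(names(v), mixes[[nm]])) {
      abort_tpp(sprintf("%s must be named over: %s.", nm,
                        paste(mixes[[nm]], collapse = ", ")), "schema")
    }
    if (any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      abort_tpp(sprintf("%s must be a probability vector summing to 1.", nm), "value")
    }
  }
  for (nm in c("exclusion_trigger_rate", "reviewer_disagreement_rate",
               "unknown_rate", "p_both_indications")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      abort_tpp(sprintf("%s must be a probability in [0, 1].", nm), "value")
    }
  }
  structure(cfg, class = "tpp_synth_config")
}

sample_cat <- function(n, mix) {
  sample(names(mix), n, replace = TRUE, prob = mix)
}

# Rejection-sample one profile whose normalised score lands in the planted
# rank's threshold band; cap the attempts so infeasible bands fail loudly.
# Thresholds are compared directly (not via assign_rank) to keep the loop
# cheap; the comparison rule is identical: inclusive at both cutoffs.
sample_profile_in_band <- function(rank, phase, scheme, unknown_rate, cap = 10000L) {
  crit <- scheme$criteria
  idx <- match(phase, scheme$thresholds$phase)
  hi <- scheme$thresholds$high[idx]
  med <- scheme$thresholds$medium[idx]
  max_att <- sum(crit$weight) * scheme$level_scores[["met_preferred"]]
  for (attempt in seq_len(cap)) {
    lv <- sample(informative_levels(), nrow(crit), replace = TRUE)
    unk <- stats::runif(nrow(crit)) < unknown_rate
    lv[unk] <- "unknown"
    r <- sum(crit$weight * unname(scheme$level_scores[lv])) / max_att
    got <- if (r >= hi) "high" else if (r >= med) "medium" else "low"
    if (got == rank) return(lv)
  }
  abort_tpp(sprintf(
    "Could not sample a profile with rank '%s' at phase %s within %d attempts; the threshold band is empty or nearly empty under this scheme.",
    rank, phase, cap
  ), "infeasible_config")
}

#' Generate a synthetic registry with planted ground truth
#'
#' Draws a registry of `n_candidates` from the configured phase, product
#' type and archetype mixes; plants the six exclusion flags independently at
#' the configured rate; and, for every retained clinical candidate-indication
#' pair, plants a rank and rejection-samples a match profile whose
#' normalised score falls in that rank's threshold band under `scheme`.
#' Reviewer A reports the planted truth; reviewer B deviates per criterion
#' with probability `reviewer_disagreement_rate` (a uniform draw from the
#' four other levels); the adjudicator reports the truth, so a noiseless or
#' truthfully adjudicated pipeline recovers every planted rank. Output is
#' fully reproducible from the seed.
#'
#' @param config A [synthetic_config()].
#' @param scheme The [tpp_scheme()] used for band placement.
#' @return A `tpp_simulation` list: `registry`, `assessments` (long, with
#'   reviewers A, B and adjudicator rows), and `truth` (list with `ranks` —
#'   tibble `candidate_id`, `indication`, `phase`, `planted_rank` — and
#'   `profiles`, the planted long level map).
#' @examples
#' sim <- simulate_registry(synthetic_config(n_candidates = 20, seed = 42))
#' sim$truth$ranks
#' @export
simulate_registry <- function(config = synthetic_config(), scheme = default_scheme()) {
  stopifnot(inherits(config, "tpp_synth_config"))
  validate_scheme(scheme)
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  n <- config$n_candidates
  phase <- sample_cat(n, config$phase_mix)
  product_type <- sample_cat(n, config$product_type_mix)
  archetype <- sample_cat(n, config$archetype_mix)
  both <- stats::runif(n) < config$p_both_indications
  single <- sample(c("prevention", "treatment"), n, replace = TRUE)
  indications <- lapply(seq_len(n), function(i) {
    if (both[i]) c("prevention", "treatment") else single[i]
  })
  flags <- matrix(stats::runif(n * 6) < config$exclusion_trigger_rate, nrow = n)
  colnames(flags) <- screening_flags

  registry <- tibble(
    candidate_id = sprintf("syn-%04d", seq_len(n)),
    name = sprintf("Compound %04d", seq_len(n)),
    indications = indications,
    product_type = product_type,
    archetype = archetype,
    phase = phase,
    last_activity_year = sample(2015:2021, n, replace = TRUE),
    trial_settings = lapply(sample(c("both", "HIC", "LMIC", "none"), n,
                                   replace = TRUE, prob = c(0.2, 0.4, 0.2, 0.2)),
                            function(s) switch(s, both = c("HIC", "LMIC"),
                                               none = character(0), s)),
    requires_cold_chain = sample(c("yes", "no", "unknown"), n, replace = TRUE,
                                 prob = c(0.2, 0.5, 0.3)),
    on_who_eml = stats::runif(n) < 0.2,
    preclinical_subclass = if_else(
      phase == "preclinical",
      sample(registry_enum$preclinical_subclass, n, replace = TRUE),
      NA_character_
    )
  )
  for (fl in screening_flags) registry[[fl]] <- flags[, fl]
  registry <- as_registry(registry)

  retained_clinical <- registry %>%
    filter(.data$phase != "preclinical", !rowSums(flags) > 0)
  pairs <- retained_clinical %>%
    select("candidate_id", "phase", "indications") %>%
    tidyr::unnest_longer("indications", values_to = "indication")

  truth_profiles <- list()
  assess <- list()
  planted <- character(nrow(pairs))
  n_crit <- nrow(scheme$criteria)
  for (i in seq_len(nrow(pairs))) {
    rank_i <- sample_cat(1, config$planted_rank_mix)
    lv <- sample_profile_in_band(rank_i, pairs$phase[i], scheme, config$unknown_rate)
    planted[i] <- rank_i
    truth_profiles[[i]] <- tibble(
      candidate_id = pairs$candidate_id[i], indication = pairs$indication[i],
      criterion_id = scheme$criteria$criterion_id, level = lv
    )
    b_lv <- lv
    flip <- stats::runif(n_crit) < config$reviewer_disagreement_rate
    for (j in which(flip)) {
      b_lv[j] <- sample(setdiff(match_levels(), lv[j]), 1)
    }
    assess[[i]] <- bind_rows(
      tibble(candidate_id = pairs$candidate_id[i], indication = pairs$indication[i],
             reviewer_id = "A", criterion_id = scheme$criteria$criterion_id, level = lv),
      tibble(candidate_id = pairs$candidate_id[i], indication = pairs$indication[i],
             reviewer_id = "B", criterion_id = scheme$criteria$criterion_id, level = b_lv),
      tibble(candidate_id = pairs$candidate_id[i], indication = pairs$indication[i],
             reviewer_id = "adjudicator", criterion_id = scheme$criteria$criterion_id,
             level = lv)
    )
  }
  truth <- list(
    ranks = pairs %>%
      select("candidate_id", "indication", "phase") %>%
      mutate(planted_rank = planted),
    profiles = if (length(truth_profiles) > 0) bind_rows(truth_profiles) else
      tibble(candidate_id = character(), indication = character(),
             criterion_id = character(), level = character())
  )
  assessments <- if (length(assess) > 0) bind_rows(assess) else
    tibble(candidate_id = character(), indication = character(),
           reviewer_id = character(), criterion_id = character(), level = character())
  structure(list(registry = registry, assessments = assessments, truth = truth,
                 config = config),
            class = "tpp_simulation")
}

#' Empirical deviation of a simulated registry from its configured mixes
#'
#' Compares the empirical proportions of phase, product type and archetype in
#' a registry against the configured probability vectors and returns the
#' maximum absolute deviation across all categories.
#'
#' @param registry A registry tibble.
#' @param config The [synthetic_config()] it was drawn from.
#' @return A single number: max over categories of |empirical - configured|.
#' @export
empirical_mix_check <- function(registry, config) {
  stopifnot(inherits(config, "tpp_synth_config"))
  registry <- as_registry(registry)
  n <- nrow(registry)
  dev <- function(values, mix) {
    emp <- table(factor(values, levels = names(mix))) / n
    max(abs(as.numeric(emp) - as.numeric(mix)))
  }
  max(
    dev(registry$phase, config$phase_mix),
    dev(registry$product_type, config$product_type_mix),
    dev(registry$archetype, config$archetype_mix)
  )
}

#' Write a simulation bundle to disk
#'
#' Emits `registry.csv`, `assessments.csv` and `truth.json` into a
#' directory.
#'
#' @param sim A `tpp_simulation` from [simulate_registry()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "tpp_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_registry(sim$registry, file.path(dir, "registry.csv"))
  write_assessments(sim$assessments, file.path(dir, "assessments.csv"))
  jsonlite::write_json(
    list(ranks = sim$truth$ranks, profiles = sim$truth$profiles,
         seed = sim$config$seed),
    file.path(dir, "truth.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
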