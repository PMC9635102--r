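#' The six exclusion rules
#'
#' Candidates are excluded from TPP matching when any of six conditions
#' holds: (1) approved and already available on the market for the
#' indication; (2) recommended or otherwise in routine clinical use for the
#' indication; (3) already recommended or widely used for a subgroup within
#' the condition; (4) inactive following negative trial outcomes; (5)
#' targeting a single symptom rather than the underlying pathology; (6)
#' indicated as inferior to current treatments. The attributes are curator
#' judgments supplied in the registry, not computed from literature.
#'
#' @return A tibble with columns `reason_code`, `flag` (registry column) and
#'   `label`.
#' @export
exclusion_rules <- function() {
  tibble(
    reason_code = 1:6,
    flag = screening_flags,
    label = c(
      "approved and on the market for this indication",
      "recommended or in routine clinical use",
      "recommended/widely used for a subgroup only",
      "inactive due to negative trial outcomes",
      "targets one symptom, not underlying pathology",
      "inferior to current treatments"
    )
  )
}

#' Screen a registry with the six exclusion rules
#'
#' Partitions a registry into retained and excluded candidates. A candidate
#' is excluded iff at least one of the six screening flags is true; the
#' primary reason is the lowest-numbered triggered rule (precedence 1 to 6),
#' with every triggered rule kept in `all_reasons`. Registry order is
#' preserved; missing flags are treated as `FALSE` with a message.
#'
#' @param registry A registry tibble (coerced via [as_registry()]).
#' @return A `tpp_screening` tibble: the registry plus `decision`
#'   (`"retained"`/`"excluded"`), `primary_reason` (integer, `NA` when
#'   retained) and `all_reasons` (list of integer vectors). Carries a
#'   `ruleset_version` attribute.
#' @examples
#' reg <- as_registry(data.frame(
#'   candidate_id = c("a", "b"), name = c("A", "B"),
#'   indications = "treatment", product_type = "drug",
#'   archetype = "repurposed", phase = "II",
#'   targets_symptom_only = c(TRUE, FALSE)
#' ))
#' apply_exclusions(reg)
#' @export
apply_exclusions <- function(registry) {
  if (is.data.frame(registry)) {
    miss <- intersect(setdiff(screening_flags, names(registry)), screening_flags)
    if (length(miss) > 0 && length(miss) < length(screening_flags)) {
      message("Screening flag(s) absent, defaulting to false: ", paste(miss, collapse = ", "))
    }
  }
  registry <- as_registry(registry)
  rules <- exclusion_rules()
  flag_mat <- matrix(FALSE, nrow = nrow(registry), ncol = nrow(rules),
                     dimnames = list(NULL, rules$flag))
  for (fl in rules$flag) {
    v <- registry[[fl]]
    v[is.na(v)] <- FALSE
    flag_mat[, fl] <- v
  }
  all_reasons <- apply(flag_mat, 1, function(r) rules$reason_code[r], simplify = FALSE)
  primary <- vapply(all_reasons, function(r) if (length(r) == 0) NA_integer_ else min(r), integer(1))
  out <- registry %>%
    mutate(
      decision = if_else(is.na(primary), "retained", "excluded"),
      primary_reason = primary,
      all_reasons = all_reasons
    )
  attr(out, "ruleset_version") <- "1.0"
  class(out) <- c("tpp_screening", class(as_tibble(out)))
  out
}

#' @rdname apply_exclusions
#' @param screening A `tpp_screening` tibble.
#' @export
retained_candidates <- function(screening) {
  stopifnot(inherits(screening, "tpp_screening"))
  as_registry(screening %>% filter(.data$decision == "retained") %>%
                select(-"decision", -"primary_reason", -"all_reasons"))
}

#' @rdname apply_exclusions
#' @export
excluded_candidates <- function(screening) {
  stopifnot(inherits(screening, "tpp_screening"))
  screening %>%
    filter(.data$decision == "excluded") %>%
    select("candidate_id", "name", "phase", "primary_reason", "all_reasons")
}

#' Flowchart-style screening counts
#'
#' Summarises a screening result as the eligibility-flowchart accounting:
#' input count, exclusions per rule (primary reason, so each candidate is
#' counted once), total excluded and retained. Counts conserve:
#' retained + excluded = input.
#'
#' @param screening A `tpp_screening` tibble from [apply_exclusions()].
#' @return A tibble with columns `stage` and `count`.
#' @export
screening_flowchart <- function(screening) {
  stopifnot(inherits(screening, "tpp_screening"))
  rules <- exclusion_rules()
  per_rule <- vapply(rules$reason_code, function(code) {
    sum(!is.na(screening$primary_reason) & screening$primary_reason == code)
  }, integer(1))
  tibble(
    stage = c("input", paste0("excluded_rule_", rules$reason_code),
              "excluded_total", "retained"),
    count = c(nrow(screening), per_rule, sum(per_rule),
              sum(screening$decision == "retained"))
  )
}

#' Write a screening report
#'
#' Emits the per-candidate decisions as CSV (`candidate_id`, `name`,
#' `decision`, `primary_reason`, `all_reasons` semicolon-joined) and,
#' optionally, the flowchart counts as a JSON object.
#'
#' @param screening A `tpp_screening` tibble.
#' @param path Output CSV path.
#' @param counts_path Optional JSON path for the flowchart counts.
#' @return Invisibly, `path`.
#' @export
write_screening <- function(screening, path, counts_path = NULL) {
  stopifnot(inherits(screening, "tpp_screening"))
  out <- screening %>%
    as_tibble() %>%
    mutate(all_reasons = vapply(.data$all_reasons,
                                function(r) paste(r, collapse = ";"), character(1))) %>%
    select("candidate_id", "name", "phase", "decision", "primary_reason", "all_reasons")
  readr::write_csv(out, path, na = "", progress = FALSE)
  if (!is.null(counts_path)) {
    fc <- screening_flowchart(screening)
    jsonlite::write_json(as.list(setNames(fc$count, fc$stage)), counts_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
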