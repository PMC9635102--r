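# Candidate registry schema, validation and CSV/JSON I/O.
#
# A registry is one row per candidate. Multi-valued fields (indications,
# trial_settings) are list-columns in R, semicolon-joined tokens in CSV and
# arrays in JSON. Absent values are empty strings in CSV, null in JSON.

registry_enum <- list(
  product_type = c("drug", "dietary", "biological"),
  archetype = c("new", "repurposed"),
  phase = c("preclinical", "I", "II", "III", "IV"),
  requires_cold_chain = c("yes", "no", "unknown"),
  preclinical_subclass = c(
    "amino acid-peptide", "antioxidant", "enzyme inhibitors (statins)",
    "hydrogen sulphide donors", "macronutrients", "polyphenol",
    "DNA/siRNA/mRNA", "small molecule", "cell therapy", "herbal",
    "vascular agents"
  ),
  indication = c("prevention", "treatment"),
  trial_setting = c("HIC", "LMIC")
)

screening_flags <- c(
  "approved_for_indication", "recommended_or_routine_use",
  "recommended_for_subgroup_only", "inactive_negative_outcome",
  "targets_symptom_only", "inferior_to_current"
)

registry_columns <- function() {
  c("candidate_id", "name", "indications", "product_type", "archetype",
    "phase", "last_activity_year", screening_flags, "trial_settings",
    "requires_cold_chain", "on_who_eml", "preclinical_subclass",
    "evidence_concerns")
}

parse_bool <- function(x, column) {
  out <- rep(NA, length(x))
  chr <- tolower(trimws(as.character(x)))
  out[chr %in% c("true", "t", "1", "yes")] <- TRUE
  out[chr %in% c("false", "f", "0", "no")] <- FALSE
  bad <- which(!is.na(chr) & nzchar(chr) & is.na(out))
  if (length(bad) > 0) {
    abort_tpp(
      sprintf("Column '%s': invalid boolean token '%s' (row %d).",
              column, x[bad[1]], bad[1]),
      "value"
    )
  }
  out
}

check_enum <- function(x, allowed, column, allow_na = FALSE) {
  bad <- which(!is.na(x) & !(x %in% allowed))
  if (length(bad) > 0) {
    abort_tpp(
      sprintf("Column '%s': invalid value '%s' (row %d); allowed: %s.",
              column, x[bad[1]], bad[1], paste(allowed, collapse = ", ")),
      "value"
    )
  }
  if (!allow_na && anyNA(x)) {
    abort_tpp(sprintf("Column '%s': missing value (row %d).", column, which(is.na(x))[1]), "value")
  }
  x
}

#' Construct and validate a candidate registry
#'
#' `as_registry()` coerces a data frame into the registry schema, filling
#' optional columns, parsing semicolon-joined multi-token fields into
#' list-columns, and enforcing the registry invariants: unique
#' `candidate_id`; `indications` a non-empty subset of
#' `{prevention, treatment}`; enum columns restricted to their token sets;
#' `preclinical_subclass` present exactly for preclinical candidates.
#' Invalid values are rejected, never coerced.
#'
#' @param df A data frame with at least `candidate_id`, `name`,
#'   `indications`, `product_type`, `archetype`, `phase`. Screening flags
#'   default to `FALSE`, `requires_cold_chain` to `"unknown"`, `on_who_eml`
#'   to `FALSE`.
#' @return A validated registry tibble (class `tpp_registry`), input order
#'   preserved.
#' @examples
#' as_registry(data.frame(
#'   candidate_id = "c1", name = "Metformin", indications = "prevention;treatment",
#'   product_type = "drug", archetype = "repurposed", phase = "II"
#' ))
#' @export
as_registry <- function(df) {
  df <- as_tibble(df)
  required <- c("candidate_id", "name", "indications", "product_type", "archetype", "phase")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    abort_tpp(paste0("Registry missing required column(s): ", paste(miss, collapse = ", ")), "schema")
  }
  n <- nrow(df)
  defaults <- list(
    last_activity_year = NA_integer_,
    trial_settings = NA_character_,
    requires_cold_chain = "unknown",
    on_who_eml = FALSE,
    preclinical_subclass = NA_character_,
    evidence_concerns = NA_character_
  )
  for (fl in screening_flags) defaults[[fl]] <- FALSE
  for (col in names(defaults)) {
    if (!col %in% names(df)) df[[col]] <- rep(defaults[[col]], n)
  }

  df$candidate_id <- as.character(df$candidate_id)
  if (anyNA(df$candidate_id) || any(!nzchar(df$candidate_id))) {
    abort_tpp("candidate_id must be non-empty.", "value")
  }
  dup <- df$candidate_id[duplicated(df$candidate_id)]
  if (length(dup) > 0) {
    abort_tpp(paste0("Duplicate candidate_id: ", paste(unique(dup), collapse = ", ")), "uniqueness")
  }
  df$name <- as.character(df$name)

  if (!is.list(df$indications)) df$indications <- split_tokens(as.character(df$indications))
  for (i in seq_len(n)) {
    ind <- df$indications[[i]]
    if (length(ind) == 0) {
      abort_tpp(sprintf("Candidate '%s': indications must be non-empty.", df$candidate_id[i]), "value")
    }
    bad <- setdiff(ind, registry_enum$indication)
    if (length(bad) > 0) {
      abort_tpp(sprintf("Candidate '%s': invalid indication '%s'.", df$candidate_id[i], bad[1]), "value")
    }
    df$indications[[i]] <- unique(ind)
  }

  df$product_type <- check_enum(as.character(df$product_type), registry_enum$product_type, "product_type")
  df$archetype <- check_enum(as.character(df$archetype), registry_enum$archetype, "archetype")
  df$phase <- check_enum(as.character(df$phase), registry_enum$phase, "phase")

  if (is.character(df$last_activity_year)) {
    df$last_activity_year[!nzchar(trimws(df$last_activity_year))] <- NA
  }
  year <- suppressWarnings(as.integer(df$last_activity_year))
  bad <- which(!is.na(df$last_activity_year) & is.na(year) & !is.na(as.character(df$last_activity_year)))
  if (length(bad) > 0) {
    abort_tpp(sprintf("Column 'last_activity_year': non-integer value (row %d).", bad[1]), "value")
  }
  df$last_activity_year <- year

  for (fl in c(screening_flags, "on_who_eml")) {
    v <- df[[fl]]
    if (!is.logical(v)) v <- parse_bool(v, fl)
    if (fl == "on_who_eml") v[is.na(v)] <- FALSE
    df[[fl]] <- v
  }

  if (!is.list(df$trial_settings)) df$trial_settings <- split_tokens(as.character(df$trial_settings))
  for (i in seq_len(n)) {
    bad <- setdiff(df$trial_settings[[i]], registry_enum$trial_setting)
    if (length(bad) > 0) {
      abort_tpp(sprintf("Candidate '%s': invalid trial setting '%s'.", df$candidate_id[i], bad[1]), "value")
    }
    df$trial_settings[[i]] <- unique(df$trial_settings[[i]])
  }

  cc <- as.character(df$requires_cold_chain)
  cc[is.na(cc) | !nzchar(trimws(cc))] <- "unknown"
  df$requires_cold_chain <- check_enum(cc, registry_enum$requires_cold_chain, "requires_cold_chain")

  sub <- as.character(df$preclinical_subclass)
  sub[!is.na(sub) & !nzchar(trimws(sub))] <- NA
  df$preclinical_subclass <- check_enum(sub, registry_enum$preclinical_subclass,
                                        "preclinical_subclass", allow_na = TRUE)
  pc <- df$phase == "preclinical"
  if (any(pc & is.na(df$preclinical_subclass))) {
    abort_tpp(sprintf("Preclinical candidate '%s' lacks preclinical_subclass.",
                      df$candidate_id[which(pc & is.na(df$preclinical_subclass))[1]]), "value")
  }
  if (any(!pc & !is.na(df$preclinical_subclass))) {
    abort_tpp(sprintf("Candidate '%s' is not preclinical but carries preclinical_subclass.",
                      df$candidate_id[which(!pc & !is.na(df$preclinical_subclass))[1]]), "value")
  }
  df$evidence_concerns <- as.character(df$evidence_concerns)

  out <- df[, registry_columns()]
  class(out) <- c("tpp_registry", class(as_tibble(out)))
  out
}

#' Read and write candidate registries
#'
#' CSV registries are UTF-8, comma-separated, one header row; multi-valued
#' fields are semicolon-joined; absent values are empty strings; booleans are
#' `true`/`false`. JSON registries are an array of objects with the same
#' field names, `null` for absent, and arrays for multi-valued fields.
#' Reading validates via [as_registry()]; a written registry re-reads
#' field-for-field identical (round-trip).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return `read_registry()` returns a validated registry tibble;
#'   `write_registry()` invisibly returns `path`.
#' @examples
#' reg <- as_registry(data.frame(
#'   candidate_id = "c1", name = "Esomeprazole", indications = "prevention",
#'   product_type = "drug", archetype = "repurposed", phase = "III"
#' ))
#' f <- tempfile(fileext = ".csv")
#' write_registry(reg, f)
#' all.equal(read_registry(f), reg, check.attributes = FALSE)
#' @export
read_registry <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) {
    abort_tpp(paste0("Registry file not found: ", path), "schema")
  }
  if (format == "csv") {
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  } else {
    rows <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    df <- purrr::map(rows, function(r) {
      r <- purrr::map(r, function(v) {
        if (is.null(v)) NA_character_
        else if (length(v) > 1 || is.list(v)) paste(unlist(v), collapse = ";")
        else as.character(v)
      })
      as_tibble(r)
    }) %>% bind_rows()
  }
  as_registry(df)
}

#' @rdname read_registry
#' @param registry A registry tibble as from [as_registry()].
#' @export
write_registry <- function(registry, path, format = c("auto", "csv", "json")) {
  registry <- as_registry(registry)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  flat <- registry %>%
    mutate(
      indications = join_tokens(.data$indications),
      trial_settings = join_tokens(.data$trial_settings)
    )
  if (format == "csv") {
    out <- flat %>%
      mutate(across(all_of(c(screening_flags, "on_who_eml")),
                    ~ if_else(.x, "true", "false")))
    readr::write_csv(out, path, na = "", progress = FALSE)
  } else {
    rows <- purrr::pmap(registry, function(...) {
      r <- list(...)
      r$indications <- as.list(r$indications)
      r$trial_settings <- if (length(r$trial_settings) == 0) NULL else as.list(r$trial_settings)
      purrr::map(r, function(v) if (length(v) == 1 && is.na(v)) NULL else v)
    })
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read reviewer TPP assessments
#'
#' Assessments are long-format records: one row per candidate, indication,
#' reviewer and criterion, with columns `candidate_id`, `indication`,
#' `reviewer_id` (`A`, `B` or `adjudicator`), `criterion_id`, `level`
#' (a [match_levels()] token).
#'
#' @param path CSV or JSON file path.
#' @param format `"auto"`, `"csv"` or `"json"`.
#' @return A validated assessments tibble.
#' @export
read_assessments <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) {
    abort_tpp(paste0("Assessments file not found: ", path), "schema")
  }
  df <- if (format == "csv") {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  } else {
    as_tibble(jsonlite::fromJSON(path, simplifyVector = TRUE))
  }
  as_assessments(df)
}

#' @rdname read_assessments
#' @param df A data frame of long-format assessment rows to validate.
#' @export
as_assessments <- function(df) {
  df <- as_tibble(df)
  need <- c("candidate_id", "indication", "reviewer_id", "criterion_id", "level")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort_tpp(paste0("Assessments missing required column(s): ", paste(miss, collapse = ", ")), "schema")
  }
  df <- df %>% mutate(across(all_of(need), as.character))
  check_enum(df$indication, registry_enum$indication, "indication")
  check_enum(df$reviewer_id, c("A", "B", "adjudicator"), "reviewer_id")
  check_enum(df$level, match_levels(), "level")
  dup <- df %>%
    count(.data$candidate_id, .data$indication, .data$reviewer_id, .data$criterion_id) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_tpp(sprintf(
      "Duplicate assessment for candidate '%s' (%s), reviewer %s, criterion '%s'.",
      dup$candidate_id[1], dup$indication[1], dup$reviewer_id[1], dup$criterion_id[1]
    ), "uniqueness")
  }
  df[, need]
}

#' @rdname read_assessments
#' @param assessments A validated assessments tibble.
#' @export
write_assessments <- function(assessments, path) {
  readr::write_csv(as_assessments(assessments), path, na = "", progress = FALSE)
  invisible(path)
}

#' Check assessment coverage against a registry
#'
#' Reports, per candidate-indication pair, which reviewers are present and
#' which criteria each reviewer is missing; flags assessments that reference
#' candidates absent from the registry, or candidate-indication pairs not
#' declared in the registry. Inputs are never modified.
#'
#' @param registry A registry tibble.
#' @param assessments A long assessments tibble ([read_assessments()]).
#' @param criteria Criterion set to check coverage against.
#' @return A tibble of defects with columns `candidate_id`, `indication`,
#'   `reviewer_id`, `defect`, `detail`; zero rows when coverage is complete.
#' @export
validate_assessments <- function(registry, assessments, criteria = tpp_criteria()) {
  registry <- as_registry(registry)
  assessments <- as_assessments(assessments)
  unknown <- setdiff(unique(assessments$candidate_id), registry$candidate_id)
  if (length(unknown) > 0) {
    abort_tpp(paste0("Assessment references unknown candidate_id: ",
                     paste(unknown, collapse = ", ")), "referential")
  }
  defects <- list()

  reg_pairs <- registry %>%
    select("candidate_id", "indications") %>%
    tidyr::unnest_longer("indications", values_to = "indication")
  stray <- assessments %>%
    distinct(.data$candidate_id, .data$indication) %>%
    anti_join(reg_pairs, by = c("candidate_id", "indication"))
  if (nrow(stray) > 0) {
    defects$stray <- stray %>%
      mutate(reviewer_id = NA_character_, defect = "indication_not_in_registry",
             detail = "assessed indication not declared for candidate")
  }

  assessed_pairs <- assessments %>% distinct(.data$candidate_id, .data$indication)
  for (rv in c("A", "B")) {
    present <- assessments %>%
      filter(.data$reviewer_id == rv) %>%
      distinct(.data$candidate_id, .data$indication)
    missing_rv <- assessed_pairs %>% anti_join(present, by = c("candidate_id", "indication"))
    if (nrow(missing_rv) > 0) {
      defects[[paste0("norev_", rv)]] <- missing_rv %>%
        mutate(reviewer_id = rv, defect = "reviewer_missing",
               detail = paste0("no assessment rows from reviewer ", rv))
    }
    have <- assessments %>% filter(.data$reviewer_id == rv)
    grid <- present %>% tidyr::crossing(criterion_id = criteria$criterion_id)
    gaps <- grid %>%
      anti_join(have, by = c("candidate_id", "indication", "criterion_id"))
    if (nrow(gaps) > 0) {
      defects[[paste0("gap_", rv)]] <- gaps %>%
        mutate(reviewer_id = rv, defect = "criterion_missing", detail = .data$criterion_id) %>%
        select(-"criterion_id")
    }
  }
  extra <- assessments %>%
    filter(!.data$criterion_id %in% criteria$criterion_id) %>%
    distinct(.data$candidate_id, .data$indication, .data$reviewer_id, .data$criterion_id)
  if (nrow(extra) > 0) {
    defects$extra <- extra %>%
      mutate(defect = "unknown_criterion", detail = .data$criterion_id) %>%
      select(-"criterion_id")
  }
  if (length(defects) == 0) {
    return(tibble(candidate_id = character(), indication = character(),
                  reviewer_id = character(), defect = character(), detail = character()))
  }
  bind_rows(defects) %>%
    select("candidate_id", "indication", "reviewer_id", "defect", "detail") %>%
    arrange(.data$candidate_id, .data$indication, .data$reviewer_id, .data$defect)
}

#' Classify development activity from the last activity year
#'
#' A candidate is active when its most recent recorded activity falls within
#' the three calendar years before the reference year, inclusive of the
#' boundary: `last_activity_year >= reference_year - 3`. With a 2021
#' reference, activity in 2018 or later counts as active. Candidates with no
#' recorded activity year are inactive.
#'
#' @param last_activity_year Integer vector (NA = no recorded activity).
#' @param reference_year Integer reference year.
#' @return Character vector, `"active"` or `"inactive"`.
#' @examples
#' classify_activity(c(2018, 2017, NA), 2021)
#' @export
classify_activity <- function(last_activity_year, reference_year) {
  stopifnot(is.numeric(reference_year), length(reference_year) == 1)
  if_else(!is.na(last_activity_year) & last_activity_year >= reference_year - 3,
          "active", "inactive")
}
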