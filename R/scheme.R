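#' Scoring schemes
#'
#' A scoring scheme bundles everything needed to turn a reconciled match
#' profile into a rank: the numeric score for each match level, the
#' per-criterion weights, and the per-phase rank thresholds expressed as
#' fractions of the maximum attainable score.
#'
#' The default scheme scores `not_met = 0`, `partially_met = 1`,
#' `met_minimum = 2`, `met_preferred = 3` and `unknown = 0` (unknown evidence
#' earns nothing but is tracked separately through the completeness
#' fraction); weights efficacy and safety at 2 against 1 for the other seven
#' criteria; and ranks a candidate high when its normalised score reaches
#' 0.60 of the maximum attainable, medium at 0.40, identically for phases
#' I-IV. All three pieces are replaceable, so a bespoke score coding and
#' per-phase threshold table can be replayed through the same engine.
#'
#' @param level_scores Named numeric vector over [match_levels()]. Must be
#'   monotone non-decreasing over the informative order.
#' @param criteria Criterion tibble as from [tpp_criteria()]: `criterion_id`,
#'   `display`, `weight`; efficacy and safety must outweigh the rest.
#' @param thresholds Tibble with columns `phase` (`I`,`II`,`III`,`IV`),
#'   `high`, `medium`; fractions of the maximum attainable score with
#'   `0 <= medium < high <= 1` per phase.
#' @return An object of class `tpp_scheme`.
#' @examples
#' sc <- default_scheme()
#' sc$level_scores
#' @export
tpp_scheme <- function(level_scores = c(not_met = 0, partially_met = 1,
                                        met_minimum = 2, met_preferred = 3,
                                        unknown = 0),
                       criteria = tpp_criteria(),
                       thresholds = tibble(
                         phase = c("I", "II", "III", "IV"),
                         high = 0.60, medium = 0.40
                       )) {
  scheme <- structure(
    list(level_scores = level_scores, criteria = criteria, thresholds = thresholds),
    class = "tpp_scheme"
  )
  validate_scheme(scheme)
}

#' @rdname tpp_scheme
#' @export
default_scheme <- function() tpp_scheme()

#' @rdname tpp_scheme
#' @param scheme A `tpp_scheme` to validate.
#' @export
validate_scheme <- function(scheme) {
  if (!inherits(scheme, "tpp_scheme")) {
    abort_tpp("`scheme` must be a tpp_scheme object.", "value")
  }
  ls <- scheme$level_scores
  missing_lv <- setdiff(match_levels(), names(ls))
  if (length(missing_lv) > 0) {
    abort_tpp(paste0("level_scores missing level(s): ", paste(missing_lv, collapse = ", ")), "schema")
  }
  if (!is.numeric(ls) || anyNA(ls)) {
    abort_tpp("level_scores must be numeric and non-missing.", "value")
  }
  ord <- ls[informative_levels()]
  if (any(diff(ord) < 0)) {
    abort_tpp("level_scores must be non-decreasing over not_met < partially_met < met_minimum < met_preferred.", "value")
  }
  cr <- scheme$criteria
  need <- c("criterion_id", "display", "weight")
  if (!all(need %in% names(cr))) {
    abort_tpp(paste0("criteria must have columns: ", paste(need, collapse = ", ")), "schema")
  }
  if (anyDuplicated(cr$criterion_id)) {
    abort_tpp("criterion_id values must be unique.", "uniqueness")
  }
  if (any(!is.finite(cr$weight)) || any(cr$weight <= 0)) {
    abort_tpp("criterion weights must be positive.", "value")
  }
  up <- c("efficacy", "safety")
  if (all(up %in% cr$criterion_id)) {
    w_up <- cr$weight[cr$criterion_id %in% up]
    w_rest <- cr$weight[!cr$criterion_id %in% up]
    if (length(w_rest) > 0 && min(w_up) <= max(w_rest)) {
      abort_tpp("efficacy and safety must carry a strictly greater weight than the other criteria.", "value")
    }
  }
  th <- scheme$thresholds
  if (!all(c("phase", "high", "medium") %in% names(th))) {
    abort_tpp("thresholds must have columns phase, high, medium.", "schema")
  }
  missing_ph <- setdiff(c("I", "II", "III", "IV"), th$phase)
  if (length(missing_ph) > 0) {
    abort_tpp(paste0("thresholds missing phase(s): ", paste(missing_ph, collapse = ", ")), "schema")
  }
  bad <- th$medium < 0 | th$high > 1 | th$medium >= th$high
  if (any(bad)) {
    abort_tpp("per-phase thresholds must satisfy 0 <= medium < high <= 1.", "value")
  }
  scheme
}

#' Read or write a scoring scheme configuration
#'
#' Scheme configurations are plain YAML or JSON with three blocks:
#' `level_scores` (level -> score), `weights` (criterion_id -> weight) and
#' `thresholds` (phase -> `{high, medium}`). Criteria keep the canonical
#' display order of [tpp_criteria()]; unknown criterion ids are rejected.
#'
#' @param path File path; format inferred from the extension (`.yaml`/`.yml`
#'   or `.json`) unless `format` is given.
#' @param format `"auto"`, `"yaml"` or `"json"`.
#' @return `read_scheme()` returns a validated `tpp_scheme`;
#'   `write_scheme()` invisibly returns `path`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_scheme(default_scheme(), f)
#' identical(read_scheme(f)$level_scores, default_scheme()$level_scores)
#' @export
read_scheme <- function(path, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  }
  if (!file.exists(path)) {
    abort_tpp(paste0("Scheme file not found: ", path), "schema")
  }
  cfg <- if (format == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (block in c("level_scores", "weights", "thresholds")) {
    if (is.null(cfg[[block]])) {
      abort_tpp(paste0("Scheme config missing block: ", block), "schema")
    }
  }
  base <- tpp_criteria()
  w <- unlist(cfg$weights)
  bad <- setdiff(names(w), base$criterion_id)
  if (length(bad) > 0) {
    abort_tpp(paste0("Unknown criterion id(s) in weights: ", paste(bad, collapse = ", ")), "value")
  }
  criteria <- base %>%
    filter(.data$criterion_id %in% names(w)) %>%
    mutate(weight = unname(w[.data$criterion_id]))
  th <- purrr::imap(cfg$thresholds, function(v, ph) {
    tibble(phase = ph, high = as.numeric(v$high %||% v["high"]),
           medium = as.numeric(v$medium %||% v["medium"]))
  }) %>% bind_rows()
  tpp_scheme(
    level_scores = unlist(cfg$level_scores)[match_levels()] %>% setNames(match_levels()),
    criteria = criteria,
    thresholds = th
  )
}

#' @rdname read_scheme
#' @param scheme A `tpp_scheme`.
#' @export
write_scheme <- function(scheme, path, format = c("auto", "yaml", "json")) {
  validate_scheme(scheme)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  }
  cfg <- list(
    level_scores = as.list(scheme$level_scores),
    weights = as.list(setNames(scheme$criteria$weight, scheme$criteria$criterion_id)),
    thresholds = setNames(
      purrr::map2(scheme$thresholds$high, scheme$thresholds$medium,
                  function(h, m) list(high = h, medium = m)),
      scheme$thresholds$phase
    )
  )
  if (format == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' @export
print.tpp_scheme <- function(x, ...) {
  cat("<tpp_scheme>\n")
  cat("  level scores: ",
      paste(names(x$level_scores), x$level_scores, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  criteria: ", nrow(x$criteria), " (weights ",
      paste(x$criteria$weight, collapse = "/"), ")\n", sep = "")
  th <- x$thresholds
  cat("  thresholds: ",
      paste(sprintf("%s high>=%.2f med>=%.2f", th$phase, th$high, th$medium), collapse = "; "),
      "\n", sep = "")
  invisible(x)
}
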