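#' Descriptive pipeline landscape summary
#'
#' Counts and percentages of candidates along four axes: development
#' activity (active/inactive, via [classify_activity()]), phase, product
#' type and archetype. Percentages are over the full registry and rounded
#' half-up to one decimal, the style used in printed pipeline reviews
#' (43.1%, 17.5%).
#'
#' @param registry A non-empty registry tibble.
#' @param reference_year Reference year for the activity axis.
#' @return A `tpp_summary` tibble with columns `axis`, `category`, `count`,
#'   `percent`; attribute `denominator` holds the registry size. Within each
#'   axis, counts sum to the denominator.
#' @examples
#' reg <- as_registry(data.frame(
#'   candidate_id = c("a", "b"), name = c("A", "B"),
#'   indications = "prevention", product_type = c("drug", "dietary"),
#'   archetype = "repurposed", phase = c("I", "III"),
#'   last_activity_year = c(2021, 2015)
#' ))
#' summarize_pipeline(reg, 2021)
#' @export
summarize_pipeline <- function(registry, reference_year) {
  registry <- as_registry(registry)
  if (nrow(registry) == 0) {
    abort_tpp("Cannot summarise an empty registry.", "empty_input")
  }
  axes <- list(
    activity = factor(classify_activity(registry$last_activity_year, reference_year),
                      levels = c("active", "inactive")),
    phase = factor(registry$phase, levels = registry_enum$phase),
    product_type = factor(registry$product_type, levels = registry_enum$product_type),
    archetype = factor(registry$archetype, levels = registry_enum$archetype)
  )
  n <- nrow(registry)
  out <- purrr::imap(axes, function(v, axis) {
    tab <- table(v)
    tibble(
      axis = axis,
      category = names(tab),
      count = as.integer(tab),
      percent = round_half_up(100 * as.integer(tab) / n, 1)
    )
  }) %>% bind_rows()
  attr(out, "denominator") <- n
  class(out) <- c("tpp_summary", class(as_tibble(out)))
  out
}

#' Preclinical taxonomy
#'
#' Accounting of a preclinical registry by medicine subclass, indication
#' membership and archetype. Dual-indication candidates (proposed for both
#' prevention and treatment) are counted once in the denominator, the
#' subclass counts and the archetype counts, and once each in the
#' prevention/treatment membership tallies, so
#' `prevention_only + treatment_only + both = denominator`.
#'
#' @param registry A registry tibble containing only preclinical candidates;
#'   any other phase raises a scope error.
#' @return A `tpp_preclinical` list: tibbles `subclass`, `indication`,
#'   `archetype` (each with `count` and `percent` over the unique
#'   denominator), `denominator`, and `notes` (character; propagates any
#'   `source_notes` attribute of the input registry).
#' @examples
#' reg <- as_registry(data.frame(
#'   candidate_id = "p1", name = "Quercetin",
#'   indications = "prevention;treatment", product_type = "dietary",
#'   archetype = "repurposed", phase = "preclinical",
#'   preclinical_subclass = "polyphenol"
#' ))
#' categorize_preclinical(reg)$indication
#' @export
categorize_preclinical <- function(registry) {
  notes <- attr(registry, "source_notes") %||% character(0)
  registry <- as_registry(registry)
  if (any(registry$phase != "preclinical")) {
    abort_tpp(sprintf(
      "categorize_preclinical expects only preclinical candidates; found '%s' at phase %s.",
      registry$candidate_id[registry$phase != "preclinical"][1],
      registry$phase[registry$phase != "preclinical"][1]
    ), "scope")
  }
  n <- nrow(registry)
  pct <- function(k) round_half_up(100 * k / n, 1)

  subclass <- registry %>%
    count(subclass = .data$preclinical_subclass, name = "count") %>%
    mutate(percent = pct(.data$count)) %>%
    arrange(desc(.data$count), .data$subclass)

  membership <- vapply(registry$indications, function(ind) {
    if (setequal(ind, c("prevention", "treatment"))) "both"
    else if ("prevention" %in% ind) "prevention_only"
    else "treatment_only"
  }, character(1))
  indication <- tibble(membership = factor(membership,
                                           levels = c("prevention_only", "treatment_only", "both"))) %>%
    count(.data$membership, name = "count", .drop = FALSE) %>%
    mutate(membership = as.character(.data$membership), percent = pct(.data$count))

  archetype <- registry %>%
    count(archetype = factor(.data$archetype, levels = registry_enum$archetype),
          name = "count", .drop = FALSE) %>%
    mutate(archetype = as.character(.data$archetype), percent = pct(.data$count))

  structure(
    list(subclass = subclass, indication = indication, archetype = archetype,
         denominator = n, notes = notes),
    class = "tpp_preclinical"
  )
}

#' @export
print.tpp_preclinical <- function(x, ...) {
  cat("<tpp_preclinical> ", x$denominator, " unique candidates\n", sep = "")
  print(x$indication)
  print(x$subclass)
  print(x$archetype)
  if (length(x$notes) > 0) cat("notes: ", paste(x$notes, collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Count unique candidate names across per-indication lists
#'
#' Takes one candidate-name vector per indication (or a list of them) and
#' returns the size of their union. Names are normalised by whitespace
#' trimming and case-folding before comparison; no fuzzy matching is
#' attempted, so distinct printed names stay distinct.
#'
#' @param ... Character vectors of candidate names, or a single list of
#'   them.
#' @return Integer: number of unique normalised names.
#' @examples
#' unique_candidate_count(c("Metformin", "Ozagrel"), c("metformin ", "Tadalafil"))
#' @export
unique_candidate_count <- function(...) {
  lists <- list(...)
  if (length(lists) == 1 && is.list(lists[[1]]) && !is.data.frame(lists[[1]])) {
    lists <- lists[[1]]
  }
  names_all <- unlist(lists, use.names = FALSE)
  if (length(names_all) == 0) return(0L)
  length(unique(tolower(trimws(as.character(names_all)))))
}

#' Write a landscape summary
#'
#' Emits the summary as tidy CSV (`axis`, `category`, `count`, `percent`)
#' or as nested JSON (one object per axis, category -> `{count, percent}`).
#'
#' @param summary A `tpp_summary` from [summarize_pipeline()].
#' @param path Output path; format inferred from extension unless given.
#' @param format `"auto"`, `"csv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_summary <- function(summary, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(summary, "tpp_summary"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    readr::write_csv(as_tibble(summary), path, progress = FALSE)
  } else {
    nested <- split(as_tibble(summary), summary$axis) %>%
      purrr::map(function(d) {
        setNames(purrr::map2(d$count, d$percent,
                             function(k, p) list(count = k, percent = p)),
                 d$category)
      })
    nested$denominator <- attr(summary, "denominator")
    jsonlite::write_json(nested, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
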