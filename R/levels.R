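#' Match levels for TPP criteria
#'
#' A candidate's fit to each target product profile (TPP) criterion is graded
#' on four informative levels with a total order,
#' `not_met < partially_met < met_minimum < met_preferred`, plus `unknown`
#' for criteria where the available evidence is insufficient. `unknown` sits
#' outside the order: it contributes no score but is tracked through the
#' completeness fraction and rendered grey in traffic-light matrices.
#'
#' @return `match_levels()` returns the five level tokens;
#'   `informative_levels()` the four ordered informative ones (lowest first).
#' @examples
#' match_levels()
#' @export
match_levels <- function() {
  c("not_met", "partially_met", "met_minimum", "met_preferred", "unknown")
}

#' @rdname match_levels
#' @export
informative_levels <- function() {
  c("not_met", "partially_met", "met_minimum", "met_preferred")
}

# Position of a level in the informative order; NA for unknown.
level_position <- function(level) {
  match(level, informative_levels())
}

#' The nine critical TPP criteria
#'
#' The default criterion set used to rank candidates in clinical development:
#' trial setting (high-income and low/middle-income country coverage),
#' clinical efficacy, need for a companion diagnostic, need for clinical
#' monitoring, safety, mode of administration, treatment adherence, stability
#' (cold-chain requirement) and WHO Essential Medicines List status. Efficacy
#' and safety carry a greater weight than the other seven criteria.
#'
#' @param efficacy_safety_weight Weight applied to the efficacy and safety
#'   criteria; all other criteria have weight 1. Default 2.
#' @return A tibble with columns `criterion_id`, `display`, `weight`, in
#'   canonical display order.
#' @examples
#' tpp_criteria()
#' @export
tpp_criteria <- function(efficacy_safety_weight = 2) {
  stopifnot(is.numeric(efficacy_safety_weight), efficacy_safety_weight > 0)
  ids <- c(
    "setting", "efficacy", "companion_diagnostic", "clinical_monitoring",
    "safety", "mode_of_administration", "treatment_adherence", "stability",
    "who_eml"
  )
  display <- c(
    "Setting", "Efficacy", "Companion diagnostic", "Clinical monitoring",
    "Safety", "Mode of administration", "Treatment adherence", "Stability",
    "WHO EML"
  )
  tibble(
    criterion_id = ids,
    display = display,
    weight = if_else(ids %in% c("efficacy", "safety"), efficacy_safety_weight, 1)
  )
}

#' Traffic-light colour coding of match levels
#'
#' Bijective map from the five match levels onto the colour tokens used in
#' traffic-light matrices: met preferred is dark green, met minimum light
#' green, partially met yellow, not met red, and unknown grey.
#'
#' @return `level_colors()` returns a named character vector
#'   (level -> colour token); `color_hex()` the default hex value for each
#'   colour token, with optional overrides.
#' @param overrides Named character vector of hex values replacing defaults,
#'   e.g. `c(red = "#cc0000")`.
#' @examples
#' level_colors()
#' color_hex(c(grey = "#cccccc"))
#' @export
level_colors <- function() {
  c(
    met_preferred = "dark_green",
    met_minimum   = "light_green",
    partially_met = "yellow",
    not_met       = "red",
    unknown       = "grey"
  )
}

#' @rdname level_colors
#' @export
color_hex <- function(overrides = NULL) {
  hex <- c(
    dark_green  = "#1a7a3c",
    light_green = "#8fd08f",
    yellow      = "#f2d21f",
    red         = "#d93025",
    grey        = "#b3b3b3"
  )
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(hex))
    if (length(bad) > 0) {
      abort_tpp(paste0("Unknown colour token(s): ", paste(bad, collapse = ", ")), "value")
    }
    hex[names(overrides)] <- overrides
  }
  hex
}
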