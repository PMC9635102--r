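#' Build a traffic-light matrix model
#'
#' Arranges reconciled match profiles into the traffic-light layout: one row
#' per ranked candidate-indication pair, one column per criterion in
#' canonical display order, plus the final rank. Rows are ordered
#' deterministically by phase (descending: IV, III, II, I), then total score
#' (descending), then name (alphabetical tie-break). Each cell carries its
#' match level and the colour token given by the fixed level -> colour map
#' ([level_colors()]).
#'
#' @param profiles Long profile tibble (`candidate_id`, `indication`,
#'   `criterion_id`, `level`).
#' @param ranked Ranked tibble as in `tidy(rank_registry(...))`; every
#'   profile must have a matching ranked row, otherwise a join error is
#'   raised.
#' @param criteria Criterion set defining column order.
#' @return A `tpp_matrix` object: list with `rows` (row order, candidate,
#'   phase, score, rank) and `cells` (long: `row`, `candidate_id`,
#'   `indication`, `criterion_id`, `level`, `color`).
#' @export
build_matrix <- function(profiles, ranked, criteria = tpp_criteria()) {
  profiles <- as_tibble(profiles)
  ranked <- as_tibble(ranked)
  prof_pairs <- profiles %>% distinct(.data$candidate_id, .data$indication)
  orphan <- prof_pairs %>% anti_join(ranked, by = c("candidate_id", "indication"))
  if (nrow(orphan) > 0) {
    abort_tpp(sprintf("Profile for candidate '%s' (%s) has no ranked entry.",
                      orphan$candidate_id[1], orphan$indication[1]), "join")
  }
  rows <- ranked %>%
    semi_join(prof_pairs, by = c("candidate_id", "indication")) %>%
    arrange(desc(match(.data$phase, registry_enum$phase)),
            desc(.data$total_score), .data$name, .data$indication) %>%
    mutate(row = row_number()) %>%
    select("row", "candidate_id", "name", "indication", "phase",
           "total_score", "rank")
  colors <- level_colors()
  cells <- rows %>%
    select("row", "candidate_id", "indication") %>%
    left_join(profiles, by = c("candidate_id", "indication")) %>%
    mutate(
      color = unname(colors[.data$level]),
      criterion_id = factor(.data$criterion_id, levels = criteria$criterion_id)
    ) %>%
    arrange(.data$row, .data$criterion_id) %>%
    mutate(criterion_id = as.character(.data$criterion_id)) %>%
    select("row", "candidate_id", "indication", "criterion_id", "level", "color")
  structure(list(rows = rows, cells = cells, criteria = criteria),
            class = "tpp_matrix")
}

#' @export
print.tpp_matrix <- function(x, ...) {
  cat("<tpp_matrix> ", nrow(x$rows), " row(s) x ", nrow(x$criteria),
      " criteria\n", sep = "")
  if (nrow(x$rows) > 0) print(head(x$rows, 10))
  invisible(x)
}

#' Render or re-read a traffic-light matrix
#'
#' CSV is the canonical, lossless machine format: one line per cell with row
#' metadata, level and colour token; [read_matrix()] reconstructs an
#' identical matrix model from it. HTML and SVG renders draw the coloured
#' grid with a legend naming all five colour tokens; they are
#' presentation-only.
#'
#' @param matrix A `tpp_matrix` from [build_matrix()].
#' @param path Output file path.
#' @param format `"csv"`, `"html"` or `"svg"`.
#' @param hex Named hex values per colour token (see [color_hex()]).
#' @return Invisibly, `path`.
#' @export
render_matrix <- function(matrix, path, format = c("csv", "html", "svg"),
                          hex = color_hex()) {
  stopifnot(inherits(matrix, "tpp_matrix"))
  if (length(format) != 1 || !format %in% c("csv", "html", "svg")) {
    abort_tpp(paste0("Unsupported render format: ", paste(format, collapse = "/"),
                     " (use csv, html or svg)."), "usage")
  }
  if (format == "csv") {
    flat <- matrix$cells %>%
      left_join(matrix$rows %>%
                  select("row", "name", "phase", "total_score", "rank"),
                by = "row") %>%
      select("row", "candidate_id", "name", "indication", "phase",
             "total_score", "rank", "criterion_id", "level", "color")
    readr::write_csv(flat, path, progress = FALSE)
  } else if (format == "html") {
    writeLines(matrix_html(matrix, hex), path)
  } else {
    writeLines(matrix_svg(matrix, hex), path)
  }
  invisible(path)
}

#' @rdname render_matrix
#' @export
read_matrix <- function(path) {
  flat <- readr::read_csv(path, col_types = readr::cols(
    row = readr::col_integer(), total_score = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
  rows <- flat %>%
    distinct(.data$row, .data$candidate_id, .data$name, .data$indication,
             .data$phase, .data$total_score, .data$rank) %>%
    arrange(.data$row)
  cells <- flat %>%
    select("row", "candidate_id", "indication", "criterion_id", "level", "color") %>%
    arrange(.data$row)
  criteria <- tpp_criteria() %>%
    filter(.data$criterion_id %in% unique(cells$criterion_id))
  structure(list(rows = rows, cells = cells, criteria = criteria),
            class = "tpp_matrix")
}

legend_entries <- function() {
  lv <- level_colors()
  labels <- c(
    met_preferred = "Met preferred",
    met_minimum = "Met minimum",
    partially_met = "Partially met minimum",
    not_met = "Did not meet minimum",
    unknown = "Not yet known"
  )
  tibble(level = names(lv), color = unname(lv), label = unname(labels[names(lv)]))
}

matrix_html <- function(matrix, hex = color_hex()) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  crits <- matrix$criteria
  head_cells <- paste0("<th>", esc(c("Candidate", "Indication", "Phase", crits$display, "Rank")),
                       "</th>", collapse = "")
  body <- character(0)
  for (i in seq_len(nrow(matrix$rows))) {
    r <- matrix$rows[i, ]
    rc <- matrix$cells %>% filter(.data$row == r$row)
    rc <- rc[match(crits$criterion_id, rc$criterion_id), ]
    tds <- paste0(
      sprintf('<td class="cell" style="background:%s" title="%s"></td>',
              hex[rc$color], esc(rc$level)),
      collapse = ""
    )
    body <- c(body, sprintf(
      "<tr><td>%s</td><td>%s</td><td>%s</td>%s<td>%s</td></tr>",
      esc(r$name), esc(r$indication), esc(r$phase), tds, esc(r$rank)
    ))
  }
  leg <- legend_entries()
  legend <- paste0(sprintf(
    '<li><span class="swatch" style="background:%s"></span> %s (%s)</li>',
    hex[leg$color], esc(leg$label), leg$color
  ), collapse = "\n")
  c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"><title>TPP matching matrix</title>",
    "<style>table{border-collapse:collapse}td,th{border:1px solid #999;padding:4px}",
    ".cell{width:28px;height:18px}.swatch{display:inline-block;width:14px;height:14px;border:1px solid #999}</style>",
    "</head><body>",
    "<h1>Target product profile matching</h1>",
    "<table>", paste0("<tr>", head_cells, "</tr>"), body, "</table>",
    "<h2>Legend</h2>", "<ul>", legend, "</ul>",
    "</body></html>"
  )
}

matrix_svg <- function(matrix, hex = color_hex()) {
  crits <- matrix$criteria
  cw <- 30; ch <- 22; label_w <- 220; header_h <- 90
  n_row <- nrow(matrix$rows); n_col <- nrow(crits)
  leg <- legend_entries()
  width <- label_w + cw * (n_col + 1) + 20
  height <- header_h + ch * n_row + 30 + 22 * nrow(leg)
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" font-family="sans-serif" font-size="11">',
    width, height
  ))
  for (j in seq_len(n_col)) {
    out <- c(out, sprintf(
      '<text x="%d" y="%d" transform="rotate(-45 %d %d)">%s</text>',
      label_w + (j - 1) * cw + 8, header_h - 6,
      label_w + (j - 1) * cw + 8, header_h - 6, crits$display[j]
    ))
  }
  out <- c(out, sprintf('<text x="%d" y="%d">Rank</text>',
                        label_w + n_col * cw + 2, header_h - 6))
  for (i in seq_len(n_row)) {
    r <- matrix$rows[i, ]
    y <- header_h + (i - 1) * ch
    out <- c(out, sprintf('<text x="4" y="%d">%s (%s, %s)</text>',
                          y + 15, r$name, r$indication, r$phase))
    rc <- matrix$cells %>% filter(.data$row == r$row)
    rc <- rc[match(crits$criterion_id, rc$criterion_id), ]
    for (j in seq_len(n_col)) {
      out <- c(out, sprintf(
        '<rect x="%d" y="%d" width="%d" height="%d" fill="%s" stroke="#666"/>',
        label_w + (j - 1) * cw, y, cw, ch, hex[rc$color[j]]
      ))
    }
    out <- c(out, sprintf('<text x="%d" y="%d">%s</text>',
                          label_w + n_col * cw + 4, y + 15, r$rank))
  }
  y0 <- header_h + n_row * ch + 20
  out <- c(out, sprintf('<text x="4" y="%d" font-weight="bold">Legend</text>', y0))
  for (k in seq_len(nrow(leg))) {
    y <- y0 + 8 + (k - 1) * 22
    out <- c(out,
             sprintf('<rect x="4" y="%d" width="14" height="14" fill="%s" stroke="#666"/>',
                     y, hex[leg$color[k]]),
             sprintf('<text x="24" y="%d">%s (%s)</text>', y + 12, leg$label[k], leg$color[k]))
  }
  c(out, "</svg>")
}

#' @export
autoplot.tpp_matrix <- function(object, hex = color_hex(), ...) {
  crits <- object$criteria
  dat <- object$cells %>%
    left_join(object$rows %>% select("row", "name", "phase", "rank"), by = "row") %>%
    mutate(
      label = paste0(.data$name, " (", .data$indication, ", ", .data$phase, ")"),
      criterion = factor(.data$criterion_id, levels = crits$criterion_id,
                         labels = crits$display)
    )
  lab_levels <- dat %>% distinct(.data$row, .data$label) %>% arrange(desc(.data$row))
  dat$label <- factor(dat$label, levels = lab_levels$label)
  leg <- legend_entries()
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$criterion, y = .data$label,
                                    fill = .data$color)) +
    ggplot2::geom_tile(color = "grey40") +
    ggplot2::scale_fill_manual(
      values = setNames(unname(hex[leg$color]), leg$color),
      breaks = leg$color, labels = paste0(leg$label),
      name = "TPP match"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
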