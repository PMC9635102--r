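# Internal helpers shared across modules.

# Round half away from zero to `digits` decimals (printed pipeline style:
# 43.1%, 17.5%), unlike base round()'s banker's rounding.
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

abort_tpp <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("tpprank_", class, "_error"), "tpprank_error"), ...)
}

# Split semicolon-joined multi-token CSV fields into character vectors;
# empty / NA become character(0).
split_tokens <- function(x) {
  lapply(x, function(v) {
    if (length(v) == 0 || is.na(v) || !nzchar(trimws(v))) return(character(0))
    trimws(strsplit(v, ";", fixed = TRUE)[[1]])
  })
}

join_tokens <- function(x) {
  vapply(x, function(v) paste(v, collapse = ";"), character(1))
}

`%||%` <- rlang::`%||%`
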