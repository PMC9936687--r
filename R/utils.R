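# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used in the rendered report tables.
#' `base::round()` rounds half to even, which disagrees with spreadsheet-style
#' percentages at .5 boundaries.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Canonical form of a dispatch-category label: trimmed, internal whitespace
# collapsed.  Matching is additionally case-insensitive (see category_key).
normalize_category <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  x
}

category_key <- function(x) tolower(normalize_category(x))

stop_contract <- function(...) {
  stop(structure(
    class = c("emstriage_contract_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_input <- function(...) {
  stop(structure(
    class = c("emstriage_input_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
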