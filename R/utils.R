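#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Parse numbers that may use a decimal comma
#'
#' Transcribed report tables often print fold changes and p-values with a
#' decimal comma (e.g. `"2,59"`, `"0,0057"`). This helper converts such
#' strings (and ordinary dot-decimal strings) to numeric.
#'
#' @param x character vector of numbers, possibly comma-decimal.
#' @return numeric vector; non-parseable entries raise an error.
#' @examples
#' parse_decimal("2,59")
#' parse_decimal(c("-1,43", "0.0186"))
#' @export
parse_decimal <- function(x) {
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(sub(",", ".", x, fixed = TRUE)))
  bad <- is.na(out) & !is.na(x) & nzchar(x)
  if (any(bad)) {
    stop("cannot parse as number: ", paste(sQuote(x[bad][1]), collapse = ", "))
  }
  out
}

# Deterministic 32-bit sub-seed from a master seed and a stage tag, so every
# generator draws from its own stream and stages can be rerun independently.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 48271 + h * 16807 + 12345) %% .Machine$integer.max)
}

# Normalize identifiers: trim whitespace; miRNA ids are lower-cased so that
# "hsa-miR-" / "HSA-MIR-" styles match, gene symbol case is preserved.
norm_mirna_id <- function(x) tolower(trimws(x))
norm_gene_symbol <- function(x) trimws(x)

stop_parse <- function(path, line, msg) {
  stop(sprintf("%s:%d: %s", path, line, msg), call. = FALSE)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
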