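#' Normalize gene symbols
#'
#' Uppercases and trims whitespace; drops empty strings. No ortholog or
#' identifier conversion is attempted — aliases are resolved only through
#' an explicit synonym table (see [unify_identifiers()]).
#'
#' @param x character vector of raw symbols
#' @return character vector of normalized, non-empty symbols (duplicates kept)
#' @export
normalize_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[nzchar(x)]
}

np_stop <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# TSV writer used by all report writers: never quotes, never rownames
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
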