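#' Canonicalize ICD-10 code strings
#'
#' Normalizes raw ICD-10 codes to a single canonical spelling: surrounding
#' whitespace is stripped, letters are upper-cased, and a code written without
#' a dot but longer than three characters gains one after the third character
#' (`"M545"` becomes `"M54.5"`). Codes are treated as opaque identifiers; no
#' lookup against an official ICD-10 catalog is performed, so version drift
#' between coding years cannot invalidate a dataset.
#'
#' @param raw character vector of raw code strings.
#' @return character vector of canonical codes, each matching
#'   `^[A-Z][0-9]{2}(\.[0-9A-Z]{1,4})?$`.
#' @examples
#' canonicalize_code(c(" m54.5 ", "M545", "G35"))
#' @export
canonicalize_code <- function(raw) {
  if (!is.character(raw)) abort("ICD-10 codes must be character, got %s", class(raw)[1])
  x <- toupper(trimws(raw))
  if (any(!nzchar(x))) abort("blank ICD-10 code in input")
  undotted <- !grepl(".", x, fixed = TRUE) & nchar(x) > 3
  x[undotted] <- paste0(substr(x[undotted], 1, 3), ".", substring(x[undotted], 4))
  ok <- grepl("^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,4})?$", x)
  if (any(!ok)) {
    abort("malformed ICD-10 code(s): %s",
          paste(sQuote(unique(trimws(raw[!ok]))), collapse = ", "))
  }
  x
}

#' Build a canonical code-set element
#'
#' An element of the diagnosis-overlap sets is the whole combination of ICD-10
#' codes attached to one exam, not an individual code: two exams carry the same
#' element exactly when their (deduplicated) code sets are identical. The
#' canonical form is the sorted, deduplicated codes joined by `"+"`, so element
#' equality is plain string equality.
#'
#' @param codes character vector of one or more ICD-10 codes (canonicalized on
#'   the way in).
#' @return length-1 character key, e.g. `"M50.30+M54.2"`.
#' @examples
#' code_set_element(c("M54.2", "m50.30", "M54.2"))
#' @export
code_set_element <- function(codes) {
  if (length(codes) < 1) abort("a code-set element requires at least one code")
  paste(sort(unique(canonicalize_code(codes))), collapse = "+")
}
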