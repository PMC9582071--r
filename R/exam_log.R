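#' Construct an exam log
#'
#' An exam log holds one row per performed MRI exam: which scanner and site ran
#' it, the body region, the protocol selected on the scanner, and the set of
#' ICD-10 admitting-diagnosis codes recorded for the order (possibly empty —
#' coding is a downstream documentation step and not every exam receives codes).
#' Codes are canonicalized and deduplicated; the body region is lower-cased to a
#' canonical tag.
#'
#' @param df data.frame with columns `exam_id`, `scanner_id`, `site_id`,
#'   `body_region`, `protocol_name`, `admitting_codes` (a list column of
#'   character vectors, or a character column of `";"`-separated codes) and
#'   optionally `exam_date` (ISO-8601 strings).
#' @return data.frame of class `exam_log` with `admitting_codes` as a list
#'   column of canonical, sorted code vectors.
#' @export
exam_log <- function(df) {
  req <- c("exam_id", "scanner_id", "site_id", "body_region",
           "protocol_name", "admitting_codes")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    abort("exam log is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  dup <- unique(df$exam_id[duplicated(df$exam_id)])
  if (length(dup)) {
    abort("duplicate exam_id(s): %s", paste(sQuote(dup), collapse = ", "))
  }
  codes <- df$admitting_codes
  if (!is.list(codes)) codes <- split_code_cells(codes)
  codes <- lapply(codes, function(cc) {
    cc <- cc[nzchar(trimws(cc))]
    if (!length(cc)) return(character(0))
    sort(unique(canonicalize_code(cc)))
  })
  out <- data.frame(
    exam_id = as.character(df$exam_id),
    scanner_id = as.character(df$scanner_id),
    site_id = as.character(df$site_id),
    body_region = tolower(as.character(df$body_region)),
    protocol_name = as.character(df$protocol_name),
    stringsAsFactors = FALSE
  )
  out$admitting_codes <- codes
  out$exam_date <- if ("exam_date" %in% names(df)) {
    d <- as.character(df$exam_date)
    d[!is.na(d) & !nzchar(d)] <- NA_character_
    d
  } else {
    rep(NA_character_, nrow(df))
  }
  class(out) <- c("exam_log", "data.frame")
  out
}

split_code_cells <- function(cells) {
  cells <- as.character(cells)
  cells[is.na(cells)] <- ""
  lapply(strsplit(cells, ";", fixed = TRUE), trimws)
}

#' Read an exam log from CSV
#'
#' Expects a UTF-8 CSV with header
#' `exam_id,scanner_id,site_id,body_region,protocol_name,admitting_codes[,exam_date]`,
#' where `admitting_codes` is a `";"`-separated list inside one cell (the
#' semicolon avoids colliding with the CSV field separator). Codes are
#' canonicalized and deduplicated per exam. Exams with an empty codes cell are
#' kept — the overlap stage excludes and counts them later — but their presence
#' is flagged with a warning so silent coding gaps surface early.
#'
#' @param path path to the CSV file.
#' @return an [exam_log] data.frame.
#' @export
read_exam_log <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  log <- exam_log(df)
  n_empty <- sum(lengths(log$admitting_codes) == 0)
  if (n_empty > 0) {
    warning(sprintf("%d exam(s) have an empty admitting-code set", n_empty),
            call. = FALSE)
  }
  log
}

#' Write an exam log to CSV
#'
#' Inverse of [read_exam_log()]: code sets are joined with `";"`, a missing
#' exam date becomes an empty cell. Writing then reading reproduces the records
#' field by field.
#'
#' @param records an [exam_log] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_exam_log <- function(records, path) {
  out <- data.frame(
    exam_id = records$exam_id,
    scanner_id = records$scanner_id,
    site_id = records$site_id,
    body_region = records$body_region,
    protocol_name = records$protocol_name,
    admitting_codes = vapply(records$admitting_codes, paste, character(1),
                             collapse = ";"),
    exam_date = ifelse(is.na(records$exam_date), "", records$exam_date),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
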