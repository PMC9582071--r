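#' Build per-protocol element sets from an exam log
#'
#' Restricts the log to one body region and maps every protocol to the set of
#' admitting-diagnosis elements observed with it. By default an element is the
#' whole code *combination* of one exam (see [code_set_element]); with
#' `granularity = "code"` each individual ICD-10 code becomes an element
#' instead (a documented variant — the combination reading is the primary
#' one). Exams without codes carry no element and are excluded with a count,
#' never silently.
#'
#' @param records an [exam_log] data.frame.
#' @param body_region canonical lowercase region tag; matching is exact string
#'   equality, no anatomical ontology.
#' @param granularity `"codeset"` (default) or `"code"`.
#' @return list with `assoc` (named list protocol -> character element keys),
#'   `exam_counts` (named integer, exams with codes per protocol),
#'   `excluded_exams` (count of empty-code exams in the region) and
#'   `body_region`.
#' @export
build_elements <- function(records, body_region,
                           granularity = c("codeset", "code")) {
  granularity <- match.arg(granularity)
  region <- tolower(body_region)
  sel <- records$body_region == region
  if (!any(sel)) abort("no exams for body region %s", sQuote(body_region))
  sub <- records[sel, , drop = FALSE]
  has_codes <- lengths(sub$admitting_codes) > 0
  excluded_exams <- sum(!has_codes)
  if (excluded_exams > 0) {
    message(sprintf("excluding %d exam(s) without admitting codes in region %s",
                    excluded_exams, sQuote(region)))
  }
  sub <- sub[has_codes, , drop = FALSE]
  if (!nrow(sub)) abort("region %s has no exams with admitting codes", sQuote(region))
  elements <- switch(granularity,
    codeset = lapply(sub$admitting_codes, function(cc) code_set_element(cc)),
    code = sub$admitting_codes
  )
  proto <- sub$protocol_name
  assoc <- lapply(split(elements, proto), function(el) {
    sort(unique(unlist(el, use.names = FALSE)))
  })
  counts <- vapply(split(proto, proto), length, integer(1))
  list(assoc = assoc, exam_counts = counts[names(assoc)],
       excluded_exams = excluded_exams, body_region = region)
}

#' Filter out rarely performed protocols
#'
#' Retains protocols performed at least `min_count` times. The default of 6
#' encodes "more than five times": a protocol seen five times or fewer is too
#' sparse for a meaningful overlap estimate.
#'
#' @param elements output of [build_elements()].
#' @param min_count positive integer; retain protocols with exam count >=
#'   `min_count`.
#' @return `elements` with `assoc`/`exam_counts` restricted to retained
#'   protocols, plus `excluded_protocols`, a data.frame of
#'   (`protocol_name`, `n_exams`) below the threshold.
#' @export
filter_protocols <- function(elements, min_count = 6) {
  if (!is.numeric(min_count) || min_count < 1)
    abort("min_count must be a positive integer")
  keep <- elements$exam_counts >= min_count
  excluded <- data.frame(
    protocol_name = names(elements$exam_counts)[!keep],
    n_exams = as.integer(elements$exam_counts[!keep]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!any(keep)) {
    abort("no protocol in region %s reaches min_count = %d",
          sQuote(elements$body_region), as.integer(min_count))
  }
  elements$assoc <- elements$assoc[keep]
  elements$exam_counts <- elements$exam_counts[keep]
  elements$excluded_protocols <- excluded
  elements
}

#' Admitting-diagnosis / protocol overlap analysis for one body region
#'
#' The full pipeline stage: build per-protocol element sets, drop rare
#' protocols, compute the pairwise overlap-coefficient matrix with its
#' complement column, and summarize the region's labeling with multi-label
#' statistics. Statistics are computed over *all* region exams with a nonempty
#' code set — before the protocol-frequency filter — while the matrix uses the
#' filtered protocol set, mirroring how dataset-level label summaries and
#' per-protocol figures cover different denominators.
#'
#' @param records an [exam_log] data.frame.
#' @param body_region canonical lowercase region tag.
#' @param min_count protocol-frequency threshold, default 6 ("more than five").
#' @param granularity element granularity, `"codeset"` (default) or `"code"`.
#' @param label_order `"frequency"` (descending exam count, ties broken
#'   lexicographically — the default, explicit and deterministic) or
#'   `"alphabetical"`.
#' @return object of class `dx_overlap_result` with fields `body_region`,
#'   `matrix` (an `overlap_matrix`), `stats` (a `label_statistics`),
#'   `excluded_protocols`, `excluded_exams`, `min_count`, `granularity`.
#' @export
run_dx_overlap <- function(records, body_region, min_count = 6,
                           granularity = c("codeset", "code"),
                           label_order = c("frequency", "alphabetical")) {
  granularity <- match.arg(granularity)
  label_order <- match.arg(label_order)
  elements <- build_elements(records, body_region, granularity)
  region <- elements$body_region
  region_records <- records[records$body_region == region, , drop = FALSE]
  stats <- label_statistics(region_records)
  filtered <- filter_protocols(elements, min_count)
  labels <- names(filtered$assoc)
  order <- switch(label_order,
    frequency = labels[order(-filtered$exam_counts[labels], labels)],
    alphabetical = sort(labels)
  )
  structure(list(
    body_region = region,
    matrix = pairwise_matrix(filtered$assoc, order),
    stats = stats,
    excluded_protocols = filtered$excluded_protocols,
    excluded_exams = elements$excluded_exams,
    min_count = as.integer(min_count),
    granularity = granularity
  ), class = "dx_overlap_result")
}

#' @export
print.dx_overlap_result <- function(x, ...) {
  off <- x$matrix$values[upper.tri(x$matrix$values)]
  comp <- x$matrix$complement[!is.na(x$matrix$complement)]
  cat(sprintf("Admitting-diagnosis overlap, region %s (%s elements)\n",
              sQuote(x$body_region), x$granularity))
  cat(sprintf("  %d protocols retained (>= %d exams), %d excluded, %d empty-code exams\n",
              length(x$matrix$labels), x$min_count,
              nrow(x$excluded_protocols), x$excluded_exams))
  if (length(off)) {
    cat(sprintf("  pairwise oc range: %.2f-%.2f; complement oc range: %.2f-%.2f\n",
                min(off), max(off), min(comp), max(comp)))
  }
  print(x$stats)
  invisible(x)
}
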