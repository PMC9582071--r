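TECHNIQUES <- c("SE", "TSE", "GRE", "EPI", "bSSFP", "UNKNOWN")
ORIENTATIONS <- c("SAG", "COR", "TRA", "OBL", "UNKNOWN")
CONTRAST_PHASES <- c("NONE", "PRE", "POST")
DIMENSIONALITIES <- c("2D", "3D")

#' Construct a parameterized pulse sequence
#'
#' Captures the acquisition parameters that determine MR image contrast —
#' repetition time TR, echo time TE, inversion time TI (ms), flip angle
#' (degrees), imaging technique, orientation — plus diffusion weightings,
#' fat suppression, contrast phase and dimensionality, together with the
#' user-given sequence name as it appears in the scanner's protocol tree.
#' A set TI implies an inversion-recovery preparation and is rejected
#' otherwise; nonempty b-values with a stated non-EPI technique only warn,
#' because vendor logs are inconsistent about the readout of diffusion scans.
#'
#' @param raw_name user-given sequence name (free text, site-specific).
#' @param tr_ms repetition time in ms, positive.
#' @param te_ms echo time in ms, nonnegative.
#' @param ti_ms inversion time in ms or `NULL`.
#' @param flip_deg flip angle in degrees, in \[0, 180\].
#' @param technique one of `"SE"`, `"TSE"`, `"GRE"`, `"EPI"`, `"bSSFP"`,
#'   `"UNKNOWN"`.
#' @param inversion_recovery logical; defaults to `TRUE` iff `ti_ms` is set.
#' @param orientation one of `"SAG"`, `"COR"`, `"TRA"`, `"OBL"`, `"UNKNOWN"`.
#' @param fat_suppression logical.
#' @param b_values numeric vector of nonnegative diffusion weightings
#'   (s/mm^2), possibly empty.
#' @param contrast_phase one of `"NONE"`, `"PRE"`, `"POST"`.
#' @param dimensionality `"2D"` or `"3D"`.
#' @param echo_train_length integer >= 1.
#' @param .where label used in error messages (e.g. a JSON path).
#' @return list of class `sequence_acquisition`.
#' @export
sequence_acquisition <- function(raw_name, tr_ms, te_ms, ti_ms = NULL,
                                 flip_deg = 90, technique = "UNKNOWN",
                                 inversion_recovery = !is.null(ti_ms),
                                 orientation = "UNKNOWN",
                                 fat_suppression = FALSE,
                                 b_values = numeric(0),
                                 contrast_phase = "NONE",
                                 dimensionality = "2D",
                                 echo_train_length = 1L,
                                 .where = "sequence") {
  if (!is.character(raw_name) || length(raw_name) != 1 || !nzchar(raw_name))
    abort("%s: raw_name must be a nonempty string", .where)
  if (!is.numeric(tr_ms) || tr_ms <= 0) abort("%s: tr_ms must be positive", .where)
  if (!is.numeric(te_ms) || te_ms < 0) abort("%s: te_ms must be nonnegative", .where)
  if (!is.null(ti_ms) && (!is.numeric(ti_ms) || ti_ms < 0))
    abort("%s: ti_ms must be nonnegative or NULL", .where)
  if (!is.numeric(flip_deg) || flip_deg < 0 || flip_deg > 180)
    abort("%s: flip_deg must lie in [0, 180]", .where)
  if (!technique %in% TECHNIQUES)
    abort("%s: unknown technique %s", .where, sQuote(technique))
  if (!orientation %in% ORIENTATIONS)
    abort("%s: unknown orientation %s", .where, sQuote(orientation))
  if (!contrast_phase %in% CONTRAST_PHASES)
    abort("%s: unknown contrast_phase %s", .where, sQuote(contrast_phase))
  if (!dimensionality %in% DIMENSIONALITIES)
    abort("%s: unknown dimensionality %s", .where, sQuote(dimensionality))
  if (length(b_values) && any(b_values < 0))
    abort("%s: b_values must be nonnegative", .where)
  echo_train_length <- as.integer(echo_train_length)
  if (is.na(echo_train_length) || echo_train_length < 1)
    abort("%s: echo_train_length must be an integer >= 1", .where)
  if (!is.null(ti_ms) && !isTRUE(inversion_recovery))
    abort("%s: ti_ms is set but inversion_recovery is FALSE", .where)
  if (length(b_values) && !technique %in% c("EPI", "UNKNOWN"))
    warning(sprintf("%s: diffusion b-values with stated technique %s (expected EPI)",
                    .where, technique), call. = FALSE)
  structure(
    list(raw_name = raw_name, tr_ms = as.numeric(tr_ms), te_ms = as.numeric(te_ms),
         ti_ms = if (is.null(ti_ms)) NULL else as.numeric(ti_ms),
         flip_deg = as.numeric(flip_deg), technique = technique,
         inversion_recovery = isTRUE(inversion_recovery),
         orientation = orientation, fat_suppression = isTRUE(fat_suppression),
         b_values = as.numeric(b_values), contrast_phase = contrast_phase,
         dimensionality = dimensionality, echo_train_length = echo_train_length),
    class = "sequence_acquisition"
  )
}

#' Construct a protocol definition
#'
#' A named, ordered, nonempty collection of pulse sequences for one exam type.
#'
#' @param protocol_name protocol name as listed in the scanner's tree.
#' @param body_region lowercase body-region tag (e.g. `"spine"`, `"brain/head"`).
#' @param sequences nonempty list of [sequence_acquisition] objects.
#' @return list of class `protocol_definition`.
#' @export
protocol_definition <- function(protocol_name, body_region, sequences) {
  if (!length(sequences)) abort("protocol %s has no sequences", sQuote(protocol_name))
  if (!all(vapply(sequences, inherits, logical(1), "sequence_acquisition")))
    abort("protocol %s: sequences must be sequence_acquisition objects",
          sQuote(protocol_name))
  structure(list(protocol_name = protocol_name,
                 body_region = tolower(body_region),
                 sequences = sequences),
            class = "protocol_definition")
}

#' Construct a protocol tree
#'
#' The per-scanner catalog of predefined protocols. Protocol names must be
#' unique within one tree; a tree with zero protocols is valid (a freshly
#' configured scanner) but warned about.
#'
#' @param scanner_id,site_id identifiers.
#' @param protocols list of [protocol_definition] objects.
#' @return list of class `protocol_tree`.
#' @export
protocol_tree <- function(scanner_id, site_id, protocols = list()) {
  nms <- vapply(protocols, `[[`, character(1), "protocol_name")
  dup <- unique(nms[duplicated(nms)])
  if (length(dup)) {
    abort("scanner %s: duplicate protocol name(s): %s", sQuote(scanner_id),
          paste(sQuote(dup), collapse = ", "))
  }
  if (!length(protocols)) {
    warning(sprintf("protocol tree of scanner %s has no protocols",
                    sQuote(scanner_id)), call. = FALSE)
  }
  structure(list(scanner_id = as.character(scanner_id),
                 site_id = as.character(site_id),
                 protocols = protocols),
            class = "protocol_tree")
}

seq_from_json <- function(node, where) {
  if (is.null(node$raw_name)) abort("%s: missing raw_name", where)
  if (is.null(node$tr_ms)) abort("%s: missing tr_ms", where)
  if (is.null(node$te_ms)) abort("%s: missing te_ms", where)
  sequence_acquisition(
    raw_name = node$raw_name, tr_ms = node$tr_ms, te_ms = node$te_ms,
    ti_ms = node$ti_ms,
    flip_deg = node$flip_deg %||% 90,
    technique = node$technique %||% "UNKNOWN",
    inversion_recovery = node$inversion_recovery %||% !is.null(node$ti_ms),
    orientation = node$orientation %||% "UNKNOWN",
    fat_suppression = node$fat_suppression %||% FALSE,
    b_values = unlist(node$b_values) %||% numeric(0),
    contrast_phase = node$contrast_phase %||% "NONE",
    dimensionality = node$dimensionality %||% "2D",
    echo_train_length = node$echo_train_length %||% 1L,
    .where = where
  )
}

#' Read protocol trees from JSON
#'
#' Parses the interchange document `{"scanners": [...]}` where each scanner
#' carries `scanner_id`, `site_id` and a `protocols` array; each protocol has
#' `protocol_name`, `body_region` and a `sequences` array with the
#' [sequence_acquisition] fields. Absent optional sequence fields default
#' conservatively (`technique`/`orientation` `"UNKNOWN"`, `contrast_phase`
#' `"NONE"`, empty `b_values`) — the reader never guesses a weighting.
#' Violations are reported with the JSON path of the offending node.
#'
#' @param path path to the JSON document.
#' @return list of [protocol_tree] objects.
#' @export
read_protocol_trees <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$scanners)) abort("$: expected top-level object with a \"scanners\" array")
  lapply(seq_along(doc$scanners), function(i) {
    sc <- doc$scanners[[i]]
    here <- sprintf("$.scanners[%d]", i)
    if (is.null(sc$scanner_id)) abort("%s: missing scanner_id", here)
    if (is.null(sc$site_id)) abort("%s: missing site_id", here)
    protocols <- lapply(seq_along(sc$protocols), function(j) {
      pr <- sc$protocols[[j]]
      pwhere <- sprintf("%s.protocols[%d]", here, j)
      if (is.null(pr$protocol_name)) abort("%s: missing protocol_name", pwhere)
      if (is.null(pr$body_region)) abort("%s: missing body_region", pwhere)
      if (!length(pr$sequences)) abort("%s: sequences array is empty", pwhere)
      seqs <- lapply(seq_along(pr$sequences), function(k) {
        seq_from_json(pr$sequences[[k]], sprintf("%s.sequences[%d]", pwhere, k))
      })
      protocol_definition(pr$protocol_name, pr$body_region, seqs)
    })
    protocol_tree(sc$scanner_id, sc$site_id, protocols)
  })
}

seq_to_json <- function(s) {
  out <- list(raw_name = s$raw_name, tr_ms = s$tr_ms, te_ms = s$te_ms)
  if (!is.null(s$ti_ms)) out$ti_ms <- s$ti_ms
  out$flip_deg <- s$flip_deg
  out$technique <- s$technique
  out$inversion_recovery <- s$inversion_recovery
  out$orientation <- s$orientation
  out$fat_suppression <- s$fat_suppression
  out$b_values <- I(s$b_values)
  out$contrast_phase <- s$contrast_phase
  out$dimensionality <- s$dimensionality
  out$echo_train_length <- s$echo_train_length
  out
}

#' Write protocol trees to JSON
#'
#' Inverse of [read_protocol_trees()]; numeric parameters are serialized at
#' full precision so a write/read round trip reproduces the trees field by
#' field.
#'
#' @param trees list of [protocol_tree] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protocol_trees <- function(trees, path) {
  doc <- list(scanners = lapply(trees, function(tr) {
    list(scanner_id = tr$scanner_id, site_id = tr$site_id,
         protocols = lapply(tr$protocols, function(pr) {
           list(protocol_name = pr$protocol_name, body_region = pr$body_region,
                sequences = lapply(pr$sequences, seq_to_json))
         }))
  }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
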