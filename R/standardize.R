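NUMERIC_RULE_FIELDS <- c("tr_ms", "te_ms", "ti_ms", "flip_deg",
                         "echo_train_length", "max_b")
CATEGORICAL_RULE_FIELDS <- c("technique", "orientation", "inversion_recovery",
                             "fat_suppression", "contrast_phase",
                             "dimensionality")

#' Read a standardization rule set from YAML
#'
#' A rule set is an ordered list of rules, each
#' `{name: ..., when: {field: condition, ...}, token: ...}`; the first rule
#' whose conditions all hold assigns the weighting token, and the last rule
#' must be a catch-all (empty `when`) so classification is total. Conditions
#' are categorical matches (a value or list of values, for `technique`,
#' `orientation`, `inversion_recovery`, `fat_suppression`, `contrast_phase`,
#' `dimensionality`) or numeric bounds (`gt`/`ge`/`lt`/`le`, for `tr_ms`,
#' `te_ms`, `ti_ms`, `flip_deg`, `echo_train_length` and the derived `max_b`,
#' the largest diffusion b-value, `-Inf` when none). All times are in
#' milliseconds, angles in degrees. The default table shipped with the package
#' encodes conventional MR contrast heuristics; sites can replace it wholesale.
#'
#' @param path path to the YAML rule file.
#' @return object of class `standardization_rules`.
#' @export
read_standardization_rules <- function(path) {
  doc <- yaml::read_yaml(path)
  rules <- doc$rules %||% doc
  as_standardization_rules(rules)
}

as_standardization_rules <- function(rules) {
  if (!is.list(rules) || !length(rules)) abort("rule set must be a nonempty list")
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    if (is.null(r$name) || is.null(r$token))
      abort("rule %d: every rule needs a name and a token", i)
    r$when <- r$when %||% list()
    for (field in names(r$when)) {
      cond <- r$when[[field]]
      if (field %in% NUMERIC_RULE_FIELDS) {
        if (!is.list(cond) || !length(cond) ||
            !all(names(cond) %in% c("gt", "ge", "lt", "le")))
          abort("rule %s: numeric condition on %s must use gt/ge/lt/le",
                sQuote(r$name), field)
        lo <- max(c(-Inf, unlist(cond[c("gt", "ge")])))
        hi <- min(c(Inf, unlist(cond[c("lt", "le")])))
        if (lo > hi) abort("rule %s: empty interval on %s", sQuote(r$name), field)
      } else if (!field %in% CATEGORICAL_RULE_FIELDS) {
        abort("rule %s: unknown field %s", sQuote(r$name), field)
      }
    }
    rules[[i]] <- r
  }
  last <- rules[[length(rules)]]
  if (length(last$when))
    abort("the final rule must be a catch-all (empty \"when\")")
  structure(rules, class = "standardization_rules")
}

#' Default standardization rule set
#'
#' Loads the rule table shipped with the package (`rules/default.yaml`):
#' diffusion (any b-value above 50) before inversion-recovery windows (FLAIR
#' TI 1800-2800 ms, STIR TI 120-300 ms) before relaxation-based rules (T1 for
#' short-TR/short-TE spin echo, T2 for long-TR/long-TE, PD for
#' long-TR/short-TE, T1 for high-flip short-TR gradient echo), then OTHER.
#' First match wins, which resolves the FLAIR/T2 and DWI/T2 ambiguities. TI
#' windows are wide enough to cover both 1.5 T and 3 T conventions.
#'
#' @return object of class `standardization_rules`.
#' @export
default_standardization_rules <- function() {
  read_standardization_rules(
    system.file("rules", "default.yaml", package = "mrioverlap", mustWork = TRUE))
}

rule_matches <- function(rule, seq) {
  for (field in names(rule$when)) {
    cond <- rule$when[[field]]
    if (field %in% NUMERIC_RULE_FIELDS) {
      val <- if (field == "max_b") {
        if (length(seq$b_values)) max(seq$b_values) else -Inf
      } else {
        seq[[field]]
      }
      if (is.null(val)) return(FALSE)
      if (!is.null(cond$gt) && !(val > cond$gt)) return(FALSE)
      if (!is.null(cond$ge) && !(val >= cond$ge)) return(FALSE)
      if (!is.null(cond$lt) && !(val < cond$lt)) return(FALSE)
      if (!is.null(cond$le) && !(val <= cond$le)) return(FALSE)
    } else {
      if (!seq[[field]] %in% unlist(cond)) return(FALSE)
    }
  }
  TRUE
}

#' Classify the contrast weighting of a pulse sequence
#'
#' Applies the ordered rule set to the sequence's acquisition parameters and
#' returns the first matching rule's token (`"T1"`, `"T2"`, `"PD"`, `"FLAIR"`,
#' `"STIR"`, `"DWI"`, ... or the catch-all's `"OTHER"`). The user-given name is
#' never consulted.
#'
#' @param seq a [sequence_acquisition].
#' @param rules a `standardization_rules` object; defaults to the shipped
#'   table.
#' @return length-1 character token.
#' @export
classify_weighting <- function(seq, rules = default_standardization_rules()) {
  stopifnot(inherits(seq, "sequence_acquisition"),
            inherits(rules, "standardization_rules"))
  for (rule in rules) {
    if (rule_matches(rule, seq)) return(rule$token)
  }
  # unreachable: the constructor guarantees a terminal catch-all
  abort("no rule matched (rule set lacks a catch-all)")
}

#' Standardize a sequence name from acquisition parameters
#'
#' Assembles the standardized name as tokens in a fixed order: weighting,
#' technique family, orientation, dimensionality, fat-saturation marker
#' (`FS`), post-contrast marker (`POST`). `UNKNOWN` technique or orientation
#' is omitted. The result is a pure function of the acquisition parameters and
#' the rule set — the user-given `raw_name` plays no part — so two sequences
#' with identical parameters always standardize identically, whatever each
#' site called them.
#'
#' @param seq a [sequence_acquisition].
#' @param rules a `standardization_rules` object.
#' @param include_dimensionality include the `2D`/`3D` token (default `TRUE`).
#' @param include_contrast include the `POST` marker for post-contrast
#'   acquisitions (default `TRUE`).
#' @return length-1 character, e.g. `"T1 SE SAG 2D"` or `"FLAIR TSE TRA 2D FS"`.
#' @export
standardize_sequence <- function(seq, rules = default_standardization_rules(),
                                 include_dimensionality = TRUE,
                                 include_contrast = TRUE) {
  tokens <- classify_weighting(seq, rules)
  if (seq$technique != "UNKNOWN") tokens <- c(tokens, seq$technique)
  if (seq$orientation != "UNKNOWN") tokens <- c(tokens, seq$orientation)
  if (include_dimensionality) tokens <- c(tokens, seq$dimensionality)
  if (seq$fat_suppression) tokens <- c(tokens, "FS")
  if (include_contrast && seq$contrast_phase == "POST") tokens <- c(tokens, "POST")
  paste(tokens, collapse = " ")
}

#' Standardize every sequence name in a protocol tree
#'
#' Returns a copy of the tree in which every sequence is annotated with its
#' standardized name (`std_name`), plus the unique-name summary: how many
#' distinct raw spellings the tree used versus how many distinct standardized
#' names remain. On trees whose raw names are synonym-noised spellings of a
#' smaller set of parameter tuples, the standardized count drops — the
#' mechanism by which standardization makes sequences comparable across
#' scanners.
#'
#' @param tree a [protocol_tree].
#' @param rules a `standardization_rules` object.
#' @param ... passed to [standardize_sequence()].
#' @return list with `tree` (annotated copy), `n_unique_raw`,
#'   `n_unique_standardized`.
#' @export
standardize_tree <- function(tree, rules = default_standardization_rules(), ...) {
  stopifnot(inherits(tree, "protocol_tree"))
  raw_names <- character(0)
  std_names <- character(0)
  tree$protocols <- lapply(tree$protocols, function(pr) {
    pr$sequences <- lapply(pr$sequences, function(s) {
      s$std_name <- standardize_sequence(s, rules, ...)
      s
    })
    pr
  })
  for (pr in tree$protocols) {
    raw_names <- c(raw_names, vapply(pr$sequences, `[[`, character(1), "raw_name"))
    std_names <- c(std_names, vapply(pr$sequences, `[[`, character(1), "std_name"))
  }
  list(tree = tree,
       n_unique_raw = length(unique(raw_names)),
       n_unique_standardized = length(unique(std_names)))
}
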