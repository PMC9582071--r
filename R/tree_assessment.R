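#' Distinct names used in a protocol tree at one naming level
#'
#' The unit of the cross-scanner heterogeneity assessment: the set of distinct
#' names a scanner's tree uses, at raw sequence-name level, at standardized
#' sequence-name level, or at protocol-name level. A name shared by several
#' protocols counts once (set semantics).
#'
#' @param tree a [protocol_tree].
#' @param level `"raw"`, `"standardized"` or `"protocol"`.
#' @param rules a `standardization_rules` object; required for
#'   `level = "standardized"`.
#' @return character vector (a set) of names; empty, with a warning, for an
#'   empty tree.
#' @export
name_sets <- function(tree, level = c("raw", "standardized", "protocol"),
                      rules = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(tree, "protocol_tree"))
  if (!length(tree$protocols)) {
    warning(sprintf("scanner %s: empty protocol tree, empty name set",
                    sQuote(tree$scanner_id)), call. = FALSE)
    return(character(0))
  }
  if (level == "protocol") {
    return(unique(vapply(tree$protocols, `[[`, character(1), "protocol_name")))
  }
  if (level == "standardized") {
    if (is.null(rules)) abort("level \"standardized\" requires a rule set")
    tree <- standardize_tree(tree, rules)$tree
    field <- "std_name"
  } else {
    field <- "raw_name"
  }
  unique(unlist(lapply(tree$protocols, function(pr) {
    vapply(pr$sequences, `[[`, character(1), field)
  }), use.names = FALSE))
}

#' Arithmetic mean of per-scanner counts with a display value
#'
#' @param counts nonempty vector of positive integers.
#' @return list with `mean` (full precision) and `display` (integer, rounded
#'   half away from zero — so a mean of 103.33 displays as 103 and 103.5 as
#'   104).
#' @export
mean_counts <- function(counts) {
  if (!length(counts)) abort("mean_counts needs a nonempty count vector")
  m <- mean(counts)
  list(mean = m, display = round_half_away(m))
}

#' Chi-square test of count variability, raw vs standardized names
#'
#' Tests homogeneity of the 2 x K contingency table whose rows are the
#' per-scanner unique raw-name counts and unique standardized-name counts and
#' whose columns are the K scanners, with expected counts from the margins and
#' K - 1 degrees of freedom. Identical or proportional rows give a statistic
#' of exactly 0. Note the construction tests whether the raw/standardized
#' *ratio* varies across scanners, not whether standardization reduces the
#' counts overall; see the methods vignette for the caveats of reading it as
#' a variability-reduction test.
#'
#' @param raw_counts,std_counts equal-length vectors of positive per-scanner
#'   counts.
#' @return list of class `variability_chisq` with `statistic`, `df`,
#'   `p_value`, `observed`, `expected`.
#' @export
variability_chisq <- function(raw_counts, std_counts) {
  if (!length(raw_counts) || length(raw_counts) != length(std_counts))
    abort("raw and standardized count vectors must be nonempty and equal length")
  if (any(c(raw_counts, std_counts) <= 0))
    abort("all counts must be positive")
  tab <- rbind(raw = raw_counts, standardized = std_counts)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0))
    abort("zero expected cell count; merge or drop the affected scanner column")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = unname(ht$p.value), observed = tab,
                 expected = expected),
            class = "variability_chisq")
}

#' Compare protocol trees across scanners against a reference
#'
#' The heterogeneity assessment: for every scanner, the number of unique raw
#' sequence names, unique standardized sequence names and unique protocol
#' names; for every non-reference scanner, the overlap coefficient of its name
#' set against the reference scanner's at each of the three levels; the mean
#' of each count across scanners (full precision plus an integer display
#' value); and the chi-square variability test on the raw-vs-standardized
#' count table. A naming level on which either tree has an empty name set
#' yields an undefined (`NA`) coefficient, reported as such.
#'
#' @param trees list of two or more [protocol_tree] objects with distinct
#'   scanner ids.
#' @param reference_scanner scanner id the coefficients are computed against.
#' @param rules a `standardization_rules` object.
#' @param all_pairs also compute the coefficients for every unordered scanner
#'   pair (default `FALSE`, reference-only as in a per-reference report).
#' @return object of class `tree_comparison` with fields `reference_scanner`,
#'   `scanners` (data.frame: counts and `oc_raw`/`oc_standardized`/
#'   `oc_protocol` vs reference, `NA` on the reference row), `means` (list of
#'   [mean_counts()] results per level), `chisq` (a `variability_chisq`) and,
#'   if requested, `pairs`.
#' @export
compare_trees <- function(trees, reference_scanner,
                          rules = default_standardization_rules(),
                          all_pairs = FALSE) {
  if (length(trees) < 2) abort("tree comparison needs at least two trees")
  ids <- vapply(trees, `[[`, character(1), "scanner_id")
  if (anyDuplicated(ids)) abort("duplicate scanner ids in tree list")
  if (!reference_scanner %in% ids)
    abort("reference scanner %s not among the trees", sQuote(reference_scanner))
  names(trees) <- ids
  sets <- lapply(trees, function(tr) list(
    raw = name_sets(tr, "raw"),
    standardized = name_sets(tr, "standardized", rules),
    protocol = name_sets(tr, "protocol")
  ))
  oc_or_na <- function(a, b) {
    if (!length(a) || !length(b)) NA_real_ else overlap_coefficient(a, b)
  }
  # keyed by scanner id, reference first then lexicographic: invariant to the
  # order the trees were supplied in
  ord <- c(reference_scanner, sort(setdiff(ids, reference_scanner)))
  ref <- sets[[reference_scanner]]
  scanners <- do.call(rbind, lapply(ord, function(id) {
    s <- sets[[id]]
    is_ref <- id == reference_scanner
    data.frame(
      scanner_id = id,
      site_id = trees[[id]]$site_id,
      n_raw_names = length(s$raw),
      n_standardized_names = length(s$standardized),
      n_protocol_names = length(s$protocol),
      oc_raw = if (is_ref) NA_real_ else oc_or_na(ref$raw, s$raw),
      oc_standardized = if (is_ref) NA_real_ else
        oc_or_na(ref$standardized, s$standardized),
      oc_protocol = if (is_ref) NA_real_ else oc_or_na(ref$protocol, s$protocol),
      stringsAsFactors = FALSE
    )
  }))
  means <- list(
    raw_names = mean_counts(scanners$n_raw_names),
    standardized_names = mean_counts(scanners$n_standardized_names),
    protocol_names = mean_counts(scanners$n_protocol_names)
  )
  chisq <- variability_chisq(scanners$n_raw_names, scanners$n_standardized_names)
  out <- list(reference_scanner = reference_scanner, scanners = scanners,
              means = means, chisq = chisq)
  if (all_pairs) {
    combs <- utils::combn(ord, 2)
    out$pairs <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
      a <- combs[1, k]; b <- combs[2, k]
      data.frame(scanner_a = a, scanner_b = b,
                 oc_raw = oc_or_na(sets[[a]]$raw, sets[[b]]$raw),
                 oc_standardized = oc_or_na(sets[[a]]$standardized,
                                            sets[[b]]$standardized),
                 oc_protocol = oc_or_na(sets[[a]]$protocol, sets[[b]]$protocol),
                 stringsAsFactors = FALSE)
    }))
  }
  class(out) <- "tree_comparison"
  out
}

#' @export
print.tree_comparison <- function(x, ...) {
  cat(sprintf("Protocol-tree comparison (reference: %s)\n", x$reference_scanner))
  print(x$scanners, row.names = FALSE, digits = 3)
  cat(sprintf("Means: %d protocols, %d raw sequence names, %d standardized\n",
              x$means$protocol_names$display, x$means$raw_names$display,
              x$means$standardized_names$display))
  cat(sprintf("Raw-vs-standardized variability: X^2 = %.3f, df = %d, p = %.3f\n",
              x$chisq$statistic, x$chisq$df, x$chisq$p_value))
  invisible(x)
}
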