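#' Jaccard index of two finite sets
#'
#' `J(A, B) = |A intersect B| / |A union B|`. Sets are given as vectors and
#' deduplicated; undefined (error) when both are empty.
#'
#' @param a,b vectors interpreted as finite sets.
#' @return ratio in \[0, 1\].
#' @examples
#' jaccard(c(1, 2, 3), c(2, 3, 4, 5)) # 0.4
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b)) abort("Jaccard index undefined for two empty sets")
  length(intersect(a, b)) / length(union(a, b))
}

#' Overlap (Szymkiewicz-Simpson) coefficient of two finite sets
#'
#' `oc(A, B) = |A intersect B| / min(|A|, |B|)`. Unlike the Jaccard index the
#' overlap coefficient is sensitive to the set sizes: whenever one set is a
#' subset of the other it equals 1, which makes it the better-behaved measure
#' for small and unequally sized sets. Undefined (error) when either set is
#' empty, since the minimum size would be 0.
#'
#' @param a,b nonempty vectors interpreted as finite sets.
#' @return ratio in \[0, 1\].
#' @examples
#' overlap_coefficient(c(1, 2, 3), c(2, 3, 4, 5)) # 2/3
#' overlap_coefficient("x", c("x", "y"))          # 1: subset
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b))
    abort("overlap coefficient undefined when either set is empty")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Complement overlap coefficient of one protocol against all others
#'
#' For protocol `A` in an association map, the complement overlap is
#' `oc(A, C)` where `C` is the union of every other protocol's element set in
#' the (filtered) dataset. It measures how much of `A`'s admitting-diagnosis
#' profile recurs anywhere else: 0 means `A`'s diagnoses are unique to it, so a
#' protocol decision could rest on the diagnosis alone. Note this is the
#' overlap against the union of the *other* sets, not against the literal
#' set-theoretic complement of `A` (which would be disjoint from `A` by
#' definition and give an identically zero, uninformative statistic).
#'
#' @param label protocol name, present in `assoc`.
#' @param assoc named list: protocol name -> character vector of element keys
#'   (see [code_set_element]).
#' @return ratio in \[0, 1\], or `NA_real_` when the dataset holds only this
#'   protocol (empty complement: the coefficient is undefined, never silently
#'   0 or 1).
#' @export
complement_overlap <- function(label, assoc) {
  if (!label %in% names(assoc))
    abort("unknown protocol %s", sQuote(label))
  others <- unique(unlist(assoc[setdiff(names(assoc), label)], use.names = FALSE))
  if (!length(others)) return(NA_real_)
  overlap_coefficient(assoc[[label]], others)
}

new_overlap_matrix <- function(labels, values, complement, element_counts) {
  stopifnot(is.matrix(values), nrow(values) == length(labels),
            ncol(values) == length(labels))
  if (anyDuplicated(labels)) abort("overlap matrix labels must be unique")
  if (any(element_counts < 1)) abort("element counts must be >= 1")
  if (max(abs(values - t(values))) > 1e-12) abort("overlap matrix must be symmetric")
  if (max(abs(diag(values) - 1)) > 1e-12) abort("overlap matrix diagonal must be 1")
  rng <- range(c(values, complement[!is.na(complement)]))
  if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12) abort("overlap values must lie in [0, 1]")
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values,
                 complement = stats::setNames(complement, labels),
                 element_counts = stats::setNames(as.integer(element_counts), labels)),
            class = "overlap_matrix")
}

#' Pairwise overlap-coefficient matrix with complement column
#'
#' Computes `oc` for every ordered pair of protocols plus, per protocol, the
#' complement overlap against the union of all the others — the tabular twin
#' of the annotated heat maps used to visualize diagnosis/protocol mapping
#' consistency.
#'
#' @param assoc named list: protocol name -> nonempty character vector of
#'   element keys.
#' @param order character vector, a permutation of `names(assoc)` fixing the
#'   row/column order.
#' @return object of class `overlap_matrix` with fields `labels`, `values`
#'   (symmetric, unit diagonal), `complement` (`NA` when undefined) and
#'   `element_counts`.
#' @export
pairwise_matrix <- function(assoc, order = names(assoc)) {
  if (!length(assoc)) abort("association map is empty")
  if (is.null(names(assoc)) || anyDuplicated(names(assoc)))
    abort("association map must have unique names")
  if (!setequal(order, names(assoc)) || length(order) != length(assoc))
    abort("label order must be a permutation of the association map's names")
  empty <- names(assoc)[lengths(assoc) == 0]
  if (length(empty))
    abort("empty element set for protocol(s): %s",
          paste(sQuote(empty), collapse = ", "))
  assoc <- lapply(assoc, unique)[order]
  n <- length(order)
  vals <- diag(nrow = n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        vals[i, j] <- vals[j, i] <- overlap_coefficient(assoc[[i]], assoc[[j]])
      }
    }
  }
  comp <- vapply(order, complement_overlap, numeric(1), assoc = assoc)
  new_overlap_matrix(order, vals, comp, lengths(assoc))
}

#' Write an overlap matrix to CSV
#'
#' Fixed export format: first column holds the protocol label, then one column
#' per protocol in matrix order, and a final column literally named
#' `"complement"`. Values are rendered with exactly two decimal places; an
#' undefined complement becomes an empty cell. Rounding happens only here, at
#' the output boundary — the in-memory matrix keeps full precision.
#'
#' @param matrix an `overlap_matrix` (see [pairwise_matrix]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "overlap_matrix"))
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))
  out <- data.frame(protocol = matrix$labels, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (j in seq_along(matrix$labels)) {
    out[[matrix$labels[j]]] <- fmt(matrix$values[, j])
  }
  out[["complement"]] <- fmt(matrix$complement)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("Overlap-coefficient matrix: %d protocols\n", length(x$labels)))
  shown <- cbind(round(x$values, 2), complement = round(x$complement, 2))
  print(shown)
  invisible(x)
}

#' Multi-label statistics of an exam log
#'
#' Summarizes the admitting-diagnosis labeling of a set of exams: label
#' *cardinality* (mean number of ICD-10 codes per exam), *density*
#' (cardinality divided by the number of unique codes) and *diversity* (number
#' of distinct code combinations). Exams with an empty code set carry no label
#' information and are excluded before computing the statistics.
#'
#' @param records an [exam_log] data.frame, or a bare list of character code
#'   vectors.
#' @return object of class `label_statistics` with fields `n_exams`,
#'   `n_unique_codes`, `cardinality`, `density`, `diversity`.
#' @export
label_statistics <- function(records) {
  codes <- if (is.data.frame(records)) records$admitting_codes else records
  if (!is.list(codes)) abort("records must be an exam_log or a list of code vectors")
  codes <- codes[lengths(codes) > 0]
  if (!length(codes)) abort("no exams with a nonempty admitting-code set")
  cardinality <- mean(lengths(codes))
  n_unique <- length(unique(unlist(codes, use.names = FALSE)))
  structure(list(
    n_exams = length(codes),
    n_unique_codes = n_unique,
    cardinality = cardinality,
    density = cardinality / n_unique,
    diversity = length(unique(vapply(codes, code_set_element, character(1))))
  ), class = "label_statistics")
}

#' @export
print.label_statistics <- function(x, ...) {
  cat(sprintf(paste0(
    "Exams: %d\nUnique ICD-10 codes: %d\nLabel cardinality: %.1f\n",
    "Label density: %.2f\nLabel diversity (code sets): %d\n"),
    x$n_exams, x$n_unique_codes, x$cardinality, x$density, x$diversity))
  invisible(x)
}
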