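# Independent naive oracles (kept free of any package internals beyond basic
# set ops) and compact fixture builders shared across the test files.

# element-by-element membership count, no set functions
oracle_intersection_size <- function(a, b) {
  a <- unique(a); b <- unique(b)
  n <- 0L
  for (x in a) {
    for (y in b) if (identical(x, y)) { n <- n + 1L; break }
  }
  n
}

oracle_oc <- function(a, b) {
  a <- unique(a); b <- unique(b)
  oracle_intersection_size(a, b) / min(length(a), length(b))
}

oracle_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  inter <- oracle_intersection_size(a, b)
  inter / (length(a) + length(b) - inter)
}

# brute-force double-loop recomputation of the full matrix + complement column
oracle_matrix <- function(assoc, order) {
  n <- length(order)
  vals <- matrix(0, n, n, dimnames = list(order, order))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      vals[i, j] <- oracle_oc(assoc[[order[i]]], assoc[[order[j]]])
    }
  }
  comp <- sapply(order, function(lab) {
    rest <- unlist(assoc[setdiff(order, lab)], use.names = FALSE)
    if (!length(rest)) NA_real_ else oracle_oc(assoc[[lab]], rest)
  })
  list(values = vals, complement = comp)
}

# textbook chi-square of homogeneity, coded from the closed form
oracle_chisq <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# random association map: protocol name -> element-key set
random_assoc <- function(n_protocols, max_elements, universe = 50) {
  pool <- sprintf("el%03d", seq_len(universe))
  assoc <- lapply(seq_len(n_protocols), function(i) {
    unique(sample(pool, sample.int(max_elements, 1)))
  })
  names(assoc) <- sprintf("P%02d", seq_len(n_protocols))
  assoc
}

# compact exam-log builder: codes given as ";"-joined strings
make_log <- function(protocols, codes, region = "spine",
                     scanner = "scanner-1", site = "site-A") {
  n <- length(protocols)
  exam_log(data.frame(
    exam_id = sprintf("e%03d", seq_len(n)),
    scanner_id = scanner, site_id = site, body_region = region,
    protocol_name = protocols, admitting_codes = codes,
    stringsAsFactors = FALSE))
}

# minimal sequence shorthand
seq_acq <- function(raw_name = "seq", tr = 500, te = 10, ti = NULL,
                    technique = "SE", orientation = "SAG", flip = 90,
                    b = numeric(0), fs = FALSE, dim = "2D", phase = "NONE") {
  sequence_acquisition(raw_name = raw_name, tr_ms = tr, te_ms = te, ti_ms = ti,
                       flip_deg = flip, technique = technique,
                       orientation = orientation, fat_suppression = fs,
                       b_values = b, contrast_phase = phase,
                       dimensionality = dim)
}

make_tree <- function(scanner_id, site_id, proto_specs) {
  protocol_tree(scanner_id, site_id, lapply(names(proto_specs), function(pn) {
    protocol_definition(pn, "spine", proto_specs[[pn]])
  }))
}

toy_rules <- function() default_standardization_rules()
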