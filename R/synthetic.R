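#' Configuration for the synthetic exam-log and protocol-tree generator
#'
#' The generator emulates the statistical structure of a real radiology
#' practice's MRI exam log and scanner protocol trees — not clinical semantics
#' (which diagnosis truly warrants which protocol), only the shape the
#' analyses consume: per-exam code-set sizes, skewed code popularity, skewed
#' protocol frequencies, and cross-scanner naming-synonym noise over a shared
#' core of parameterized sequences. Defaults reproduce the scale of a
#' six-month, three-scanner practice extract: 727 spine exams over 127 unique
#' codes with mean label cardinality 1.1 and protocol frequencies spanning
#' 6-341, 249 brain/head exams over 98 codes with cardinality 1.2, roughly 100
#' protocols and 200 raw sequence-name spellings per scanner.
#'
#' @param seed integer root seed; together with the configuration it fully
#'   determines every output (each component draws from its own derived
#'   stream, so adding a component does not perturb the others).
#' @param n_scanners,n_sites number of scanners and sites; scanners are spread
#'   over sites in order (with 3 scanners and 2 sites, scanners 1-2 share
#'   site A and scanner 3 sits at site B).
#' @param regions named list of region settings, each a list with
#'   `n_protocols`, `n_exams`, `code_vocabulary_size`,
#'   `cardinality_distribution` (named probabilities for 1, 2, 3... codes per
#'   exam, summing to 1), `protocol_frequency_range` (`c(low, high)`),
#'   `zipf_exponent` (code-popularity skew, default 1.2) and
#'   `planted_overlaps`, a list of `list(i, j, oc)` protocol-index pairs whose
#'   pairwise overlap coefficient the generator realizes exactly by explicit
#'   shared/private element construction.
#' @param tree list of tree settings: `n_protocols_per_scanner`,
#'   `sequences_per_protocol` (`c(min, max)`), `n_core_parameter_tuples`
#'   (acquisition-parameter tuples shared by all scanners),
#'   `synonyms_per_tuple` (spellings available per tuple),
#'   `synonym_noise_rate` (probability a sequence slot uses a non-canonical
#'   spelling), `site_specific_sequence_rate` (site-only tuples as a fraction
#'   of the core) and `protocol_name_overlap` (fraction of protocol names
#'   shared by all scanners).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_scanners = 3L,
    n_sites = 2L,
    regions = list(
      spine = list(n_protocols = 18, n_exams = 727, code_vocabulary_size = 127,
                   cardinality_distribution = c("1" = 0.9, "2" = 0.1),
                   protocol_frequency_range = c(6, 341)),
      `brain/head` = list(n_protocols = 16, n_exams = 249,
                          code_vocabulary_size = 98,
                          cardinality_distribution = c("1" = 0.8, "2" = 0.2),
                          protocol_frequency_range = c(6, 120))
    ),
    tree = list()) {
  region_defaults <- list(zipf_exponent = 1.2, planted_overlaps = list())
  tree_defaults <- list(n_protocols_per_scanner = 100L,
                        sequences_per_protocol = c(3L, 8L),
                        n_core_parameter_tuples = 110L,
                        synonyms_per_tuple = 2L,
                        synonym_noise_rate = 0.5,
                        site_specific_sequence_rate = 0.15,
                        protocol_name_overlap = 0.8)
  regions <- lapply(regions, function(rg) {
    # merged by name, except the unnamed-list field which modifyList would mangle
    merged <- utils::modifyList(region_defaults,
                                rg[setdiff(names(rg), "planted_overlaps")])
    merged$planted_overlaps <- rg$planted_overlaps %||% list()
    merged
  })
  tree <- utils::modifyList(tree_defaults, tree)
  for (rn in names(regions)) {
    rg <- regions[[rn]]
    p <- rg$cardinality_distribution
    if (abs(sum(p) - 1) > 1e-9)
      abort("region %s: cardinality probabilities must sum to 1", sQuote(rn))
    fr <- rg$protocol_frequency_range
    if (length(fr) != 2 || fr[1] > fr[2] || fr[1] < 1)
      abort("region %s: malformed protocol_frequency_range", sQuote(rn))
    for (po in rg$planted_overlaps) {
      if (is.null(po$i) || is.null(po$j) || is.null(po$oc) ||
          po$i == po$j || po$oc < 0 || po$oc > 1 ||
          po$i > rg$n_protocols || po$j > rg$n_protocols)
        abort("region %s: malformed planted overlap entry", sQuote(rn))
    }
    planted_ids <- unlist(lapply(rg$planted_overlaps, function(po) c(po$i, po$j)))
    if (anyDuplicated(planted_ids))
      abort("region %s: a protocol may appear in at most one planted pair", sQuote(rn))
  }
  if (tree$synonym_noise_rate < 0 || tree$synonym_noise_rate > 1 ||
      tree$site_specific_sequence_rate < 0 || tree$site_specific_sequence_rate > 1)
    abort("tree rates must lie in [0, 1]")
  structure(list(seed = as.integer(seed), n_scanners = as.integer(n_scanners),
                 n_sites = as.integer(n_sites), regions = regions, tree = tree),
            class = "synthetic_config")
}

#' Read a generator configuration from YAML
#'
#' Thin wrapper: the YAML document carries the [synthetic_config()] arguments
#' (`seed`, `n_scanners`, `n_sites`, `regions`, `tree`); absent entries take
#' the built-in defaults. The package ships `configs/paper_scale.yaml` (the
#' default study-scale conditions) and `configs/toy.yaml` (a small log with a
#' planted overlap pair, handy for demonstrations).
#'
#' @param path path to the YAML file.
#' @param seed optional integer overriding the file's seed.
#' @return list of class `synthetic_config`.
#' @export
read_synthetic_config <- function(path, seed = NULL) {
  doc <- yaml::read_yaml(path)
  if (!is.null(doc$regions)) {
    doc$regions <- lapply(doc$regions, function(rg) {
      if (!is.null(rg$cardinality_distribution))
        rg$cardinality_distribution <- unlist(rg$cardinality_distribution)
      if (!is.null(rg$protocol_frequency_range))
        rg$protocol_frequency_range <- unlist(rg$protocol_frequency_range)
      rg
    })
  }
  if (!is.null(seed)) doc$seed <- seed
  do.call(synthetic_config, doc)
}

#' Generate a vocabulary of ICD-10-shaped codes
#'
#' Distinct codes in canonical form (letter, two digits, usually a one- or
#' two-character subcode), deterministic under the seed. Codes are shaped like
#' ICD-10 but carry no clinical meaning.
#'
#' @param size number of distinct codes, >= 1.
#' @param seed integer seed.
#' @return character vector of `size` distinct canonical codes.
#' @export
generate_code_vocabulary <- function(size, seed) {
  if (size < 1) abort("vocabulary size must be >= 1")
  set.seed(stream_seed(seed, "code-vocabulary"))
  chapters <- c("M", "G", "S", "R", "C", "D", "I", "J", "K", "N", "T", "F", "H", "E")
  out <- character(0)
  while (length(out) < size) {
    n <- size - length(out)
    major <- sprintf("%s%02d", sample(chapters, n, replace = TRUE),
                     sample(0:99, n, replace = TRUE))
    sub <- ifelse(stats::runif(n) < 0.75,
                  sprintf(".%d", sample(0:9, n, replace = TRUE)),
                  ifelse(stats::runif(n) < 0.4,
                         sprintf(".%02d", sample(0:99, n, replace = TRUE)), ""))
    out <- unique(c(out, paste0(major, sub)))
  }
  canonicalize_code(out[seq_len(size)])
}

make_protocol_names <- function(region, n) {
  stems <- c("WITHOUT", "W&WO", "WITH", "POST OP", "METAL", "TUMOR",
             "SCREENING", "ROUTINE")
  prefix <- toupper(gsub("[^a-z]+", "-", region))
  sprintf("%s-%02d/%s", prefix, seq_len(n),
          stems[(seq_len(n) - 1) %% length(stems) + 1])
}

site_of_scanner <- function(s, n_scanners, n_sites) {
  chunk <- ceiling(n_scanners / n_sites)
  paste0("site-", LETTERS[min(n_sites, ceiling(s / chunk))])
}

# Heavy-tailed protocol frequencies within [low, high] summing exactly to
# n_exams. Draws from a stretched uniform power shape, then repairs the sum by
# unit steps that respect the bounds.
draw_frequencies <- function(n, n_exams, range) {
  low <- range[1]; high <- range[2]
  if (n * low > n_exams || n * high < n_exams)
    abort("frequency range [%d, %d] cannot place %d exams on %d protocols",
          low, high, n_exams, n)
  w <- low * (high / low)^(stats::runif(n)^3)
  f <- pmin(high, pmax(low, round(w * n_exams / sum(w))))
  gap <- n_exams - sum(f)
  while (gap != 0) {
    if (gap > 0) {
      idx <- which(f < high)
      take <- idx[seq_len(min(length(idx), gap))]
      f[take] <- f[take] + 1
    } else {
      idx <- which(f > low)
      take <- idx[seq_len(min(length(idx), -gap))]
      f[take] <- f[take] - 1
    }
    gap <- n_exams - sum(f)
  }
  f
}

# Enumerate distinct code combinations (singles, then pairs, then triples)
# from a reserved slice of the vocabulary, used to realize planted overlaps
# exactly.
reserved_combos <- function(reserve, n_needed) {
  combos <- as.list(reserve)
  if (length(combos) < n_needed && length(reserve) >= 2) {
    prs <- utils::combn(reserve, 2, simplify = FALSE)
    combos <- c(combos, prs)
  }
  if (length(combos) < n_needed && length(reserve) >= 3) {
    tri <- utils::combn(reserve, 3, simplify = FALSE)
    combos <- c(combos, tri)
  }
  combos
}

# Largest m' <= m with target * m' integral (so the planted coefficient is
# realized exactly); NA when none exists at or above `low`.
exact_planted_size <- function(m, target, low) {
  for (mp in seq(m, low)) {
    if (abs(target * mp - round(target * mp)) < 1e-9) return(mp)
  }
  NA_integer_
}

#' Generate a synthetic exam log
#'
#' One region at a time: protocol frequencies are drawn heavy-tailed within
#' the configured range (summing exactly to the region's exam count), each
#' exam's code-set size follows the cardinality distribution, and code
#' popularity is Zipf-like so single-code occurrence spans roughly 1 to the
#' observed maximum. For every planted `(i, j, oc)` pair the two protocols'
#' element sets are built explicitly — `oc * min(|A_i|, |A_j|)` shared
#' combinations plus private ones, all drawn from a reserved vocabulary slice
#' disjoint per pair — so the pipeline-recovered matrix cell equals the target
#' exactly (the smaller protocol's frequency is nudged down to the nearest
#' size at which the target is exactly realizable; the freed exams move to
#' unplanted protocols). Infeasible targets are rejected naming the pair.
#'
#' @param config a [synthetic_config()].
#' @return an [exam_log] data.frame covering all configured regions, with a
#'   `planted` attribute (data.frame of planted pairs and their protocol
#'   names) for downstream verification.
#' @export
generate_exam_log <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  rows <- list()
  planted_info <- list()
  exam_counter <- 0L
  for (rn in names(config$regions)) {
    rg <- config$regions[[rn]]
    vocab <- generate_code_vocabulary(rg$code_vocabulary_size,
                                      stream_seed(config$seed, paste0("vocab/", rn)))
    set.seed(stream_seed(config$seed, paste0("exams/", rn)))
    proto_names <- make_protocol_names(rn, rg$n_protocols)
    f <- draw_frequencies(rg$n_protocols, rg$n_exams, rg$protocol_frequency_range)
    low <- rg$protocol_frequency_range[1]

    planted_ids <- unlist(lapply(rg$planted_overlaps, function(po) c(po$i, po$j)))
    plan <- vector("list", rg$n_protocols)

    # reserved vocabulary tail for exact planted construction
    n_reserve <- if (length(rg$planted_overlaps))
      max(6L, min(30L, floor(rg$code_vocabulary_size / 4))) else 0L
    reserve <- if (n_reserve) utils::tail(vocab, n_reserve) else character(0)
    combo_cursor <- 0L

    for (po in rg$planted_overlaps) {
      m_holder <- if (f[po$i] <= f[po$j]) po$i else po$j
      m <- f[m_holder]
      mp <- exact_planted_size(m, po$oc, low)
      if (is.na(mp))
        abort("planted overlap (%s, %s): target %.3f not exactly realizable at sizes >= %d",
              proto_names[po$i], proto_names[po$j], po$oc, low)
      freed <- m - mp
      f[m_holder] <- mp
      if (freed > 0) {
        open <- setdiff(seq_len(rg$n_protocols), planted_ids)
        for (k in open) {
          room <- rg$protocol_frequency_range[2] - f[k]
          add <- min(room, freed)
          f[k] <- f[k] + add
          freed <- freed - add
          if (freed == 0) break
        }
      }
      shared_n <- as.integer(round(po$oc * min(f[po$i], f[po$j])))
      need <- f[po$i] + f[po$j] - shared_n
      combos <- reserved_combos(reserve, combo_cursor + need)
      if (combo_cursor + need > length(combos))
        abort("planted overlap (%s, %s): set sizes too large for the reserved vocabulary slice",
              proto_names[po$i], proto_names[po$j])
      pool <- combos[combo_cursor + seq_len(need)]
      combo_cursor <- combo_cursor + need
      shared <- pool[seq_len(shared_n)]
      priv_i <- pool[shared_n + seq_len(f[po$i] - shared_n)]
      priv_j <- pool[shared_n + f[po$i] - shared_n + seq_len(f[po$j] - shared_n)]
      plan[[po$i]] <- c(shared, priv_i)
      plan[[po$j]] <- c(shared, priv_j)
      planted_info[[length(planted_info) + 1]] <- data.frame(
        body_region = tolower(rn), protocol_i = proto_names[po$i],
        protocol_j = proto_names[po$j], target_oc = po$oc,
        stringsAsFactors = FALSE)
    }

    zipf_w <- seq_len(rg$code_vocabulary_size)^(-rg$zipf_exponent)
    vocab_shuffled <- sample(vocab)
    card_sizes <- as.integer(names(rg$cardinality_distribution))

    region_rows <- vector("list", rg$n_protocols)
    for (p in seq_len(rg$n_protocols)) {
      np <- f[p]
      codes <- if (!is.null(plan[[p]])) {
        plan[[p]][sample.int(np)]  # one distinct element per exam, order shuffled
      } else {
        ks <- card_sizes[sample.int(length(card_sizes), np, replace = TRUE,
                                    prob = rg$cardinality_distribution)]
        lapply(ks, function(k) sample(vocab_shuffled, k, prob = zipf_w))
      }
      region_rows[[p]] <- data.frame(
        exam_id = sprintf("E%05d", exam_counter + seq_len(np)),
        scanner_id = paste0("scanner-", sample.int(config$n_scanners, np,
                                                   replace = TRUE)),
        body_region = tolower(rn),
        protocol_name = proto_names[p],
        exam_date = as.character(as.Date("2019-01-01") +
                                   sample.int(181, np, replace = TRUE) - 1),
        stringsAsFactors = FALSE)
      region_rows[[p]]$admitting_codes <- codes
      exam_counter <- exam_counter + np
    }
    rows[[rn]] <- do.call(rbind, region_rows)
  }
  df <- do.call(rbind, rows)
  df$site_id <- vapply(as.integer(sub("scanner-", "", df$scanner_id)),
                       site_of_scanner, character(1),
                       n_scanners = config$n_scanners, n_sites = config$n_sites)
  rownames(df) <- NULL
  log <- exam_log(df)
  attr(log, "planted") <- if (length(planted_info))
    do.call(rbind, planted_info) else NULL
  log
}

# acquisition-parameter archetypes the tuple generator draws from
TUPLE_ARCHETYPES <- list(
  t1se = function() list(technique = sample(c("SE", "TSE"), 1),
                         tr_ms = stats::runif(1, 400, 700),
                         te_ms = stats::runif(1, 8, 20)),
  t2tse = function() list(technique = "TSE", tr_ms = stats::runif(1, 3000, 6000),
                          te_ms = stats::runif(1, 90, 130)),
  pd = function() list(technique = "TSE", tr_ms = stats::runif(1, 2500, 4000),
                       te_ms = stats::runif(1, 10, 25)),
  flair = function() list(technique = "TSE", tr_ms = stats::runif(1, 8000, 10000),
                          te_ms = stats::runif(1, 90, 130),
                          ti_ms = stats::runif(1, 2000, 2600),
                          inversion_recovery = TRUE),
  stir = function() list(technique = "TSE", tr_ms = stats::runif(1, 3000, 5000),
                         te_ms = stats::runif(1, 40, 70),
                         ti_ms = stats::runif(1, 150, 250),
                         inversion_recovery = TRUE),
  dwi = function() list(technique = "EPI", tr_ms = stats::runif(1, 3000, 6000),
                        te_ms = stats::runif(1, 60, 90),
                        b_values = c(0, sample(c(500, 800, 1000), 1))),
  t1gre = function() list(technique = "GRE", tr_ms = stats::runif(1, 200, 700),
                          te_ms = stats::runif(1, 2, 10),
                          flip_deg = stats::runif(1, 55, 80)),
  ssfp = function() list(technique = "bSSFP", tr_ms = stats::runif(1, 3, 6),
                         te_ms = stats::runif(1, 1, 3),
                         flip_deg = stats::runif(1, 40, 70))
)

make_parameter_tuple <- function(id) {
  arch_name <- sample(names(TUPLE_ARCHETYPES), 1)
  params <- TUPLE_ARCHETYPES[[arch_name]]()
  params$orientation <- sample(c("SAG", "COR", "TRA"), 1)
  params$fat_suppression <- stats::runif(1) < 0.25
  params$dimensionality <- sample(c("2D", "3D"), 1, prob = c(0.8, 0.2))
  params$contrast_phase <- sample(c("NONE", "POST"), 1, prob = c(0.85, 0.15))
  params$echo_train_length <- if (params$technique %in% c("TSE", "EPI"))
    sample(8:32, 1) else 1L
  base <- tolower(paste(arch_name, params$technique, params$orientation,
                        params$dimensionality, sprintf("%03d", id), sep = "_"))
  # disjoint synonym pool per tuple (the id keeps pools from colliding), first
  # spelling is the canonical one shared across scanners
  spellings <- c(base,
                 toupper(chartr("_", " ", base)),
                 sub("^([a-z0-9]+)_", "\\1w-", base),
                 paste0(base, "-v2"))
  list(id = id, params = params, spellings = spellings)
}

#' Generate synthetic multi-scanner protocol trees
#'
#' Builds a shared core of acquisition-parameter tuples reused by every
#' scanner, plus site-specific tuples at the configured rate. Each tuple owns
#' a disjoint pool of raw-name spellings (same parameters, different site
#' habits); every time a protocol uses a tuple, the spelling is the canonical
#' one with probability `1 - synonym_noise_rate` and a synonym otherwise.
#' Standardization therefore provably increases cross-scanner name overlap:
#' the standardized name depends only on the tuple's parameters, which the
#' scanners share, while raw spellings diverge. Protocol names overlap across
#' scanners at `protocol_name_overlap`. Deterministic under the config seed.
#'
#' @param config a [synthetic_config()].
#' @return list of [protocol_tree] objects, one per scanner.
#' @export
generate_trees <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  tc <- config$tree
  set.seed(stream_seed(config$seed, "trees/tuples"))
  core <- lapply(seq_len(tc$n_core_parameter_tuples), make_parameter_tuple)
  n_site_specific <- round(tc$site_specific_sequence_rate *
                             tc$n_core_parameter_tuples)
  sites <- unique(vapply(seq_len(config$n_scanners), site_of_scanner,
                         character(1), n_scanners = config$n_scanners,
                         n_sites = config$n_sites))
  next_id <- tc$n_core_parameter_tuples
  site_tuples <- list()
  for (st in sites) {
    site_tuples[[st]] <- lapply(seq_len(n_site_specific) + next_id,
                                make_parameter_tuple)
    next_id <- next_id + n_site_specific
  }

  set.seed(stream_seed(config$seed, "trees/protocol-names"))
  n_shared <- round(tc$protocol_name_overlap * tc$n_protocols_per_scanner)
  shared_names <- make_protocol_names("mixed", n_shared)
  region_tags <- names(config$regions) %||% "mixed"

  lapply(seq_len(config$n_scanners), function(s) {
    set.seed(stream_seed(config$seed, paste0("trees/scanner-", s)))
    site <- site_of_scanner(s, config$n_scanners, config$n_sites)
    pool <- c(core, site_tuples[[site]])
    n_prot <- tc$n_protocols_per_scanner
    own <- sprintf("SC%d-%02d/LOCAL", s, seq_len(n_prot - n_shared))
    prot_names <- c(shared_names, own)
    n_seq <- sample(seq(tc$sequences_per_protocol[1],
                        tc$sequences_per_protocol[2]),
                    n_prot, replace = TRUE)
    # assign tuples to sequence slots; every pool tuple is used at least once
    # so a zero-noise, zero-site-rate configuration yields identical raw-name
    # sets on all scanners
    total_slots <- sum(n_seq)
    if (total_slots < length(pool))
      abort("not enough sequence slots (%d) to cover %d parameter tuples",
            total_slots, length(pool))
    slot_tuples <- c(sample(seq_along(pool)),
                     sample(seq_along(pool), total_slots - length(pool),
                            replace = TRUE))
    cursor <- 0L
    protocols <- lapply(seq_len(n_prot), function(p) {
      idx <- slot_tuples[cursor + seq_len(n_seq[p])]
      cursor <<- cursor + n_seq[p]
      seqs <- lapply(idx, function(ti) {
        tup <- pool[[ti]]
        n_syn <- min(tc$synonyms_per_tuple, length(tup$spellings))
        spelling <- if (n_syn > 1 && stats::runif(1) < tc$synonym_noise_rate) {
          tup$spellings[sample(2:n_syn, 1)]
        } else {
          tup$spellings[1]
        }
        do.call(sequence_acquisition, c(list(raw_name = spelling), tup$params))
      })
      protocol_definition(prot_names[p], sample(region_tags, 1), seqs)
    })
    protocol_tree(paste0("scanner-", s), site, protocols)
  })
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper bundling [generate_exam_log()] and [generate_trees()].
#'
#' @param config a [synthetic_config()].
#' @return list with `exams` (an [exam_log]) and `trees` (list of
#'   [protocol_tree]).
#' @export
generate_dataset <- function(config) {
  list(exams = generate_exam_log(config), trees = generate_trees(config))
}
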