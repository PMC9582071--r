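test_that("weighting classification follows the default rule table", {
  rules <- toy_rules()
  # inversion recovery with a long TI wins over the T2-like TR/TE
  expect_equal(classify_weighting(
    seq_acq(tr = 9000, te = 120, ti = 2500, technique = "TSE"), rules), "FLAIR")
  expect_equal(classify_weighting(
    seq_acq(tr = 4000, te = 55, ti = 180, technique = "TSE"), rules), "STIR")
  expect_equal(classify_weighting(seq_acq(tr = 500, te = 10), rules), "T1")
  expect_equal(classify_weighting(
    seq_acq(tr = 4000, te = 70, technique = "EPI", b = c(0, 1000)), rules), "DWI")
  expect_equal(classify_weighting(
    seq_acq(tr = 4500, te = 100, technique = "TSE"), rules), "T2")
  expect_equal(classify_weighting(
    seq_acq(tr = 3000, te = 15, technique = "TSE"), rules), "PD")
  expect_equal(classify_weighting(
    seq_acq(tr = 400, te = 5, technique = "GRE", flip = 70), rules), "T1")
  # diffusion beats everything, even an IR-looking TI
  expect_equal(classify_weighting(
    seq_acq(tr = 9000, te = 120, ti = 2500, technique = "UNKNOWN",
            b = c(0, 800)), rules), "DWI")
  # nothing matches: terminal catch-all
  expect_equal(classify_weighting(
    seq_acq(tr = 1500, te = 50, technique = "bSSFP"), rules), "OTHER")
})

test_that("standardized names assemble tokens in the fixed order", {
  rules <- toy_rules()
  expect_equal(standardize_sequence(seq_acq(tr = 500, te = 10), rules),
               "T1 SE SAG 2D")
  expect_equal(standardize_sequence(
    seq_acq(tr = 9000, te = 120, ti = 2500, technique = "TSE",
            orientation = "TRA", fs = TRUE), rules),
    "FLAIR TSE TRA 2D FS")
  expect_equal(standardize_sequence(
    seq_acq(tr = 4000, te = 70, technique = "EPI", orientation = "TRA",
            b = c(0, 1000)), rules),
    "DWI EPI TRA 2D")
  # UNKNOWN orientation and technique are omitted; POST marker appended
  expect_equal(standardize_sequence(
    seq_acq(tr = 500, te = 10, orientation = "UNKNOWN", phase = "POST"), rules),
    "T1 SE 2D POST")
  # togglable tokens
  expect_equal(standardize_sequence(
    seq_acq(tr = 500, te = 10, phase = "POST"), rules,
    include_dimensionality = FALSE, include_contrast = FALSE),
    "T1 SE SAG")
})

test_that("standardization is a pure function of parameters, never the raw name", {
  rules <- toy_rules()
  a <- seq_acq(raw_name = "t1_se_sag", tr = 500, te = 10)
  b <- seq_acq(raw_name = "T1 SAGITTAL", tr = 500, te = 10)
  expect_identical(standardize_sequence(a, rules), standardize_sequence(b, rules))
  # determinism: same inputs, same output
  expect_identical(standardize_sequence(a, rules), standardize_sequence(a, rules))
})

test_that("raw-name permutation leaves all standardized outputs unchanged", {
  cfg <- synthetic_config(seed = 21, tree = list(
    n_protocols_per_scanner = 10, n_core_parameter_tuples = 15,
    sequences_per_protocol = c(3, 5)))
  tree <- generate_trees(cfg)[[1]]
  rules <- toy_rules()
  std1 <- standardize_tree(tree, rules)
  # permute raw names across all sequences
  permuted <- tree
  all_names <- unlist(lapply(permuted$protocols, function(pr)
    vapply(pr$sequences, `[[`, character(1), "raw_name")))
  set.seed(9); shuffled <- sample(all_names)
  k <- 0
  permuted$protocols <- lapply(permuted$protocols, function(pr) {
    pr$sequences <- lapply(pr$sequences, function(s) {
      k <<- k + 1; s$raw_name <- shuffled[k]; s
    })
    pr
  })
  std2 <- standardize_tree(permuted, rules)
  names1 <- unlist(lapply(std1$tree$protocols, function(pr)
    vapply(pr$sequences, `[[`, character(1), "std_name")))
  names2 <- unlist(lapply(std2$tree$protocols, function(pr)
    vapply(pr$sequences, `[[`, character(1), "std_name")))
  expect_identical(names1, names2)
})

test_that("tree standardization counts distinct names and collapses synonyms", {
  rules <- toy_rules()
  # all raw names are distinct spellings of one parameter tuple
  specs <- list(P1 = list(seq_acq("t1_se_sag"), seq_acq("T1 SAG")),
                P2 = list(seq_acq("t1w_se_sag")))
  tree <- make_tree("sc1", "A", specs)
  std <- standardize_tree(tree, rules)
  expect_equal(std$n_unique_raw, 3)
  expect_equal(std$n_unique_standardized, 1)

  empty <- suppressWarnings(protocol_tree("sc2", "A", list()))
  std0 <- standardize_tree(empty, rules)
  expect_equal(std0$n_unique_raw, 0)
  expect_equal(std0$n_unique_standardized, 0)
})

test_that("standardized counts never exceed raw counts on generator output", {
  for (seed in c(2, 31, 77)) {
    cfg <- synthetic_config(seed = seed, tree = list(
      n_protocols_per_scanner = 15, n_core_parameter_tuples = 20))
    for (tree in generate_trees(cfg)) {
      std <- standardize_tree(tree, toy_rules())
      expect_lte(std$n_unique_standardized, std$n_unique_raw)
    }
  }
})

test_that("rule order is explicit: swapping overlapping rules flips only shared matches", {
  overlap_rules <- as_rules <- function(lst) {
    # build via YAML to go through the public surface
    path <- withr::local_tempfile(fileext = ".yaml")
    yaml::write_yaml(list(rules = lst), path)
    read_standardization_rules(path)
  }
  r_long_tr <- list(name = "long-tr", when = list(tr_ms = list(gt = 2000)),
                    token = "LONG")
  r_long_te <- list(name = "long-te", when = list(te_ms = list(gt = 80)),
                    token = "LATE")
  catchall <- list(name = "rest", when = NULL, token = "OTHER")
  rules_ab <- overlap_rules(list(r_long_tr, r_long_te, catchall))
  rules_ba <- overlap_rules(list(r_long_te, r_long_tr, catchall))
  both <- seq_acq(tr = 4000, te = 100)    # matches both rules
  only_tr <- seq_acq(tr = 4000, te = 20)  # matches long-tr only
  only_te <- seq_acq(tr = 800, te = 100)  # matches long-te only
  expect_equal(classify_weighting(both, rules_ab), "LONG")
  expect_equal(classify_weighting(both, rules_ba), "LATE")
  expect_equal(classify_weighting(only_tr, rules_ab),
               classify_weighting(only_tr, rules_ba))
  expect_equal(classify_weighting(only_te, rules_ab),
               classify_weighting(only_te, rules_ba))
})

test_that("rule files are validated: catch-all required, intervals well-formed", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(rules = list(
    list(name = "a", when = list(tr_ms = list(gt = 2000)), token = "X"))), path)
  expect_error(read_standardization_rules(path), "catch-all")
  yaml::write_yaml(list(rules = list(
    list(name = "a", when = list(tr_ms = list(ge = 100, le = 50)), token = "X"),
    list(name = "z", when = NULL, token = "OTHER"))), path)
  expect_error(read_standardization_rules(path), "empty interval")
})
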