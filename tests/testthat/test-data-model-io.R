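test_that("code canonicalization normalizes case, whitespace and dot placement", {
  expect_equal(canonicalize_code(" m54.5 "), "M54.5")
  expect_equal(canonicalize_code("M545"), "M54.5")
  expect_equal(canonicalize_code("m5430"), "M54.30")
  expect_equal(canonicalize_code("G35"), "G35")
  expect_error(canonicalize_code("54X"), "malformed.*54X")
  expect_error(canonicalize_code("M5"), "malformed")
  expect_error(canonicalize_code("  "), "blank")
})

test_that("code canonicalization is idempotent", {
  raw <- c(" m54.5 ", "M545", "g35", "s7200", "C50.911")
  once <- canonicalize_code(raw)
  expect_identical(canonicalize_code(once), once)
})

test_that("code-set elements are sorted, deduplicated and order-insensitive", {
  expect_equal(code_set_element(c("M54.2", "m50.30", "M54.2")), "M50.30+M54.2")
  expect_equal(code_set_element(c("m50.30", "M54.2")),
               code_set_element(c("M54.2", "M50.30")))
  expect_error(code_set_element(character(0)), "at least one code")
})

test_that("exam-log CSV parsing canonicalizes, dedups and flags empty cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "exam_id,scanner_id,site_id,body_region,protocol_name,admitting_codes",
    "e1,sc1,A,spine,CERVICAL/WITHOUT,M54.2",
    "e2,sc1,A,spine,CERVICAL/WITHOUT,M54.2;M50.30",
    "e3,sc1,A,Spine,LUMBAR/WITHOUT,M54.2;m54.2",
    "e4,sc1,A,spine,LUMBAR/WITHOUT,"), path)
  expect_warning(log <- read_exam_log(path), "empty admitting-code")
  expect_equal(nrow(log), 4)
  expect_equal(log$admitting_codes[[1]], "M54.2")
  expect_equal(log$admitting_codes[[2]], c("M50.30", "M54.2"))
  expect_equal(log$admitting_codes[[3]], "M54.2")
  expect_equal(log$admitting_codes[[4]], character(0))
  expect_equal(log$body_region[3], "spine")  # lowercased tag
})

test_that("exam-log reading rejects missing columns and duplicate ids", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("exam_id,scanner_id,body_region,protocol_name,admitting_codes",
               "e1,sc1,spine,P,M54.2"), path)
  expect_error(read_exam_log(path), "site_id")
  writeLines(c("exam_id,scanner_id,site_id,body_region,protocol_name,admitting_codes",
               "e1,sc1,A,spine,P,M54.2",
               "e1,sc1,A,spine,Q,M54.3"), path)
  expect_error(read_exam_log(path), "duplicate exam_id.*e1")
})

test_that("exam logs round-trip through CSV field by field", {
  set.seed(42)
  cfg <- synthetic_config(seed = 3, regions = list(
    spine = list(n_protocols = 4, n_exams = 40, code_vocabulary_size = 20,
                 cardinality_distribution = c("1" = 0.7, "2" = 0.3),
                 protocol_frequency_range = c(6, 20))))
  log <- generate_exam_log(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_exam_log(log, path)
  back <- read_exam_log(path)
  for (col in c("exam_id", "scanner_id", "site_id", "body_region",
                "protocol_name", "admitting_codes", "exam_date")) {
    expect_equal(back[[col]], log[[col]], ignore_attr = TRUE)
  }
})

test_that("protocol-tree JSON parsing validates structure with JSON paths", {
  path <- withr::local_tempfile(fileext = ".json")
  doc <- list(scanners = list(list(
    scanner_id = "sc1", site_id = "A",
    protocols = list(
      list(protocol_name = "P1", body_region = "spine",
           sequences = list(
             list(raw_name = "t1_se", tr_ms = 500, te_ms = 10),
             list(raw_name = "t2_tse", tr_ms = 4000, te_ms = 100,
                  technique = "TSE"),
             list(raw_name = "dwi", tr_ms = 4000, te_ms = 70,
                  technique = "EPI", b_values = c(0, 1000)))),
      list(protocol_name = "P2", body_region = "spine",
           sequences = list(
             list(raw_name = "flair", tr_ms = 9000, te_ms = 110,
                  ti_ms = 2500, inversion_recovery = TRUE, technique = "TSE"),
             list(raw_name = "t1_se", tr_ms = 500, te_ms = 10),
             list(raw_name = "loc", tr_ms = 5, te_ms = 2, technique = "bSSFP")))))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  trees <- read_protocol_trees(path)
  expect_length(trees, 1)
  expect_length(trees[[1]]$protocols, 2)
  # optional fields defaulted conservatively
  s1 <- trees[[1]]$protocols[[1]]$sequences[[1]]
  expect_equal(s1$technique, "UNKNOWN")
  expect_equal(s1$orientation, "UNKNOWN")
  expect_equal(s1$contrast_phase, "NONE")

  # TI without inversion recovery is rejected, with the offending path
  doc$scanners[[1]]$protocols[[2]]$sequences[[1]]$inversion_recovery <- FALSE
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_protocol_trees(path),
               "scanners\\[1\\].protocols\\[2\\].sequences\\[1\\].*inversion_recovery")

  # duplicate protocol names within a scanner are rejected
  doc$scanners[[1]]$protocols[[2]]$sequences[[1]]$inversion_recovery <- TRUE
  doc$scanners[[1]]$protocols[[2]]$protocol_name <- "P1"
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_protocol_trees(path), "duplicate protocol name")
})

test_that("an empty protocol list is a valid tree, with a warning", {
  expect_warning(tr <- protocol_tree("sc1", "A", list()), "no protocols")
  expect_length(tr$protocols, 0)
})

test_that("protocol trees round-trip through JSON field by field", {
  cfg <- synthetic_config(seed = 5, tree = list(
    n_protocols_per_scanner = 8, n_core_parameter_tuples = 12,
    sequences_per_protocol = c(3, 5)))
  trees <- generate_trees(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_protocol_trees(trees, path)
  back <- read_protocol_trees(path)
  expect_equal(back, trees)
})

test_that("diffusion b-values with a non-EPI technique warn but do not reject", {
  expect_warning(
    seq_acq(b = c(0, 800), technique = "GRE"),
    "expected EPI")
  expect_silent(seq_acq(b = c(0, 800), technique = "EPI"))
  expect_silent(seq_acq(b = c(0, 800), technique = "UNKNOWN"))
})

test_that("matrix CSV export uses two decimals, label rows and a complement column", {
  assoc <- list(P1 = c("a", "b", "c"), P2 = c("b", "c", "x"))
  m <- pairwise_matrix(assoc, c("P1", "P2"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(m, path)
  got <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  expect_equal(names(got), c("protocol", "P1", "P2", "complement"))
  expect_equal(nrow(got), 2)
  expect_equal(got$P1, c("1.00", "0.67"))  # diagonal 1.00; 2/3 rounds to 0.67
  expect_equal(got$complement, c("0.67", "0.67"))

  # undefined complement renders as an empty cell
  m1 <- pairwise_matrix(list(P1 = c("a", "b")))
  write_matrix_csv(m1, path)
  got1 <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  expect_equal(got1$complement, "")
})
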