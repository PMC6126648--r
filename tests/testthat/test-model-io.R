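# Structure/sequence I/O and gap detection

test_that("PDB round trip preserves coordinates, cell and symmetry", {
  gt <- build_ground_truth(helix_fixture_spec(n = 10, gap_len = 0))
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(gt, p)
  m <- read_structure(p)
  expect_equal(coords(m), coords(gt), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(m$cell, gt$cell, tolerance = 1e-2)
  expect_equal(length(m$sym_ops), length(gt$sym_ops))
  # idempotence at format precision
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("mmCIF and PDB encodings of the same model read back equal", {
  gt <- build_ground_truth(helix_fixture_spec(n = 8, gap_len = 0))
  pp <- withr::local_tempfile(fileext = ".pdb")
  pc <- withr::local_tempfile(fileext = ".cif")
  write_structure(gt, pp)
  write_structure(gt, pc)
  m1 <- read_structure(pp)
  m2 <- read_structure(pc)
  for (col in c("record", "name", "resname", "chain", "resno"))
    expect_identical(m1$atoms[[col]], m2$atoms[[col]])
  expect_equal(coords(m1), coords(m2), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(m1$atoms$occ, m2$atoms$occ)
  expect_equal(m1$atoms$b, m2$atoms$b)
})

test_that("malformed records give parse errors naming the line", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  N   ALA A   1      11.104   6.134",
               "END"), p)
  expect_error(read_structure(p), "line 1")
})

test_that("case coding follows backbone completeness", {
  gt <- build_ground_truth(helix_fixture_spec(n = 12, gap_len = 0))
  construct <- stats::setNames(
    paste(aa_3to1[vapply(1:12, function(i)
      gt$atoms$resname[gt$atoms$resno == i][1], "")], collapse = ""), "A")
  # remove residues 6-8 entirely
  m <- gt
  m$atoms <- m$atoms[!(m$atoms$resno %in% 6:8), ]
  s <- sequence_strings(extract_case_coded_sequence(m, construct))
  ch <- strsplit(s[["A"]], "")[[1]]
  expect_true(all(ch[6:8] == tolower(ch[6:8])))
  expect_true(all(ch[c(1:5, 9:12)] == toupper(ch[c(1:5, 9:12)])))

  # dropping one O atom makes that position lowercase
  m2 <- gt
  drop <- which(m2$atoms$resno == 4 & m2$atoms$name == "O")
  m2$atoms <- m2$atoms[-drop, ]
  s2 <- strsplit(sequence_strings(
    extract_case_coded_sequence(m2, construct))[["A"]], "")[[1]]
  expect_identical(s2[4], tolower(s2[4]))
  expect_identical(s2[5], toupper(s2[5]))
})

test_that("unmappable chains raise an unmapped-chain error", {
  gt <- build_ground_truth(helix_fixture_spec(n = 8, gap_len = 0))
  expect_error(
    extract_case_coded_sequence(gt, stats::setNames("WWWWWWWW", "A")),
    "unmapped chain")
})

test_that("gap detection finds internal lowercase runs with 5-residue anchors", {
  spec <- helix_fixture_spec(n = 26, gap_start = 11, gap_len = 3)
  fx <- make_fixture(spec)
  gaps <- find_missing_loops(fx$target, fx$construct)
  expect_equal(nrow(gaps), 1)
  expect_equal(gaps$first, 11)
  expect_equal(gaps$last, 13)
  expect_gte(gaps$n_anchor_before, 5)
  expect_gte(gaps$n_anchor_after, 5)

  # gap-free chain: nothing reported
  expect_equal(nrow(find_missing_loops(fx$truth, fx$construct)), 0)

  # terminal runs are never loops
  m <- fx$truth
  m$atoms <- m$atoms[!(m$atoms$resno %in% 1:3), ]
  expect_equal(nrow(find_missing_loops(m, fx$construct)), 0)
})

test_that("gaps longer than the maximum loop length are not reported", {
  spec <- helix_fixture_spec(n = 45, gap_start = 8, gap_len = 31)
  fx <- make_fixture(spec)
  expect_equal(nrow(find_missing_loops(fx$target, fx$construct)), 0)
  expect_equal(nrow(find_missing_loops(fx$target, fx$construct,
                                       max_len = 31)), 1)
  # at the default boundary, a 30-residue gap is reported
  spec30 <- helix_fixture_spec(n = 44, gap_start = 8, gap_len = 30)
  fx30 <- make_fixture(spec30)
  expect_equal(nrow(find_missing_loops(fx30$target, fx30$construct)), 1)
})

test_that("zero-occupancy stretches are gaps flagged as extra candidates", {
  spec <- helix_fixture_spec(n = 24, gap_start = 11, gap_len = 2,
                             zero_occ = TRUE)
  fx <- make_fixture(spec)
  gaps <- find_missing_loops(fx$target, fx$construct)
  expect_equal(nrow(gaps), 1)
  expect_true(gaps$zero_occupancy_modeled)
})

test_that("anchors containing non-CA backbone alternates flag the gap skipped", {
  spec <- helix_fixture_spec(n = 26, gap_start = 12, gap_len = 2)
  fx <- make_fixture(spec)
  m <- fx$target
  # inject an alternate N in an anchor residue
  row <- m$atoms[m$atoms$resno == 10 & m$atoms$name == "N", ][1, ]
  m$atoms$alt[m$atoms$resno == 10 & m$atoms$name == "N"] <- "A"
  row$alt <- "B"; row$x <- row$x + 0.3
  m$atoms <- dplyr::bind_rows(m$atoms, row)
  gaps <- find_missing_loops(m, fx$construct)
  expect_true(gaps$skip[1])
  expect_equal(gaps$skip_reason[1], "ambiguous_alternates")

  # CA-only alternates are tolerated
  m2 <- fx$target
  row2 <- m2$atoms[m2$atoms$resno == 10 & m2$atoms$name == "CA", ][1, ]
  m2$atoms$alt[m2$atoms$resno == 10 & m2$atoms$name == "CA"] <- "A"
  row2$alt <- "B"; row2$x <- row2$x + 0.2
  m2$atoms <- dplyr::bind_rows(m2$atoms, row2)
  gaps2 <- find_missing_loops(m2, fx$construct)
  expect_false(gaps2$skip[1])
})

test_that("partially modeled edge residues are folded into the gap and flagged", {
  spec <- helix_fixture_spec(n = 26, gap_start = 12, gap_len = 2)
  fx <- make_fixture(spec)
  m <- fx$target
  # strip the O atom of the residue just before the gap: it becomes part
  # of the lowercase run
  m$atoms <- m$atoms[!(m$atoms$resno == 11 & m$atoms$name == "O"), ]
  gaps <- find_missing_loops(m, fx$construct)
  expect_equal(gaps$first, 11)
  expect_true(gaps$partial_edge_before)
  expect_false(gaps$partial_edge_after)
})

test_that("SEQRES records can serve as construct fallback", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "SEQRES   1 A    4  ALA GLY SER VAL",
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    "END"), p)
  sr <- read_seqres(p)
  expect_identical(sr[["A"]], "AGSV")
})
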