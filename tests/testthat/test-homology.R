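# Sequence alignment, source eligibility, anchor preparation, and the
# quaternion superposition against an independent Kabsch oracle

test_that("sequence alignment and window identity behave as documented", {
  p <- align_homolog_sequence("ARNDCQEGHI", "ARNDCQEGHI")
  expect_equal(window_identity(p, 1:10), 100)
  expect_equal(p$tpos, p$hpos)

  p2 <- align_homolog_sequence("ARNDCQEGHI", "ARNDCAEGHI")
  expect_equal(window_identity(p2, 1:10), 90)
  expect_equal(window_identity(p2, 6), 0)
})

test_that("superposition handles exact and noisy cases like Kabsch", {
  set.seed(101)
  pts <- matrix(rnorm(30, sd = 4), ncol = 3)
  tr <- superpose_quaternion(pts, pts)
  expect_equal(tr$rmsd, 0, tolerance = 1e-9)
  expect_equal(tr$R, diag(3), tolerance = 1e-9)

  shifted <- sweep(pts, 2, c(5, 0, 0), "+")
  tr2 <- superpose_quaternion(pts, shifted)
  expect_equal(tr2$t, c(-5, 0, 0), tolerance = 1e-9)
  expect_equal(tr2$rmsd, 0, tolerance = 1e-9)

  # rotation + noise: agreement with the SVD oracle
  th <- 30 * pi / 180
  rotz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                 3, byrow = TRUE)
  moving <- pts %*% t(rotz) + matrix(rnorm(30, sd = 0.1), ncol = 3)
  tr3 <- superpose_quaternion(pts, moving)
  expect_equal(tr3$rmsd, kabsch_rmsd(pts, moving), tolerance = 1e-9)
  expect_equal(det(tr3$R), 1, tolerance = 1e-9)
  expect_equal(sum(tr3$q^2), 1, tolerance = 1e-12)
})

test_that("superposition properties: symmetry, rigid invariance, oracle sweep", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(4:25, 1)
    fixed <- matrix(rnorm(n * 3, sd = 5), ncol = 3)
    moving <- sweep(fixed %*% t(loopgraft:::random_rotation()), 2,
                    rnorm(3, sd = 3), "+") +
      matrix(rnorm(n * 3, sd = 0.2), ncol = 3)
    r1 <- superpose_quaternion(fixed, moving)$rmsd
    expect_equal(r1, kabsch_rmsd(fixed, moving), tolerance = 1e-9)
    expect_equal(r1, superpose_quaternion(moving, fixed)$rmsd,
                 tolerance = 1e-9)
    # global rigid motion of both sets leaves the rmsd unchanged
    rot <- loopgraft:::random_rotation(); tt <- rnorm(3, sd = 4)
    r2 <- superpose_quaternion(sweep(fixed %*% t(rot), 2, tt, "+"),
                               sweep(moving %*% t(rot), 2, tt, "+"))$rmsd
    expect_equal(r1, r2, tolerance = 1e-8)
  }
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose_quaternion(line, line), "degenerate")
  expect_error(superpose_quaternion(matrix(0, 2, 3), matrix(0, 2, 3)),
               "at least 3")
})

test_that("eligible sources respect completeness and identity rules", {
  spec <- helix_fixture_spec(n = 28, gap_start = 13, gap_len = 3,
                             n_homologs = 1, noise = 0.1, seed = 31)
  fx <- make_fixture(spec)
  gaps <- find_missing_loops(fx$target, fx$construct)
  gap <- gaps[1, ]
  src <- collect_sources(gap, fx$construct, fx$homologs)
  expect_length(src, 1)

  # homolog missing one loop residue is excluded
  h2 <- fx$homologs[[1]]
  h2$atoms <- h2$atoms[h2$atoms$resno != 14, ]
  expect_length(collect_sources(gap, fx$construct, list(h2)), 0)

  # loop identity below 50% excludes the homolog...
  h3 <- fx$homologs[[1]]
  for (rn in 13:14) {
    cur <- h3$atoms$resname[h3$atoms$resno == rn][1]
    new3 <- setdiff(c("ALA", "SER"), cur)[1]
    h3$atoms <- loopgraft:::mutate_residue(h3$atoms, rn, new3)
  }
  expect_length(collect_sources(gap, fx$construct, list(h3)), 0)

  # ...but a single-residue loop may be mutated
  spec1 <- helix_fixture_spec(n = 26, gap_start = 13, gap_len = 1,
                              n_homologs = 1, noise = 0.1, seed = 32)
  fx1 <- make_fixture(spec1)
  gap1 <- find_missing_loops(fx1$target, fx1$construct)[1, ]
  h4 <- fx1$homologs[[1]]
  cur <- h4$atoms$resname[h4$atoms$resno == 13][1]
  h4$atoms <- loopgraft:::mutate_residue(h4$atoms, 13,
                                         setdiff(c("ALA", "SER"), cur)[1])
  expect_length(collect_sources(gap1, fx1$construct, list(h4)), 1)
})

test_that("homolog loop alternates expand into separate candidates", {
  spec <- helix_fixture_spec(n = 26, gap_start = 13, gap_len = 2,
                             n_homologs = 1, noise = 0.05, seed = 33)
  fx <- make_fixture(spec)
  gap <- find_missing_loops(fx$target, fx$construct)[1, ]
  h <- fx$homologs[[1]]
  # duplicate the loop backbone as alternate B
  la <- h$atoms[h$atoms$resno %in% 13:14, ]
  h$atoms$alt[h$atoms$resno %in% 13:14] <- "A"
  la$alt <- "B"
  la$x <- la$x + 0.4
  h$atoms <- dplyr::bind_rows(h$atoms, la)
  src <- collect_sources(gap, fx$construct, list(h))
  expect_length(src, 2)
  expect_setequal(vapply(src, function(s) s$alt, ""), c("A", "B"))
})

test_that("DEFY flips restore equivalent-atom pairing and mutations crop side chains", {
  # ground truth with an ASP at an anchor position
  seq <- "AAAAAAAADAAAAAAAAAAAAAAAA"  # ASP at position 9 (anchor of gap 13-14)
  spec <- fixture_spec(sequence = seq, plan = strrep("H", nchar(seq)),
                       gap_start = 13, gap_len = 2, n_homologs = 1,
                       noise = 0.05, seed = 41)
  fx <- make_fixture(spec)
  gap <- find_missing_loops(fx$target, fx$construct)[1, ]
  src <- collect_sources(gap, fx$construct, fx$homologs)[[1]]
  h <- fx$homologs[[1]]
  # swap the OD1/OD2 labels in the homolog
  i1 <- which(h$atoms$resno == 9 & h$atoms$name == "OD1")
  i2 <- which(h$atoms$resno == 9 & h$atoms$name == "OD2")
  h$atoms$name[i1] <- "OD2"; h$atoms$name[i2] <- "OD1"
  pa <- prepare_anchor_atoms(fx$target, gap, src, h)
  tr <- superpose_quaternion(pa$fixed, pa$moving,
                             rmsd_subset = pa$is_backbone)
  # after the flip correction the full-atom fit is as tight as without
  # the label swap
  pa0 <- prepare_anchor_atoms(fx$target, gap, src, fx$homologs[[1]])
  tr0 <- superpose_quaternion(pa0$fixed, pa0$moving,
                              rmsd_subset = pa0$is_backbone)
  moved <- apply_transform(tr, pa$moving)
  moved0 <- apply_transform(tr0, pa0$moving)
  expect_equal(mean(rowSums((moved - pa$fixed)^2)),
               mean(rowSums((moved0 - pa0$fixed)^2)), tolerance = 1e-3)

  # a mutated anchor contributes backbone only
  h2 <- fx$homologs[[1]]
  h2$atoms <- loopgraft:::mutate_residue(h2$atoms, 9, "SER")
  src2 <- collect_sources(gap, fx$construct, list(h2))[[1]]
  pa2 <- prepare_anchor_atoms(fx$target, gap, src2, h2)
  expect_lt(nrow(pa2$fixed), nrow(pa0$fixed))
})
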