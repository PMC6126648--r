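# Geometry RMSZ scores, filters, Ramachandran Z and the Grubbs veto

test_that("ideal fragments score near zero; +1 sigma bonds give rmsz_bond 1", {
  gt <- build_ground_truth(helix_fixture_spec(n = 10, gap_len = 0))
  gs <- geometry_scores(gt$atoms)
  expect_lt(gs$rmsz_bond, 0.1)
  expect_lt(gs$rmsz_angle, 0.1)
  expect_lt(gs$rmsz_chir, 0.1)
  expect_lt(gs$rmsz_plane, 0.1)
  expect_lt(gs$rmsz_torsion, 0.1)

  infl <- build_sigma_inflated_fragment(n = 6)
  gi <- geometry_scores(infl)
  expect_equal(gi$rmsz_bond, 1.0, tolerance = 0.05)
  expect_lt(gi$rmsz_angle, 0.1)
})

test_that("rmsz is invariant under rigid motion", {
  gt <- build_ground_truth(helix_fixture_spec(n = 8, gap_len = 0, seed = 3))
  a <- gt$atoms
  rot <- loopgraft:::random_rotation()
  b <- loopgraft:::set_coords(a, sweep(coords(a) %*% t(rot), 2,
                                       c(5, -3, 11), "+"))
  g1 <- geometry_scores(a); g2 <- geometry_scores(b)
  for (f in c("rmsz_bond", "rmsz_angle", "rmsz_chir", "rmsz_plane",
              "rmsz_torsion"))
    expect_equal(g1[[f]], g2[[f]], tolerance = 1e-8)
})

test_that("missing backbone atoms are reported by name", {
  gt <- build_ground_truth(helix_fixture_spec(n = 6, gap_len = 0))
  a <- gt$atoms[!(gt$atoms$resno == 3 & gt$atoms$name == "O"), ]
  expect_error(geometry_scores(a), "O")
})

test_that("the geometry filter rejects at the documented gates", {
  ok <- geometry_scores(build_ground_truth(
    helix_fixture_spec(n = 6, gap_len = 0))$atoms)
  expect_true(geometry_filter(ok)$accept)
  expect_false(geometry_filter(ok, converged = FALSE)$accept)

  tweak <- function(field, value) { s <- ok; s[[field]] <- value; s }
  expect_true(geometry_filter(tweak("rmsz_bond", 1.19))$accept)
  expect_false(geometry_filter(tweak("rmsz_bond", 1.21))$accept)
  expect_true(geometry_filter(tweak("rmsz_angle", 1.19))$accept)
  expect_false(geometry_filter(tweak("rmsz_angle", 1.21))$accept)
  expect_true(geometry_filter(tweak("rmsz_chir", 1.49))$accept)
  expect_false(geometry_filter(tweak("rmsz_chir", 1.51))$accept)
  expect_true(geometry_filter(tweak("rmsz_plane", 1.99))$accept)
  expect_false(geometry_filter(tweak("rmsz_plane", 2.01))$accept)
  expect_true(geometry_filter(tweak("rmsz_torsion", 1.99))$accept)
  expect_false(geometry_filter(tweak("rmsz_torsion", 2.01))$accept)

  # a broken peptide bond rejects
  expect_false(geometry_filter(tweak("peptide_gaps", TRUE))$accept)
})

test_that("omega distortions: single allowed, sequential rejected", {
  ok <- geometry_scores(build_ground_truth(
    helix_fixture_spec(n = 6, gap_len = 0))$atoms)
  single <- ok; single$omega_devs <- c(5, 30 + 1e-6, 2, 3, 4)
  expect_true(geometry_filter(single)$accept)
  seq2 <- ok; seq2$omega_devs <- c(40, 41, 2, 3, 4)
  expect_false(geometry_filter(seq2)$accept)
  nonadj <- ok; nonadj$omega_devs <- c(40, 2, 41, 3, 4)
  expect_true(geometry_filter(nonadj)$accept)
})

test_that("cis peptides are only allowed when the source loop has them", {
  ok <- geometry_scores(build_ground_truth(
    helix_fixture_spec(n = 6, gap_len = 0))$atoms)
  cis <- ok; cis$cis_flags <- c(TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_false(geometry_filter(
    cis, source_cis = rep(FALSE, 5))$accept)
  expect_true(geometry_filter(
    cis, source_cis = c(TRUE, FALSE, FALSE, FALSE, FALSE))$accept)
  expect_true(geometry_filter(cis, source_cis = NULL)$accept)
})

test_that("helical fragments score well, uniform dihedrals poorly", {
  gt <- build_ground_truth(helix_fixture_spec(n = 20, gap_len = 0, seed = 5))
  rz <- rama_z(gt)
  expect_gt(rz$z, -5)
  set.seed(71)
  u <- cbind(runif(50, -180, 180), runif(50, -180, 180))
  expect_lt(mean(loopgraft:::rama_score_angles(u)), -5)
})

test_that("reference-sampled fragments score near zero on average", {
  set.seed(72)
  zs <- replicate(200, mean(loopgraft:::rama_score_angles(
    rama_sample("general", 20))))
  expect_lt(abs(mean(zs)), 0.2)
})

test_that("rama_z is renumbering-invariant and rewards modal residues", {
  gt <- build_ground_truth(helix_fixture_spec(n = 12, gap_len = 0, seed = 6))
  a <- gt$atoms
  b <- a; b$resno <- b$resno + 100L
  expect_equal(rama_z(a)$z, rama_z(b)$z, tolerance = 1e-12)
  # adding a residue at the modal phi/psi never decreases the mean
  # log-density
  ref <- rama_reference("general")
  modal <- max(ref$logp)
  per <- rama_z(a)$per_residue
  expect_gte(mean(c(per$logp, modal)), mean(per$logp))
})

test_that("no scoreable residue raises an error", {
  one <- atom_row("CA", 0, 0, 0)
  expect_error(rama_z(dplyr::bind_rows(
    atom_row("N", -1.4, 0, 0), one, atom_row("C", 0.5, 1.4, 0),
    atom_row("O", 1.7, 1.4, 0))), "no scoreable")
})

test_that("the Grubbs veto fires only below -5 and at 2 sigma", {
  # spec-level arithmetic cases
  expect_true(rama_outlier_filter(-6, c(-5.5, -6.2, -5.8))$accept)
  expect_false(rama_outlier_filter(-9, c(-2.1, -2.4, -1.9, -2.2))$accept)
  expect_true(rama_outlier_filter(-4, c(-2.1, -2.4, -1.9))$accept)
  # small populations give insufficient evidence
  expect_true(rama_outlier_filter(-9, c(-2.1, -2.4))$accept)
  # boundary: candidate just inside / outside 2 sigma of the peers
  peers <- c(-2, -2.5, -1.5, -2)
  m <- mean(peers); s <- sd(peers)
  just_in <- m - 1.99 * s
  just_out <- m - 2.01 * s
  expect_true(rama_outlier_filter(just_in, peers, poor_z = 0)$accept)
  expect_false(rama_outlier_filter(just_out, peers, poor_z = 0)$accept)
  # source-loop comparison fires independently
  expect_false(rama_outlier_filter(-9, numeric(0),
                                   source_zs = c(-2, -2.2, -1.8))$accept)
})
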