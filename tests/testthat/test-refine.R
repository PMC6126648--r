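# Junction closing and the restrained real-space minimizer

test_that("junction N atoms are moved into open gaps, bonded ones left alone", {
  gt <- build_ground_truth(helix_fixture_spec(n = 8, gap_len = 0, seed = 9))
  a <- gt$atoms
  # already bonded: nothing moves
  out <- close_gap_pregame(a)
  expect_equal(coords(out), coords(a[order(a$resno), ]), ignore_attr = TRUE)

  # open both junctions by dragging two N atoms away
  a2 <- a
  for (rn in c(4, 7)) {
    i <- which(a2$resno == rn & a2$name == "N")
    a2$x[i] <- a2$x[i] + 1.8
  }
  cpos <- function(at, rn, nm)
    as.numeric(at[at$resno == rn & at$name == nm, c("x", "y", "z")][1, ])
  for (rn in c(4, 7))
    expect_gt(loopgraft:::vnorm(cpos(a2, rn, "N") - cpos(a2, rn - 1, "C")),
              1.6)
  out2 <- close_gap_pregame(a2)
  for (rn in c(4, 7)) {
    d <- loopgraft:::vnorm(cpos(out2, rn, "N") - cpos(out2, rn - 1, "C"))
    expect_lte(d, 1.6)
  }
  # only the junction N atoms moved
  moved <- which(rowSums(abs(coords(out2) -
                               coords(a2[order(a2$resno), ]))) > 1e-12)
  expect_equal(sort(out2$name[moved]), c("N", "N"))
})

test_that("a junction opened to 2.4 A regularizes to a proper peptide bond", {
  gt <- build_ground_truth(helix_fixture_spec(n = 8, gap_len = 0, seed = 10))
  map <- synthesize_map(gt, b_blur = 15, spacing = 0.7)
  a <- gt$atoms
  i <- which(a$resno == 5 & a$name == "N")
  cpos <- as.numeric(a[a$resno == 4 & a$name == "C", c("x", "y", "z")])
  npos <- as.numeric(a[i, c("x", "y", "z")])
  dirv <- (npos - cpos) / loopgraft:::vnorm(npos - cpos)
  newn <- cpos + 2.4 * dirv
  a$x[i] <- newn[1]; a$y[i] <- newn[2]; a$z[i] <- newn[3]
  a2 <- close_gap_pregame(a)
  d_pre <- loopgraft:::vnorm(
    as.numeric(a2[a2$resno == 5 & a2$name == "N", c("x", "y", "z")]) - cpos)
  expect_lte(d_pre, 1.6)
  rr <- rsr_minimize(a2, map)
  d_post <- rr$scores$peptide_dists[4]
  expect_equal(d_post, 1.33, tolerance = 0.1)
})

test_that("an ideal loop in its own density barely moves", {
  # self-consistency needs density that resolves individual atoms: at
  # atomic sharpness (low B, fine grid) the minimum of the combined
  # target coincides with the true coordinates; at working B factors the
  # overlapping atom Gaussians shift the per-atom density optimum by
  # ~0.1 A, which the geometry terms only partly resist
  gt <- build_ground_truth(helix_fixture_spec(n = 10, gap_len = 0,
                                              seed = 11, b_factor = 10))
  map <- synthesize_map(gt, b_blur = 2, spacing = 0.3)
  region <- gt$atoms[gt$atoms$resno %in% 3:8, ]
  static <- gt$atoms[gt$atoms$resno %in% c(2, 9) &
                       gt$atoms$name %in% c("N", "CA", "C", "O"), ]
  rr <- rsr_minimize(region, map, static_atoms = static)
  shifts <- sqrt(rowSums((coords(rr$atoms) -
                            coords(region[order(region$resno,
                                                match(region$name,
                                                      c("N", "CA", "C", "O", "CB"))), ]))^2))
  expect_lt(max(shifts), 0.05)
  expect_true(rr$converged)
})

test_that("a rigidly displaced loop is pulled back into its density", {
  gt <- build_ground_truth(helix_fixture_spec(n = 10, gap_len = 0, seed = 12))
  map <- synthesize_map(gt, b_blur = 15, spacing = 0.7)
  region <- gt$atoms[gt$atoms$resno %in% 3:8, ]
  displaced <- loopgraft:::set_coords(
    region, sweep(coords(region), 2, c(0.8, 0, 0) / sqrt(1), "+"))
  rr <- rsr_minimize(displaced, map)
  ref <- region[order(region$resno, match(region$name,
                                          c("N", "CA", "C", "O", "CB"))), ]
  bb <- rr$atoms$name %in% c("N", "CA", "C", "O")
  ref_bb <- ref$name %in% c("N", "CA", "C", "O")
  rmsd <- sqrt(mean(rowSums((coords(rr$atoms[bb, ]) -
                               coords(ref[ref_bb, ]))^2)))
  expect_lt(rmsd, 0.3)
})

test_that("with a flat map, minimization only reduces the geometry penalty", {
  gt <- build_ground_truth(helix_fixture_spec(n = 8, gap_len = 0, seed = 13))
  region <- gt$atoms[gt$atoms$resno %in% 2:7, ]
  set.seed(14)
  pert <- loopgraft:::set_coords(
    region, coords(region) + matrix(rnorm(nrow(region) * 3, sd = 0.1),
                                    ncol = 3))
  g0 <- geometry_scores(pert)
  rr <- rsr_minimize(pert, map = NULL, w_map = 0)
  g1 <- rr$scores
  expect_lt(g1$rmsz_bond, g0$rmsz_bond)
  expect_lt(g1$rmsz_angle, g0$rmsz_angle)
  # output scores equal an independent recomputation on the refined
  # coordinates (single source of truth)
  g2 <- geometry_scores(rr$atoms)
  expect_equal(g1$rmsz_bond, g2$rmsz_bond, tolerance = 1e-12)
})

test_that("the energy gradient matches finite differences", {
  gt <- build_ground_truth(helix_fixture_spec(n = 8, gap_len = 0, seed = 15))
  frag <- gt$atoms[gt$atoms$resno %in% 3:6, ]
  map <- synthesize_map(gt, b_blur = 15, spacing = 0.7)
  rs <- loopgraft:::build_restraints(frag, NULL, w_rama = 0.05)
  set.seed(16)
  par0 <- as.numeric(t(coords(frag))) + rnorm(nrow(frag) * 3, sd = 0.05)
  eg <- loopgraft:::region_energy(par0, rs, map, occ = frag$occ)
  idx <- sample(length(par0), 12)
  num <- vapply(idx, function(i) {
    e <- rep(0, length(par0)); e[i] <- 1e-6
    (loopgraft:::region_energy(par0 + e, rs, map, occ = frag$occ,
                               want_grad = FALSE) -
       loopgraft:::region_energy(par0 - e, rs, map, occ = frag$occ,
                                 want_grad = FALSE)) / 2e-6
  }, 1)
  ana <- as.numeric(t(eg$G))[idx]
  expect_lt(max(abs(ana - num) / (abs(num) + 1)), 1e-5)
})

test_that("non-finite positions trigger a numerical error", {
  gt <- build_ground_truth(helix_fixture_spec(n = 6, gap_len = 0, seed = 17))
  frag <- gt$atoms[gt$atoms$resno %in% 2:5, ]
  map <- synthesize_map(gt, b_blur = 15, spacing = 0.7)
  rs <- loopgraft:::build_restraints(frag, NULL)
  par0 <- as.numeric(t(coords(frag)))
  par0[5] <- NaN
  expect_error(loopgraft:::region_energy(par0, rs, map, occ = frag$occ),
               "non-finite")
})
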