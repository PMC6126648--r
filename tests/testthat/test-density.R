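# Map interpolation, synthesis, density ratio, RSCC/RSR, CCP4 round trip

poly_map <- function(d = c(10, 12, 14)) {
  m <- map_grid(array(0, d), c(d, 90, 90, 90))
  g <- expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1), z = 0:(d[3] - 1))
  f <- function(x, y, z) 0.5 * x^3 - x^2 + 2 * y + 0.1 * y^3 + 3 * z +
    0.02 * z^3 + 1
  m$values <- array(f(g$x, g$y, g$z), dim = d)
  list(map = m, f = f)
}

test_that("interpolation is exact at nodes and for cubic fields", {
  pm <- poly_map()
  # node exactness
  nodes <- rbind(c(3, 4, 5), c(0, 0, 0), c(7, 9, 11))
  expect_equal(interpolate_cubic(pm$map, nodes),
               pm$f(nodes[, 1], nodes[, 2], nodes[, 3]), tolerance = 1e-12)
  # degree-3 polynomial exactness away from the wrap
  set.seed(7)
  pts <- cbind(runif(100, 2, 7), runif(100, 2, 9), runif(100, 2, 11))
  expect_lt(max(abs(interpolate_cubic(pm$map, pts) -
                      pm$f(pts[, 1], pts[, 2], pts[, 3]))), 1e-9)
  # constant map
  cm <- map_grid(array(4.2, c(5, 5, 5)), c(5, 5, 5, 90, 90, 90))
  expect_equal(interpolate_cubic(cm, pts %% 4), rep(4.2, 100),
               tolerance = 1e-12)
  expect_error(interpolate_cubic(cm, c(NaN, 1, 1)), "non-finite")
})

test_that("interpolation is continuous across cell boundaries", {
  set.seed(8)
  m <- map_grid(array(rnorm(6 * 6 * 6), c(6, 6, 6)), c(6, 6, 6, 90, 90, 90))
  for (x0 in 1:4) {
    lo <- interpolate_cubic(m, c(x0 - 1e-9, 2.5, 2.5))
    hi <- interpolate_cubic(m, c(x0 + 1e-9, 2.5, 2.5))
    expect_equal(lo, hi, tolerance = 1e-6)
  }
})

test_that("synthetic maps behave like Gaussian atoms", {
  one <- structure_model(atom_row("CA", 10, 10, 10), cell = c(20, 20, 20, 90, 90, 90))
  m <- synthesize_map(one, b_blur = 15, spacing = 0.5)
  peak <- interpolate_cubic(m, c(10, 10, 10))
  for (r in c(0.5, 1, 1.5, 2)) {
    v <- interpolate_cubic(m, c(10 + r, 10, 10))
    expect_lt(v, peak)
    if (r > 0.5)
      expect_lt(v, interpolate_cubic(m, c(10 + r - 0.5, 10, 10)))
  }
  # peak heights proportional to electron counts (C=6 vs O=8)
  two <- structure_model(dplyr::bind_rows(
    atom_row("CA", 6, 10, 10), atom_row("O", 16, 10, 10)),
    cell = c(24, 20, 20, 90, 90, 90))
  m2 <- synthesize_map(two, b_blur = 15, spacing = 0.5)
  pc <- interpolate_cubic(m2, c(6, 10, 10))
  po <- interpolate_cubic(m2, c(16, 10, 10))
  expect_equal(po / pc, 8 / 6, tolerance = 0.01)
  # occupancy linearity
  half <- two
  half$atoms$occ <- 0.5
  m3 <- synthesize_map(half, b_blur = 15, spacing = 0.5)
  expect_equal(max(m3$values) * 2, max(m2$values), tolerance = 1e-9)
})

test_that("density ratio compares loop against the always-ordered control", {
  spec <- helix_fixture_spec(n = 30, gap_start = 14, gap_len = 3,
                             n_homologs = 1, noise = 0.05, seed = 61)
  fx <- make_fixture(spec)
  # loop atoms at truth positions: ratio ~ 1
  loop_atoms <- fx$truth$atoms[fx$truth$atoms$resno %in% 13:17, ]
  rep <- density_ratio(loop_atoms, fx$target, NULL, fx$map)
  expect_gt(rep$ratio, 0.9)
  expect_true(rep$acceptable)
  # loop placed in empty space: ratio ~ 0, reject
  far <- loopgraft:::set_coords(loop_atoms, coords(loop_atoms) * 0 + 1.0)
  rep0 <- density_ratio(far, fx$target, NULL, fx$map)
  expect_lt(abs(rep0$ratio), 0.05)
  expect_false(rep0$acceptable)
  # ratio is invariant to uniform map scaling
  m2 <- fx$map; m2$values <- m2$values * 7.5
  expect_equal(density_ratio(loop_atoms, fx$target, NULL, m2)$ratio,
               rep$ratio, tolerance = 1e-9)
})

test_that("half-height loop density gives ratio near 0.5", {
  spec <- helix_fixture_spec(n = 30, gap_start = 14, gap_len = 3,
                             n_homologs = 1, seed = 62)
  fx <- make_fixture(spec)
  # synthesize a map in which the loop atoms contribute at half occupancy
  half <- fx$truth
  half$atoms$occ[half$atoms$resno %in% 13:17] <- 0.5
  m <- synthesize_map(half, b_blur = 15, spacing = 0.7)
  loop_atoms <- fx$truth$atoms[fx$truth$atoms$resno %in% 13:17, ]
  rep <- density_ratio(loop_atoms, fx$target, NULL, m)
  expect_equal(rep$ratio, 0.5, tolerance = 0.05)
})

test_that("control set falls back below 30 atoms", {
  spec <- helix_fixture_spec(n = 30, gap_start = 14, gap_len = 3,
                             n_homologs = 1, seed = 63)
  fx <- make_fixture(spec)
  loop_atoms <- fx$truth$atoms[fx$truth$atoms$resno %in% 13:17, ]
  # 8 control positions -> 32 atoms: no fallback
  ctl8 <- tibble::tibble(chain = "A", pos = 1:8, resno = 1:8)
  r1 <- density_ratio(loop_atoms, fx$target, ctl8, fx$map)
  expect_false(r1$used_fallback)
  expect_equal(r1$control_set_size, 32)
  # 7 positions -> 28 atoms: fallback to all non-loop main chain
  ctl7 <- ctl8[1:7, ]
  r2 <- density_ratio(loop_atoms, fx$target, ctl7, fx$map)
  expect_true(r2$used_fallback)
  expect_gt(r2$control_set_size, 28)
})

test_that("RSCC matches a brute-force Pearson oracle and RSR its formula", {
  spec <- helix_fixture_spec(n = 16, gap_len = 0, seed = 64)
  fx <- make_fixture(spec)
  obs <- fx$map
  calc <- synthesize_map(fx$truth, b_blur = 15,
                         cell = obs$cell, dim = obs$dim)
  atoms <- fx$truth$atoms[fx$truth$atoms$resno %in% 5:8, ]
  r <- rscc(atoms, obs, calc, radius = 2.0)
  expect_equal(r$rscc, 1, tolerance = 1e-9)
  expect_equal(r$rsr, 0, tolerance = 1e-9)

  # seeded noise: compare against an independent masked-Pearson oracle
  set.seed(99)
  noisy <- obs
  noisy$values <- obs$values + array(rnorm(length(obs$values),
                                           sd = sd(obs$values) / 5),
                                     dim = obs$dim)
  r2 <- rscc(atoms, noisy, calc, radius = 2.0)
  # oracle: explicit distance test on every grid node
  d <- obs$dim
  g <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  node_xyz <- sweep(g, 2, d, "/") %*% t(loopgraft:::orthogonalization_matrix(obs$cell))
  xyz <- coords(atoms)
  inmask <- rep(FALSE, nrow(node_xyz))
  for (i in seq_len(nrow(xyz))) {
    d2 <- (node_xyz[, 1] - xyz[i, 1])^2 + (node_xyz[, 2] - xyz[i, 2])^2 +
      (node_xyz[, 3] - xyz[i, 3])^2
    inmask <- inmask | d2 <= 4
  }
  o <- as.numeric(noisy$values)[inmask]
  c_ <- as.numeric(calc$values)[inmask]
  expect_equal(r2$rscc, cor(o, c_), tolerance = 1e-12)
  expect_equal(r2$rsr, sum(abs(o - c_)) / sum(abs(o + c_)),
               tolerance = 1e-12)

  # anti-correlated maps
  neg <- calc; neg$values <- -calc$values
  expect_equal(rscc(atoms, neg, calc, radius = 2.0)$rscc, -1,
               tolerance = 1e-9)
  # affine rescaling leaves RSCC unchanged
  aff <- noisy; aff$values <- 3 * noisy$values + 2
  expect_equal(rscc(atoms, aff, calc, radius = 2.0)$rscc, r2$rscc,
               tolerance = 1e-9)
})

test_that("CCP4 maps round-trip through write and read", {
  set.seed(11)
  m <- map_grid(array(rnorm(8 * 10 * 12), c(8, 10, 12)),
                c(12.5, 15, 18, 90, 90, 90))
  p <- withr::local_tempfile(fileext = ".ccp4")
  write_ccp4(m, p)
  m2 <- read_ccp4(p)
  expect_equal(m2$dim, m$dim)
  expect_equal(m2$cell, m$cell, tolerance = 1e-6)
  expect_equal(m2$values, m$values, tolerance = 1e-6)
})
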