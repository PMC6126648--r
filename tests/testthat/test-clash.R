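# Clash detection (severity, classification, symmetry images) and the
# adjudication hierarchy

# a lone loop atom plus a configurable partner in a model
clash_pair_model <- function(partner, cell = c(40, 40, 40, 90, 90, 90),
                             sym_ops = NULL) {
  structure_model(partner, cell = cell, sym_ops = sym_ops)
}

loop_atom <- function(name = "CA", resno = 50L, x = 10, y = 10, z = 10)
  atom_row(name, x, y, z, resno = resno)

test_that("severity classes flip at 2.1 and 2.6 angstrom", {
  for (case in list(list(d = 2.09, sev = "heavy"),
                    list(d = 2.11, sev = "small"),
                    list(d = 2.59, sev = "small"))) {
    m <- clash_pair_model(atom_row("O", 10 + case$d, 10, 10, resno = 1L))
    rep <- find_clashes(loop_atom(), m)
    expect_equal(nrow(rep), 1)
    expect_equal(rep$severity, case$sev)
  }
  m <- clash_pair_model(atom_row("O", 10 + 2.61, 10, 10, resno = 1L))
  expect_equal(nrow(find_clashes(loop_atom(), m)), 0)
})

test_that("classification: CB is main chain, waters and ligands labelled", {
  m <- clash_pair_model(dplyr::bind_rows(
    atom_row("CB", 12, 10, 10, resno = 1L),
    atom_row("CG", 10, 12, 10, resname = "LEU", resno = 2L),
    atom_row("O", 10, 10, 12, resname = "HOH", resno = 3L,
             record = "HETATM"),
    atom_row("O1", 8, 10, 10, resname = "GOL", resno = 4L,
             record = "HETATM"),
    atom_row("C1", 10, 8, 10, resname = "NAG", resno = 5L,
             record = "HETATM"),
    atom_row("N", 10, 10, 8, resno = 6L, occ = 0.01)))
  rep <- find_clashes(loop_atom(), m)
  cls <- stats::setNames(rep$other_class, rep$other_resname)
  expect_equal(cls[["ALA"]], "main")      # the CB partner
  expect_equal(cls[["LEU"]], "side")
  expect_equal(cls[["HOH"]], "water")
  expect_equal(cls[["GOL"]], "exception_ligand")
  expect_equal(cls[["NAG"]], "other_ligand")
  expect_equal(unname(cls[which(rep$other_resno == 6)]), "low_occ")
})

test_that("clashes with symmetry mates are found and labelled", {
  # two-fold rotation about z through the cell center plus identity;
  # the direct distance is large, the image comes close
  cell <- c(20, 20, 30, 90, 90, 90)
  op2 <- list(R = matrix(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), 3, byrow = TRUE),
              t = c(1, 1, 0))
  partner <- atom_row("O", 11.2, 10, 5, resno = 1L)
  m <- clash_pair_model(partner, cell = cell,
                        sym_ops = list(loopgraft:::sym_identity(), op2))
  probe <- loop_atom(x = 10.8, y = 10, z = 5)
  rep <- find_clashes(probe, m)
  expect_true(any(rep$sym_op > 0))
  # brute-force oracle over all images in a 3x3x3 block
  ortho <- loopgraft:::orthogonalization_matrix(cell)
  frac <- solve(ortho, as.numeric(partner[1, c("x", "y", "z")]))
  dmin <- Inf
  for (op in list(loopgraft:::sym_identity(), op2))
    for (tx in -1:1) for (ty in -1:1) for (tz in -1:1) {
      f2 <- op$R %*% frac + op$t + c(tx, ty, tz)
      p <- as.numeric(ortho %*% f2)
      d <- sqrt(sum((p - c(10.8, 10, 5))^2))
      if (d > 1e-6) dmin <- min(dmin, d)
    }
  expect_equal(min(rep$distance), dmin, tolerance = 1e-9)
})

test_that("adjudication follows the importance hierarchy", {
  # rule 1: loop main vs existing main, heavy -> discard
  m <- clash_pair_model(atom_row("O", 12, 10, 10, resno = 1L))
  dec <- adjudicate(find_clashes(loop_atom(), m), m)
  expect_equal(dec$verdict, "discard_candidate")
  expect_length(dec$delete_model_rows, 0)

  # rule 1: loop main vs non-exception ligand, heavy -> discard
  m <- clash_pair_model(atom_row("C1", 12, 10, 10, resname = "NAG",
                                 resno = 1L, record = "HETATM"))
  expect_equal(adjudicate(find_clashes(loop_atom(), m), m)$verdict,
               "discard_candidate")

  # rule 2: loop main vs glycerol, heavy -> delete the glycerol
  gol <- dplyr::bind_rows(
    atom_row("O1", 12, 10, 10, resname = "GOL", resno = 1L,
             record = "HETATM"),
    atom_row("C1", 13, 10, 10, resname = "GOL", resno = 1L,
             record = "HETATM"))
  m <- clash_pair_model(gol)
  dec <- adjudicate(find_clashes(loop_atom(), m), m)
  expect_equal(dec$verdict, "keep")
  expect_equal(dec$delete_model_rows, c(1L, 2L))  # whole compound

  # rule 3: existing side chain vs loop backbone -> delete that side chain
  ser <- dplyr::bind_rows(
    atom_row("OG", 12, 10, 10, resname = "SER", resno = 1L),
    atom_row("CB", 13, 10, 10, resname = "SER", resno = 1L),
    atom_row("CA", 14, 10, 10, resname = "SER", resno = 1L))
  m <- clash_pair_model(ser)
  dec <- adjudicate(find_clashes(loop_atom(), m), m)
  expect_equal(dec$verdict, "keep")
  expect_equal(dec$delete_model_rows, 1L)  # OG only; CB and CA are main

  # rule 3 veto: disulfide-bonded cysteine -> discard
  cys <- dplyr::bind_rows(
    atom_row("SG", 12, 10, 10, resname = "CYS", resno = 1L, element = "S"),
    atom_row("SG", 12, 12, 10, resname = "CYS", resno = 8L, element = "S"))
  m <- clash_pair_model(cys)
  dec <- adjudicate(find_clashes(loop_atom(), m), m)
  expect_equal(dec$verdict, "discard_candidate")
  expect_equal(dec$reason, "disulfide_bridge")

  # rule 4: loop side chain vs protein -> crop the loop side chain
  m <- clash_pair_model(atom_row("CA", 12, 10, 10, resno = 1L))
  dec <- adjudicate(find_clashes(loop_atom(name = "OG"), m), m)
  expect_equal(dec$verdict, "keep")
  expect_equal(dec$crop_loop_resno, 50)

  # rule 5: waters deleted even on small clashes (2.5 A, side chain)
  m <- clash_pair_model(atom_row("O", 12.5, 10, 10, resname = "HOH",
                                 resno = 1L, record = "HETATM"))
  dec <- adjudicate(find_clashes(loop_atom(name = "OG"), m), m)
  expect_equal(dec$verdict, "keep")
  expect_equal(dec$delete_model_rows, 1L)

  # loop side vs water: water goes, the loop side chain is not cropped
  expect_length(dec$crop_loop_resno, 0)
})

test_that("adjudication is a pure function and never deletes kept classes", {
  gol <- dplyr::bind_rows(
    atom_row("O1", 12, 10, 10, resname = "GOL", resno = 1L,
             record = "HETATM"),
    atom_row("N", 10, 12.5, 10, resno = 2L),
    atom_row("O", 10, 10, 12.5, resname = "HOH", resno = 3L,
             record = "HETATM"))
  m <- clash_pair_model(gol)
  rep <- find_clashes(loop_atom(), m)
  d1 <- adjudicate(rep, m)
  d2 <- adjudicate(rep, m)
  expect_identical(d1, d2)
  # no deletion of existing protein main-chain atoms
  expect_false(2L %in% d1$delete_model_rows)
})

test_that("deletions resolve the clashes they were issued for", {
  gol <- dplyr::bind_rows(
    atom_row("O1", 12, 10, 10, resname = "GOL", resno = 1L,
             record = "HETATM"),
    atom_row("O", 12.4, 10.3, 10, resname = "HOH", resno = 2L,
             record = "HETATM"))
  m <- clash_pair_model(gol)
  dec <- adjudicate(find_clashes(loop_atom(), m), m)
  rep2 <- find_clashes(loop_atom(), m, exclude_atoms = dec$delete_model_rows)
  expect_equal(nrow(rep2[rep2$severity == "heavy", ]), 0)
})
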