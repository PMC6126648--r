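# Clash detection against the existing model (including crystallographic
# symmetry copies) and the importance-hierarchy adjudication.
#
# Severity: heavy = interatomic distance < 2.1 A, small = < 2.6 A.
# CB counts as main chain: its position is dictated by the backbone.

#' Find clashes between a candidate loop and the model
#'
#' All atom pairs under `small` angstrom between candidate atoms and
#' retained model atoms (the residues being replaced by the graft are
#' excluded), over all symmetry images whose atoms come within reach of
#' the candidate. Hydrogens are ignored.
#'
#' @param candidate a `candidate_loop` or atom tibble.
#' @param model target [structure_model()].
#' @param exclude_keys residue keys (chain resno insert) excluded from the
#'   clash search (the replaced span); deleted-atom bookkeeping can extend
#'   this via `exclude_atoms` (row indices into `model$atoms`).
#' @param exclude_atoms integer row indices of model atoms to ignore.
#' @param heavy,small severity cutoffs in angstrom (defaults 2.1 / 2.6).
#' @param exception_ligands residue codes of deletable compounds.
#' @return a `clash_report` tibble: model_row, sym_op, distance, severity,
#'   loop_atom, loop_resno, loop_side, other_chain, other_resno,
#'   other_resname, other_name, other_class.
#' @export
find_clashes <- function(candidate, model, exclude_keys = character(0),
                         exclude_atoms = integer(0),
                         heavy = 2.1, small = 2.6,
                         exception_ligands = EXCEPTION_LIGAND_CODES) {
  loop_atoms <- if (inherits(candidate, "candidate_loop"))
    candidate$atoms else candidate
  loop_atoms <- loop_atoms[loop_atoms$element != "H", ]
  lxyz <- coords(loop_atoms)

  a <- model$atoms
  keep <- !(residue_key(a) %in% exclude_keys) & a$element != "H"
  if (length(exclude_atoms) > 0) keep[exclude_atoms] <- FALSE
  rows <- which(keep)
  ma <- a[rows, ]
  mxyz <- coords(ma)

  out <- list()
  images <- symmetry_images(model)
  lo <- apply(lxyz, 2, min) - small
  hi <- apply(lxyz, 2, max) + small
  for (im in images) {
    sxyz <- im$f(mxyz)
    inbox <- sxyz[, 1] >= lo[1] & sxyz[, 1] <= hi[1] &
      sxyz[, 2] >= lo[2] & sxyz[, 2] <= hi[2] &
      sxyz[, 3] >= lo[3] & sxyz[, 3] <= hi[3]
    if (!any(inbox)) next
    sx <- sxyz[inbox, , drop = FALSE]
    srows <- which(inbox)
    for (j in seq_len(nrow(lxyz))) {
      d2 <- (sx[, 1] - lxyz[j, 1])^2 + (sx[, 2] - lxyz[j, 2])^2 +
        (sx[, 3] - lxyz[j, 3])^2
      hit <- which(d2 < small^2)
      if (im$id == 0) {
        # identity image: skip self-pairs with the candidate's own span
        hit <- hit[!(residue_key(ma[srows[hit], ]) %in%
                       unique(residue_key(loop_atoms)))]
      }
      for (k in hit) {
        mi <- srows[k]
        out[[length(out) + 1]] <- tibble::tibble(
          model_row = rows[mi], sym_op = im$id,
          distance = sqrt(d2[k]),
          severity = if (sqrt(d2[k]) < heavy) "heavy" else "small",
          loop_atom = loop_atoms$name[j], loop_resno = loop_atoms$resno[j],
          loop_side = if (loop_atoms$name[j] %in% MAINCHAIN_CLASH_NAMES)
            "main" else "side",
          other_chain = ma$chain[mi], other_resno = ma$resno[mi],
          other_resname = ma$resname[mi], other_name = ma$name[mi],
          other_class = classify_other(ma[mi, ], exception_ligands))
      }
    }
  }
  res <- if (length(out) == 0) tibble::tibble(
    model_row = integer(0), sym_op = integer(0), distance = numeric(0),
    severity = character(0), loop_atom = character(0),
    loop_resno = integer(0), loop_side = character(0),
    other_chain = character(0), other_resno = integer(0),
    other_resname = character(0), other_name = character(0),
    other_class = character(0)) else dplyr::bind_rows(out)
  class(res) <- c("clash_report", class(res))
  res
}

classify_other <- function(row, exception_ligands) {
  if (row$occ <= 0.01) return("low_occ")
  if (row$resname %in% WATER_CODES) return("water")
  if (row$resname %in% exception_ligands) return("exception_ligand")
  if (row$resname %in% names(aa_3to1)) {
    if (row$name %in% MAINCHAIN_CLASH_NAMES) return("main")
    return("side")
  }
  "other_ligand"
}

# symmetry images of the model as coordinate maps; id 0 = identity.
# Includes lattice translations -1..1 so contacts across cell borders are
# seen; images are produced lazily as closures.
symmetry_images <- function(model) {
  images <- list(list(id = 0, f = identity))
  if (is.null(model$cell)) return(images)
  ortho <- orthogonalization_matrix(model$cell)
  inv <- solve(ortho)
  id <- 0
  for (i in seq_along(model$sym_ops)) {
    op <- model$sym_ops[[i]]
    for (tx in -1:1) for (ty in -1:1) for (tz in -1:1) {
      if (i == 1 && tx == 0 && ty == 0 && tz == 0) next  # identity
      is_ident <- isTRUE(all.equal(op$R, diag(3))) &&
        isTRUE(all.equal(unname(op$t), c(0, 0, 0)))
      if (is_ident && tx == 0 && ty == 0 && tz == 0) next
      id <- id + 1
      local({
        R <- op$R; tt <- op$t + c(tx, ty, tz); myid <- id
        images[[length(images) + 1]] <<- list(
          id = myid,
          f = function(xyz) {
            fr <- t(inv %*% t(xyz))
            fr <- sweep(fr %*% t(R), 2, tt, "+")
            t(ortho %*% t(fr))
          })
      })
    }
  }
  images
}

#' Adjudicate clashes by the importance hierarchy
#'
#' Applies, in order: (1) a heavy clash of the loop main chain with
#' existing main chain or a non-exception ligand discards the candidate;
#' (2) a heavy clash of the loop main chain with an exception ligand
#' (glycerol, ethanol, ethanediol, PEG forms) deletes that ligand; (3) an
#' existing side chain clashing heavily with the loop backbone is deleted,
#' unless it is a cysteine in a disulfide bridge, which discards the
#' candidate; (4) a loop side chain clashing heavily with any protein atom
#' or non-water compound is cropped from the gamma atom onward; (5) waters
#' and atoms at occupancy <= 0.01 are deleted on any clash, small or
#' heavy.
#'
#' @param reports a `clash_report` from [find_clashes()].
#' @param model the target model (used to detect disulfide bridges:
#'   SG-SG under 2.5 angstrom).
#' @return a `clash_decision` list: `verdict` ("keep" or
#'   "discard_candidate"), `reason`, `delete_model_rows` (atom row indices
#'   into `model$atoms`), `crop_loop_resno` (loop residues to crop to CB).
#' @export
adjudicate <- function(reports, model) {
  decision <- function(verdict, reason = "", del = integer(0),
                       crop = integer(0)) {
    structure(list(verdict = verdict, reason = reason,
                   delete_model_rows = del, crop_loop_resno = crop),
              class = "clash_decision")
  }
  if (nrow(reports) == 0) return(decision("keep"))
  heavy <- reports[reports$severity == "heavy", ]

  # rule 1: loop main chain vs existing main chain / non-exception ligand
  r1 <- heavy$loop_side == "main" &
    heavy$other_class %in% c("main", "other_ligand")
  if (any(r1))
    return(decision("discard_candidate", "mainchain_clash"))

  # rule 3 veto first: disulfide-bonded cysteine SG vs loop backbone
  r3 <- heavy$loop_side == "main" & heavy$other_class == "side"
  if (any(r3)) {
    hh <- heavy[r3, ]
    for (i in seq_len(nrow(hh))) {
      if (hh$other_resname[i] == "CYS" &&
          in_disulfide(model, hh$other_chain[i], hh$other_resno[i]))
        return(decision("discard_candidate", "disulfide_bridge"))
    }
  }

  del <- integer(0); crop <- integer(0)
  a <- model$atoms
  # rule 2: exception ligands deleted wholesale
  r2 <- heavy$loop_side == "main" & heavy$other_class == "exception_ligand"
  for (i in which(r2)) {
    key <- residue_key(a[heavy$model_row[i], ])
    del <- c(del, which(residue_key(a) == key))
  }
  # rule 3: existing side chains deleted (gamma onward belongs to side)
  for (i in which(r3)) {
    key <- residue_key(a[heavy$model_row[i], ])
    rows <- which(residue_key(a) == key &
                    !(a$name %in% MAINCHAIN_CLASH_NAMES))
    del <- c(del, rows)
  }
  # rule 4: loop side chains cropped from the gamma atom onward
  r4 <- heavy$loop_side == "side" &
    heavy$other_class %in% c("main", "side", "exception_ligand",
                             "other_ligand")
  crop <- unique(heavy$loop_resno[r4])
  # rule 5: waters / low-occupancy atoms removed on any clash
  r5 <- reports$other_class %in% c("water", "low_occ")
  for (i in which(r5)) {
    row <- reports$model_row[i]
    if (reports$other_class[i] == "water") {
      key <- residue_key(a[row, ])
      del <- c(del, which(residue_key(a) == key))
    } else del <- c(del, row)
  }
  decision("keep", del = sort(unique(del)), crop = sort(crop))
}

in_disulfide <- function(model, chain, resno) {
  a <- model$atoms
  sg <- a[a$resname == "CYS" & a$name == "SG", ]
  me <- sg[sg$chain == chain & sg$resno == resno, ]
  if (nrow(me) == 0) return(FALSE)
  others <- sg[!(sg$chain == chain & sg$resno == resno), ]
  if (nrow(others) == 0) return(FALSE)
  d <- sqrt((others$x - me$x[1])^2 + (others$y - me$y[1])^2 +
              (others$z - me$z[1])^2)
  any(d < 2.5)
}

#' @export
print.clash_decision <- function(x, ...) {
  cat(sprintf("<clash_decision> %s%s | delete %d atom(s), crop %d loop residue(s)\n",
              x$verdict, if (nzchar(x$reason)) paste0(" (", x$reason, ")") else "",
              length(x$delete_model_rows), length(x$crop_loop_resno)))
  invisible(x)
}
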