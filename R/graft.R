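# Loop grafting: transfer the homolog loop (plus the two adjacent
# remodeled residues) into the target frame, manage occupancies, B-factor
# scaling, MET/MSE conversion, mutation cropping, and the candidate pool
# (dedup + ranking, zero-occupancy promotion).

new_candidate <- function(atoms, source, align_rmsd, transform,
                          state = "raw") {
  structure(list(atoms = atoms, source = source, align_rmsd = align_rmsd,
                 transform = transform, state = state,
                 reject_reason = "", scores = NULL,
                 fit = NULL, deletions = NULL),
            class = "candidate_loop")
}

#' @export
print.candidate_loop <- function(x, ...) {
  src <- if (is.null(x$source)) "zero-occupancy loop"
  else sprintf("homolog %d chain %s%s", x$source$homolog, x$source$chain,
               if (nzchar(x$source$alt)) paste0(" alt ", x$source$alt) else "")
  cat(sprintf("<candidate_loop> %s | %d atoms, align rmsd %.3f A, state %s\n",
              src, nrow(x$atoms), x$align_rmsd, x$state))
  invisible(x)
}

# residue span replaced by a graft: gap plus the two remodel residues
graft_span <- function(gap) (gap$first - 1):(gap$last + 1)

#' Graft a homolog loop into the target model
#'
#' Takes the homolog residues matching the gap plus the two directly
#' adjacent (remodel) residues, applies the anchor transform, crops side
#' chains at mutated positions to CB, renames MET/MSE to the target
#' model's prevailing type, sets all occupancies to 1.00 and multiplies
#' each atom's B factor by the ratio of protein-average B factors of
#' target and homolog.
#'
#' @param model target [structure_model()].
#' @param gap a gap row from [find_missing_loops()].
#' @param source a source from [collect_sources()].
#' @param homolog the source homolog [structure_model()].
#' @param transform the anchor `rigid_transform` (its `rmsd` must be below
#'   the alignment cutoff; enforced by the pipeline).
#' @param construct named construct sequences (used to fix the residue
#'   types of the grafted region); `NULL` falls back to the types modeled
#'   in target or homolog.
#' @return a `candidate_loop` in state "raw".
#' @export
graft_loop <- function(model, gap, source, homolog, transform,
                       construct = NULL) {
  span <- graft_span(gap)
  ha <- homolog$atoms[is_protein_row(homolog$atoms) &
                        homolog$atoms$chain == source$chain, ]
  b_ratio <- model_mean_b(model) / model_mean_b(homolog)

  target_uses_mse <- {
    tm <- model$atoms$resname[is_protein_row(model$atoms)]
    sum(tm == "MSE") > sum(tm == "MET")
  }

  rows <- list()
  for (pos in span) {
    hrn <- source_resno_at(source, pos)
    g <- select_altloc(ha[ha$resno == hrn, ], source$alt)
    g <- g[!duplicated(g$name) & g$element != "H", ]
    target_type <- target_residue_type(model, gap, pos, construct)
    if (is.na(target_type)) target_type <- g$resname[1]
    if (g$resname[1] != target_type) {
      met_pair <- all(sort(c(g$resname[1], target_type)) %in%
                        c("MET", "MSE")) && g$resname[1] %in% c("MET", "MSE")
      if (met_pair) {
        g <- convert_met_mse(g, target_type)
      } else {
        g <- g[crop_to_cb(g$name), ]
        if (target_type == "GLY") g <- g[g$name != "CB", ]
        g$resname <- target_type
      }
    }
    if (target_uses_mse && g$resname[1] == "MET") g <- convert_met_mse(g, "MSE")
    if (!target_uses_mse && g$resname[1] == "MSE") g <- convert_met_mse(g, "MET")
    g$chain <- gap$chain
    g$resno <- pos + gap$offset
    g$insert <- ""
    g$alt <- ""
    g$occ <- 1.0
    g$b <- g$b * b_ratio
    rows[[length(rows) + 1]] <- g
  }
  atoms <- dplyr::bind_rows(rows)
  atoms <- set_coords(atoms, apply_transform(transform, coords(atoms)))
  new_candidate(atoms, source, transform$rmsd, transform)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# target residue type at a construct position: from the construct
# sequence when available, else from modeled atoms
target_residue_type <- function(model, gap, pos, cons = NULL) {
  if (!is.null(cons)) {
    s <- toupper(construct_for_chain(cons, gap$chain))
    aa <- substr(s, pos, pos)
    if (nzchar(aa) && aa %in% names(aa_1to3)) return(unname(aa_1to3[aa]))
  }
  ta <- model$atoms[is_protein_row(model$atoms) &
                      model$atoms$chain == gap$chain &
                      model$atoms$resno == pos + gap$offset, ]
  if (nrow(ta) > 0) return(ta$resname[1])
  NA_character_
}

convert_met_mse <- function(g, to) {
  if (to == "MSE") {
    g$resname <- "MSE"
    g$record <- "HETATM"
    i <- g$name == "SD"
    g$name[i] <- "SE"; g$element[i] <- "SE"
  } else {
    g$resname <- "MET"
    g$record <- "ATOM"
    i <- g$name == "SE"
    g$name[i] <- "SD"; g$element[i] <- "S"
  }
  g
}

#' Promote a zero-occupancy loop to a candidate
#'
#' When a gap is actually modeled at occupancy <= 0.01, the existing
#' coordinates enter the candidate pool as an extra candidate with
#' alignment RMSD 0 and no transform; occupancies are set to 1.00 and the
#' candidate passes through the same filter chain as grafted candidates.
#'
#' @param model target [structure_model()].
#' @param gap a gap row with `zero_occupancy_modeled = TRUE`.
#' @return a `candidate_loop`.
#' @export
zero_occupancy_candidate <- function(model, gap) {
  if (!isTRUE(gap$zero_occupancy_modeled))
    stop("gap is not modeled at zero occupancy")
  span <- graft_span(gap)
  a <- model$atoms[is_protein_row(model$atoms) &
                     model$atoms$chain == gap$chain &
                     model$atoms$resno %in% (span + gap$offset), ]
  a <- a[a$alt == "" | a$alt == sort(unique(a$alt))[1], ]
  a <- a[!duplicated(paste(a$resno, a$name)) & a$element != "H", ]
  a$alt <- ""
  a$occ <- 1.0
  cand <- new_candidate(a, NULL, 0, NULL)
  # the loop vouches for its own cis peptides
  dih <- backbone_dihedrals(a)
  om <- dih$omega[!is.na(dih$omega)]
  cand$own_cis <- abs(om) < 90
  cand
}

# backbone coordinate matrix of a candidate in fixed atom order
candidate_backbone <- function(cand) {
  a <- cand$atoms[cand$atoms$name %in% BACKBONE_NAMES, ]
  a <- a[order(a$resno, match(a$name, BACKBONE_NAMES)), ]
  coords(a)
}

#' Deduplicate and rank candidate loops
#'
#' Candidates are sorted by ascending anchor-alignment RMSD (ties broken
#' by homolog input order for determinism). Walking that order, a
#' candidate is dropped when its loop-backbone RMSD to an already kept
#' candidate is below `dedup_rmsd` (the kept one has the better alignment
#' RMSD, so for any such pair the one with the worse alignment is the one
#' discarded). The survivors are truncated to `top_n`.
#'
#' @param cands list of `candidate_loop`s.
#' @param top_n number of candidates retained (default 10).
#' @param dedup_rmsd conformational similarity threshold in angstrom
#'   (default 0.1).
#' @return list of surviving `candidate_loop`s, best alignment first.
#' @export
dedup_and_rank <- function(cands, top_n = 10, dedup_rmsd = 0.1) {
  if (length(cands) == 0) return(cands)
  key <- vapply(cands, function(c)
    if (is.null(c$source)) -1L else c$source$homolog, 1L)
  ord <- order(vapply(cands, function(c) c$align_rmsd, 1), key)
  kept <- list(); kept_bb <- list()
  for (i in ord) {
    bb <- candidate_backbone(cands[[i]])
    dup <- FALSE
    for (kb in kept_bb) {
      if (nrow(kb) == nrow(bb) && coord_rmsd(kb, bb) < dedup_rmsd) {
        dup <- TRUE; break
      }
    }
    if (!dup) {
      kept[[length(kept) + 1]] <- cands[[i]]
      kept_bb[[length(kept_bb) + 1]] <- bb
    }
  }
  kept[seq_len(min(top_n, length(kept)))]
}
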