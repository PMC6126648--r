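# Homolog handling: sequence alignment of homolog chains onto the target
# construct, eligibility rules, anchor-atom preparation (with DEFY flips)
# and the rigid-body alignment around a gap.

# modeled 1-letter sequence of one chain of a model, with resnos
modeled_sequence <- function(model, chain) {
  a <- model$atoms
  a <- a[is_protein_row(a) & a$chain == chain, ]
  res <- dplyr::distinct(a, resno, resname)
  res <- res[order(res$resno), ]
  list(seq = paste(unname(aa_3to1[res$resname]), collapse = ""),
       resno = res$resno)
}

#' Align a homolog chain sequence to a target construct
#'
#' Global Needleman-Wunsch alignment (BLOSUM62, affine gap penalties
#' 11/1) of the homolog's modeled sequence against the target construct
#' sequence. Identity can then be evaluated over any construct-position
#' window via [window_identity()] (aligned columns only).
#'
#' @param target_seq target construct sequence (1-letter, case ignored).
#' @param homolog_seq homolog sequence (1-letter).
#' @return a pairing tibble: `tpos` (target construct position), `hpos`
#'   (position in `homolog_seq`), `taa`, `haa`, `match`.
#' @export
align_homolog_sequence <- function(target_seq, homolog_seq) {
  t_up <- toupper(target_seq); h_up <- toupper(homolog_seq)
  if (!nzchar(t_up) || !nzchar(h_up)) stop("empty sequence")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(t_up), Biostrings::AAString(h_up),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  su <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ti <- cumsum(pa != "-")
  hi <- cumsum(su != "-")
  keep <- pa != "-" & su != "-"
  tibble::tibble(tpos = ti[keep], hpos = hi[keep],
                 taa = pa[keep], haa = su[keep],
                 match = pa[keep] == su[keep])
}

#' Percent identity over a construct-position window (aligned columns)
#' @param pairing from [align_homolog_sequence()].
#' @param positions construct positions of the window.
#' @return percent identity in `[0, 100]`; `NA` if no aligned column.
#' @export
window_identity <- function(pairing, positions) {
  p <- pairing[pairing$tpos %in% positions, ]
  if (nrow(p) == 0) return(NA_real_)
  100 * mean(p$match)
}

# anchor positions for a gap: the 8 alignment residues (4 each side) and
# the 2 remodel-pair residues directly adjacent to the gap
anchor_positions <- function(gap) {
  list(align = c((gap$first - 5):(gap$first - 2),
                 (gap$last + 2):(gap$last + 5)),
       remodel = c(gap$first - 1, gap$last + 1))
}

# does the homolog chain have a complete backbone at all these construct
# positions (alt handling: complete in at least one alt-loc)?
homolog_complete_at <- function(hmodel, chain, pairing, positions) {
  hp <- pairing$hpos[match(positions, pairing$tpos)]
  if (any(is.na(hp))) return(FALSE)
  ms <- modeled_sequence(hmodel, chain)
  resnos <- ms$resno[hp]
  a <- hmodel$atoms
  a <- a[is_protein_row(a) & a$chain == chain, ]
  for (rn in resnos) {
    g <- a[a$resno == rn & a$name %in% BACKBONE_NAMES & a$occ > 0.01, ]
    if (!all(BACKBONE_NAMES %in% g$name)) return(FALSE)
  }
  TRUE
}

#' Collect eligible homolog sources for a gap
#'
#' A homolog chain is eligible when its whole-chain identity to the target
#' construct is at least `chain_identity_min`, it has a complete backbone
#' over the loop plus the ten flanking residues, and its sequence identity
#' over the loop window and over the eight alignment residues is at least
#' `identity_min` percent (single-residue loops are exempt from the
#' loop-window rule). Backbone alternates inside the homolog loop expand
#' into one source per alternate; homologs with several separate
#' alternate-containing stretches in the loop are skipped.
#'
#' @param gap one row of [find_missing_loops()] output.
#' @param construct named construct sequences.
#' @param homologs list of [structure_model()]s.
#' @param identity_min loop/anchor identity floor in percent (default 50).
#' @param chain_identity_min whole-chain homolog eligibility floor
#'   (default 70).
#' @return list of source records: homolog index, chain, pairing, resno
#'   lookup, alt id, identities, cis flags and Ramachandran Z of the
#'   source loop.
#' @export
collect_sources <- function(gap, construct, homologs,
                            identity_min = 50, chain_identity_min = 70) {
  tseq <- toupper(construct_for_chain(construct, gap$chain))
  loop_pos <- gap$first:gap$last
  anch <- anchor_positions(gap)
  span <- (gap$first - 5):(gap$last + 5)
  sources <- list()
  for (h in seq_along(homologs)) {
    hm <- homologs[[h]]
    for (ch in unique(hm$atoms$chain[is_protein_row(hm$atoms)])) {
      ms <- modeled_sequence(hm, ch)
      pairing <- align_homolog_sequence(tseq, ms$seq)
      chain_id <- 100 * mean(pairing$match)
      if (chain_id < chain_identity_min) next
      if (!homolog_complete_at(hm, ch, pairing, span)) next
      loop_id <- window_identity(pairing, loop_pos)
      anchor_id <- window_identity(pairing, anch$align)
      if (is.na(anchor_id) || anchor_id < identity_min) next
      if (gap$length > 1 && (is.na(loop_id) || loop_id < identity_min)) next

      # backbone alternates in the homolog loop region
      hresno <- ms$resno[pairing$hpos[match(span, pairing$tpos)]]
      loop_resno <- ms$resno[pairing$hpos[match(loop_pos, pairing$tpos)]]
      a <- hm$atoms[is_protein_row(hm$atoms) & hm$atoms$chain == ch, ]
      la <- a[a$resno %in% loop_resno, ]
      alt_ids <- setdiff(unique(la$alt[la$name %in% BACKBONE_NAMES]), "")
      if (length(alt_ids) > 0) {
        has_alt <- vapply(loop_resno, function(rn)
          any(nzchar(la$alt[la$resno == rn & la$name %in% BACKBONE_NAMES])),
          TRUE)
        r <- rle(has_alt)
        if (sum(r$values) > 1) next  # several alternate stretches: skip
      } else alt_ids <- ""

      for (alt in alt_ids) {
        cis <- source_cis_flags(a, loop_resno, alt)
        zspan <- (min(loop_resno) - 2):(max(loop_resno) + 2)
        zr <- tryCatch(
          rama_z(select_altloc(a[a$resno %in% zspan, ], alt))$z,
          error = function(e) NA_real_)
        sources[[length(sources) + 1]] <- list(
          homolog = h, chain = ch, pairing = pairing,
          hres = stats::setNames(ms$resno, seq_along(ms$resno)),
          alt = alt, chain_identity = chain_id,
          loop_identity = if (is.na(loop_id)) 100 else loop_id,
          anchor_identity = anchor_id,
          cis_flags = cis, source_rama_z = zr)
      }
    }
  }
  sources
}

# keep blank-alt atoms plus those of the requested alternate
select_altloc <- function(atoms, alt) {
  atoms[atoms$alt == "" | atoms$alt == alt, ]
}

# cis flags of the peptides inside (and bounding) the source loop region
source_cis_flags <- function(chain_atoms, loop_resno, alt) {
  span <- (min(loop_resno) - 1):(max(loop_resno) + 1)
  a <- select_altloc(chain_atoms[chain_atoms$resno %in% span, ], alt)
  if (nrow(a) == 0) return(logical(0))
  dih <- backbone_dihedrals(a)
  om <- dih$omega[!is.na(dih$omega)]
  abs(om) < 90
}

# homolog resno for a construct position under a source's pairing
source_resno_at <- function(source, tpos) {
  hp <- source$pairing$hpos[match(tpos, source$pairing$tpos)]
  unname(source$hres[as.character(hp)])
}

# DEFY flips: chemically equivalent atom label pairs per residue type
DEFY_SWAPS <- list(
  ASP = list(c("OD1", "OD2")),
  GLU = list(c("OE1", "OE2")),
  PHE = list(c("CD1", "CD2"), c("CE1", "CE2")),
  TYR = list(c("CD1", "CD2"), c("CE1", "CE2"))
)

#' Prepare paired anchor atoms for superposition
#'
#' Pairs the backbone atoms (N, CA, C, O) of the eight alignment residues
#' of target and homolog, plus all side-chain atoms of residues whose type
#' matches (mutated positions contribute backbone only, side chains
#' beyond CB are excluded). For Asp/Glu/Phe/Tyr, chemically equivalent
#' atom labels on the homolog side are swapped when the swap reduces the
#' summed squared distance after a provisional backbone-only fit (DEFY
#' flips). Residues with alternate side-chain conformations contribute
#' backbone only; alternate C-alpha atoms use the first location.
#'
#' @param model target [structure_model()].
#' @param gap a gap row.
#' @param source a source from [collect_sources()].
#' @param homolog the source's [structure_model()].
#' @return list: `fixed` (target coords), `moving` (homolog coords),
#'   `is_backbone` logical vector.
#' @export
prepare_anchor_atoms <- function(model, gap, source, homolog) {
  anch <- anchor_positions(gap)
  ta <- model$atoms[is_protein_row(model$atoms) &
                      model$atoms$chain == gap$chain, ]
  ha <- homolog$atoms[is_protein_row(homolog$atoms) &
                        homolog$atoms$chain == source$chain, ]
  fixed <- list(); moving <- list(); bb <- c()
  sidechain_rows <- list()  # per-residue bookkeeping for DEFY pass
  for (pos in anch$align) {
    trn <- pos + gap$offset
    hrn <- source_resno_at(source, pos)
    tg <- ta[ta$resno == trn, ]
    hg <- select_altloc(ha[ha$resno == hrn, ], source$alt)
    tg <- tg[!duplicated(tg$name), ]
    hg <- hg[!duplicated(hg$name), ]
    for (nm in BACKBONE_NAMES) {
      ti <- which(tg$name == nm); hi <- which(hg$name == nm)
      if (length(ti) == 0 || length(hi) == 0)
        stop("missing backbone atom ", nm, " in anchor residue")
      fixed[[length(fixed) + 1]] <- as.numeric(tg[ti[1], c("x", "y", "z")])
      moving[[length(moving) + 1]] <- as.numeric(hg[hi[1], c("x", "y", "z")])
      bb <- c(bb, TRUE)
    }
    same_type <- tg$resname[1] == hg$resname[1]
    no_alts <- !any(nzchar(tg$alt)) && !any(nzchar(hg$alt))
    if (same_type && no_alts) {
      sc_names <- intersect(setdiff(tg$name, BACKBONE_NAMES),
                            setdiff(hg$name, BACKBONE_NAMES))
      if (length(sc_names) > 0) {
        start <- length(fixed)
        for (nm in sc_names) {
          fixed[[length(fixed) + 1]] <-
            as.numeric(tg[tg$name == nm, c("x", "y", "z")][1, ])
          moving[[length(moving) + 1]] <-
            as.numeric(hg[hg$name == nm, c("x", "y", "z")][1, ])
          bb <- c(bb, FALSE)
        }
        sidechain_rows[[length(sidechain_rows) + 1]] <-
          list(resname = tg$resname[1], names = sc_names,
               rows = start + seq_along(sc_names))
      }
    }
  }
  fixed <- do.call(rbind, fixed)
  moving <- do.call(rbind, moving)

  # DEFY pass: provisional backbone-only fit, then per-residue label swaps
  prov <- superpose_quaternion(fixed[bb, , drop = FALSE],
                               moving[bb, , drop = FALSE])
  for (sr in sidechain_rows) {
    swaps <- DEFY_SWAPS[[sr$resname]]
    if (is.null(swaps)) next
    rows <- sr$rows
    moved <- apply_transform(prov, moving[rows, , drop = FALSE])
    cur <- sum((moved - fixed[rows, , drop = FALSE])^2)
    perm <- seq_along(sr$names)
    for (sw in swaps) {
      i1 <- which(sr$names == sw[1]); i2 <- which(sr$names == sw[2])
      if (length(i1) == 0 || length(i2) == 0) next
      p2 <- perm; p2[c(i1, i2)] <- p2[c(i2, i1)]
      alt_cost <- sum((moved[p2, , drop = FALSE] -
                         fixed[rows, , drop = FALSE])^2)
      if (alt_cost < cur) { perm <- p2; cur <- alt_cost }
    }
    moving[rows, ] <- moving[rows, , drop = FALSE][perm, , drop = FALSE]
  }
  list(fixed = fixed, moving = moving, is_backbone = bb)
}

#' Rigid alignment of a homolog onto the anchors of a gap
#'
#' Runs [prepare_anchor_atoms()] and [superpose_quaternion()]; the
#' reported RMSD is over backbone atoms only.
#'
#' @inheritParams prepare_anchor_atoms
#' @return a `rigid_transform`.
#' @export
align_source <- function(model, gap, source, homolog) {
  pa <- prepare_anchor_atoms(model, gap, source, homolog)
  superpose_quaternion(pa$fixed, pa$moving, rmsd_subset = pa$is_backbone)
}
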