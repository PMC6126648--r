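# Reconstruction of missing main-chain atoms from peptide-plane geometry,
# C-terminal OXT completion, and occupancy normalization.
#
# The five atoms CA(i), C(i), O(i), N(i+1), CA(i+1) lie in a plane with
# fixed internal geometry (trans or cis). With at least three of the five
# present, superposing an ideal planar template onto the present atoms
# determines the coordinates of the missing ones.

# ideal in-plane 2D coordinates of the five peptide-plane atoms, embedded
# in 3D (z = 0), for a given omega (180 = trans, 0 = cis)
peptide_plane_template <- function(omega = 180) {
  geom <- protein_geometry()
  bt <- function(a, b) geom$bonds$target[geom$bonds$a == a & geom$bonds$b == b]
  at <- function(a, b, c)
    geom$angles$target[geom$angles$a == a & geom$angles$b == b &
                         geom$angles$c == c]
  ca1 <- c(0, 0, 0)
  c1 <- c(bt("CA", "C"), 0, 0)
  # N at angle CA-C-N from the CA->C direction, in-plane
  a_can <- at("CA", "C", "N+") * pi / 180
  n2 <- c1 + bt("C", "N+") * c(-cos(a_can), sin(a_can), 0)
  # O on the opposite side of the C-N axis from CA2 (trans) / same (cis)
  a_cao <- at("CA", "C", "O") * pi / 180
  o1 <- c1 + bt("C", "O") * c(-cos(a_cao), -sin(a_cao), 0)
  # CA2 from N, angle C-N-CA, in-plane; omega rotates it across the axis
  a_cnca <- at("C-", "N", "CA") * pi / 180
  dir_cn <- (n2 - c1) / vnorm(n2 - c1)
  # rotate dir by +/- angle within the plane
  rot2 <- function(v, th) c(cos(th) * v[1] - sin(th) * v[2],
                            sin(th) * v[1] + cos(th) * v[2], 0)
  ca2_cis <- n2 + bt("N", "CA") * rot2(dir_cn, pi - a_cnca)
  ca2_trans <- n2 + bt("N", "CA") * rot2(dir_cn, -(pi - a_cnca))
  ca2 <- if (abs(omega) < 90) ca2_cis else ca2_trans
  rbind(CA1 = ca1, C = c1, O = o1, N = n2, CA2 = ca2)
}

#' Reconstruct missing peptide-plane atoms
#'
#' Given the five plane positions (any of which may be `NULL`), superposes
#' the ideal planar template onto the atoms present and returns
#' coordinates for the missing ones. Requires at least three present
#' atoms. When both template senses are plausible, the one fitting the
#' present atoms best (lower residual) is used.
#'
#' @param context named list with entries `CA1`, `C`, `O`, `N`, `CA2`,
#'   each a length-3 numeric or `NULL` if missing.
#' @return named list of coordinates for the missing atoms, or `NULL`
#'   when fewer than three atoms are present (cannot reconstruct).
#' @export
reconstruct_missing <- function(context) {
  nm <- c("CA1", "C", "O", "N", "CA2")
  present <- nm[!vapply(context[nm], is.null, TRUE)]
  missing <- setdiff(nm, present)
  if (length(present) < 3) return(NULL)
  if (length(missing) == 0) return(list())
  obs <- do.call(rbind, context[present])
  best <- NULL
  for (om in c(180, 0)) {
    tmpl <- peptide_plane_template(om)
    tr <- tryCatch(superpose_quaternion(obs, tmpl[present, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(tr)) next
    if (is.null(best) || tr$rmsd < best$rmsd) best <- list(tr = tr, tmpl = tmpl,
                                                           rmsd = tr$rmsd)
  }
  if (is.null(best)) return(NULL)
  placed <- apply_transform(best$tr, best$tmpl[missing, , drop = FALSE])
  out <- lapply(seq_along(missing), function(i) placed[i, ])
  names(out) <- missing
  out
}

#' Complete missing backbone atoms in a model
#'
#' Scans every protein chain for residues missing up to three of their
#' main-chain atoms and rebuilds them from the planarity of the peptide
#' unit combined with ideal geometry. A C-alpha lies in two planes and is
#' rebuilt from the preceding residue's plane when both are available
#' (the discrepancy between the two solutions is recorded as a
#' diagnostic). Reconstructed atoms get occupancy 1.0 and the mean B of
#' the atoms of their plane.
#'
#' @param model a [structure_model()].
#' @return list: `model` (completed), `added` tibble (chain, resno, name,
#'   n_plane_atoms, ca_discrepancy).
#' @export
reconstruct_main_chain <- function(model) {
  a <- model$atoms
  added <- list()
  for (ch in unique(a$chain[is_protein_row(a)])) {
    ca <- a[is_protein_row(a) & a$chain == ch, ]
    resnos <- sort(unique(ca$resno))
    get_atom <- function(rn, nm) {
      g <- a[a$chain == ch & a$resno == rn & a$name == nm &
               is_protein_row(a), ]
      if (nrow(g) == 0) return(NULL)
      as.numeric(g[1, c("x", "y", "z")])
    }
    for (k in seq_along(resnos)) {
      rn <- resnos[k]
      have <- function(nm) !is.null(get_atom(rn, nm))
      miss <- BACKBONE_NAMES[!vapply(BACKBONE_NAMES, have, TRUE)]
      if (length(miss) == 0 || length(miss) > 3) next
      has_prev <- k > 1 && resnos[k - 1] == rn - 1
      has_next <- k < length(resnos) && resnos[k + 1] == rn + 1
      # CA reconstruction requires both neighbors modeled
      if ("CA" %in% miss && !(has_prev && has_next)) next
      new_atoms <- list()
      # plane of (rn-1, rn): covers this residue's N (and CA via CA2)
      if (has_prev) {
        ctx <- list(CA1 = get_atom(rn - 1, "CA"), C = get_atom(rn - 1, "C"),
                    O = get_atom(rn - 1, "O"), N = get_atom(rn, "N"),
                    CA2 = get_atom(rn, "CA"))
        rec <- reconstruct_missing(ctx)
        if (!is.null(rec)) {
          if ("N" %in% names(rec) && "N" %in% miss)
            new_atoms[["N"]] <- rec$N
          if ("CA2" %in% names(rec) && "CA" %in% miss)
            new_atoms[["CA"]] <- rec$CA2
        }
      }
      # plane of (rn, rn+1): covers CA, C, O of this residue
      if (has_next) {
        ctx <- list(CA1 = if (!is.null(new_atoms[["CA"]]))
          new_atoms[["CA"]] else get_atom(rn, "CA"),
          C = get_atom(rn, "C"), O = get_atom(rn, "O"),
          N = get_atom(rn + 1, "N"), CA2 = get_atom(rn + 1, "CA"))
        rec <- reconstruct_missing(ctx)
        if (!is.null(rec)) {
          for (nm in intersect(names(rec), c("C", "O")))
            if (nm %in% miss) new_atoms[[nm]] <- rec[[nm]]
          if ("CA1" %in% names(rec) && "CA" %in% miss &&
              is.null(new_atoms[["CA"]]))
            new_atoms[["CA"]] <- rec$CA1
        }
      }
      if (length(new_atoms) == 0) next
      # CA discrepancy diagnostic: the alternative solution from the
      # following residue's plane, when that plane has enough atoms
      ca_disc <- NA_real_
      if ("CA" %in% names(new_atoms) && has_prev && has_next) {
        rec2 <- reconstruct_missing(list(
          CA1 = NULL, C = get_atom(rn, "C"), O = get_atom(rn, "O"),
          N = get_atom(rn + 1, "N"), CA2 = get_atom(rn + 1, "CA")))
        if (!is.null(rec2) && "CA1" %in% names(rec2))
          ca_disc <- vnorm(rec2$CA1 - new_atoms[["CA"]])
      }
      plane_b <- mean(a$b[a$chain == ch & a$resno %in% c(rn - 1, rn, rn + 1) &
                            a$name %in% BACKBONE_NAMES])
      tmpl_rows <- lapply(names(new_atoms), function(nm) {
        tibble::tibble(record = "ATOM", eleno = 0L, name = nm, alt = "",
                       resname = ca$resname[ca$resno == rn][1], chain = ch,
                       resno = rn, insert = "",
                       x = new_atoms[[nm]][1], y = new_atoms[[nm]][2],
                       z = new_atoms[[nm]][3], occ = 1, b = plane_b,
                       element = substr(nm, 1, 1))
      })
      a <- dplyr::bind_rows(a, dplyr::bind_rows(tmpl_rows))
      for (nm in names(new_atoms))
        added[[length(added) + 1]] <- tibble::tibble(
          chain = ch, resno = rn, name = nm,
          n_plane_atoms = 5 - length(miss), ca_discrepancy = ca_disc)
    }
  }
  a <- a[order(match(a$chain, unique(a$chain)), a$resno), ]
  a$eleno <- seq_len(nrow(a))
  model$atoms <- a
  list(model = model,
       added = if (length(added) == 0)
         tibble::tibble(chain = character(0), resno = integer(0),
                        name = character(0), n_plane_atoms = integer(0),
                        ca_discrepancy = numeric(0))
       else dplyr::bind_rows(added))
}

#' Add the C-terminal OXT where the construct shows the chain is complete
#'
#' OXT is added when the chain's last modeled residue is the construct's
#' last residue and the residue is otherwise complete. It is placed in the
#' terminal carboxylate plane, symmetric to O about the CA-C axis, at
#' C-OXT 1.25 angstrom. Idempotent.
#'
#' @param model a [structure_model()].
#' @param construct named construct sequences; if `NULL` the operation is
#'   skipped with a warning (the terminal residue cannot be verified).
#' @return the model with OXT atoms added where justified.
#' @export
add_oxt <- function(model, construct = NULL) {
  if (is.null(construct)) {
    warning("no sequence source: OXT addition skipped")
    return(model)
  }
  a <- model$atoms
  for (ch in unique(a$chain[is_protein_row(a)])) {
    cs <- tryCatch(construct_for_chain(construct, ch),
                   error = function(e) NULL)
    if (is.null(cs)) next
    off <- tryCatch(chain_construct_offset(model, ch, cs),
                    error = function(e) NULL)
    if (is.null(off)) next
    ca <- a[is_protein_row(a) & a$chain == ch, ]
    last_rn <- max(ca$resno)
    if (last_rn - off != nchar(cs)) next        # chain truncated early
    g <- ca[ca$resno == last_rn, ]
    if (!all(BACKBONE_NAMES %in% g$name)) next  # residue incomplete
    if ("OXT" %in% g$name) next                 # already present
    CA <- as.numeric(g[g$name == "CA", c("x", "y", "z")][1, ])
    C <- as.numeric(g[g$name == "C", c("x", "y", "z")][1, ])
    O <- as.numeric(g[g$name == "O", c("x", "y", "z")][1, ])
    u <- (C - CA) / vnorm(C - CA)
    v <- O - C
    refl <- 2 * sum(v * u) * u - v  # reflection of the C->O vector about CA->C
    oxt <- C + 1.25 * refl / vnorm(refl)
    a <- dplyr::bind_rows(a, tibble::tibble(
      record = "ATOM", eleno = 0L, name = "OXT", alt = "",
      resname = g$resname[1], chain = ch, resno = last_rn, insert = "",
      x = oxt[1], y = oxt[2], z = oxt[3], occ = 1,
      b = mean(g$b[g$name %in% BACKBONE_NAMES]), element = "O"))
  }
  a <- a[order(match(a$chain, unique(a$chain)), a$resno), ]
  a$eleno <- seq_len(nrow(a))
  model$atoms <- a
  model
}

#' Reset partial occupancies to 1.0 where nothing justifies them
#'
#' A protein atom's occupancy is reset to full when its residue contains
#' no alternates and both sequence-adjacent bonded atoms are at full
#' occupancy. The carbonyl O, bonded only to its C, requires only that C
#' at full occupancy. HETATM records are never touched.
#'
#' @param model a [structure_model()].
#' @return the model with occupancies normalized.
#' @export
reset_occupancies <- function(model) {
  a <- model$atoms
  # bonded neighbors along the backbone / side chain, per atom name
  neighbor_names <- function(tmpl, name) {
    nb <- character(0)
    if (name == "N") nb <- c("prev:C", "CA")
    else if (name == "CA") nb <- c("N", "C")
    else if (name == "C") nb <- c("CA", "next:N")
    else if (name == "O") nb <- "C"
    else if (name == "OXT") nb <- "C"
    else if (name == "CB") nb <- "CA"
    else if (!is.null(tmpl)) {
      i <- which(tmpl$name == name)
      if (length(i) == 1) nb <- tmpl$c[i]
      kids <- tmpl$name[tmpl$c == name]
      nb <- c(nb, kids)
    }
    nb
  }
  prot <- which(is_protein_row(a))
  for (i in prot) {
    if (a$occ[i] >= 1) next
    res_rows <- which(a$chain == a$chain[i] & a$resno == a$resno[i] &
                        a$insert == a$insert[i])
    if (any(nzchar(a$alt[res_rows]))) next
    tmpl <- sidechain_template(a$resname[i])
    nbs <- neighbor_names(tmpl, a$name[i])
    if (length(nbs) == 0) next
    ok <- TRUE
    for (nb in nbs) {
      if (startsWith(nb, "prev:") || startsWith(nb, "next:")) {
        drn <- if (startsWith(nb, "prev:")) -1 else 1
        nm <- sub("^(prev|next):", "", nb)
        rows <- which(a$chain == a$chain[i] & a$resno == a$resno[i] + drn &
                        a$name == nm & is_protein_row(a))
        if (length(rows) == 0) next  # terminus: no constraint from there
        if (max(a$occ[rows]) < 1) { ok <- FALSE; break }
      } else {
        rows <- res_rows[a$name[res_rows] == nb]
        if (length(rows) == 0) { ok <- FALSE; break }
        if (max(a$occ[rows]) < 1) { ok <- FALSE; break }
      }
    }
    if (ok) a$occ[i] <- 1
  }
  model$atoms <- a
  model
}

#' Run the full main-chain fixing pass
#'
#' Reconstructs missing backbone atoms, adds C-terminal OXT atoms (when a
#' sequence source confirms the terminus) and resets unjustified partial
#' occupancies, in that order.
#'
#' @param model a [structure_model()].
#' @param construct named construct sequences or `NULL`.
#' @param oxt,occ_reset toggles for the respective steps.
#' @return list: `model`, `added` (reconstruction log tibble).
#' @export
fix_main_chain <- function(model, construct = NULL, oxt = TRUE, occ_reset = TRUE) {
  res <- reconstruct_main_chain(model)
  m <- res$model
  if (oxt) m <- add_oxt(m, construct)
  if (occ_reset) m <- reset_occupancies(m)
  list(model = m, added = res$added)
}
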