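# Synthetic fixture generation: ideal-geometry ground-truth structures,
# perturbed homologs, targets with deleted loops, and Gaussian-atom maps.
# Everything is reproducible from (spec, seed).

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Fixture specification
#'
#' Describes a synthetic study system: a ground-truth chain (sequence plus
#' a secondary-structure plan), the gap to carve out of the target, the
#' homolog recipe and the map recipe.
#'
#' @param sequence 1-letter construct sequence.
#' @param plan per-residue secondary structure string of the same length:
#'   `H` (helix, phi/psi -63/-42), `E` (strand, -120/135), `L` (loop,
#'   cycling through basin-interior phi/psi pairs). Default: all helix.
#' @param gap_start,gap_len construct position and length of the region
#'   removed from the target (`gap_len = 0`: no gap).
#' @param n_homologs number of perturbed homologs.
#' @param noise amplitude (angstrom) of the smooth per-residue
#'   displacement field applied to homologs. The field varies slowly along
#'   the chain so local bond geometry stays near-ideal, as in real
#'   homologous structures that differ by conformational change rather
#'   than distorted chemistry.
#' @param mutations number of random point mutations per homolog.
#' @param b_scale homolog B factors are multiplied by this factor.
#' @param zero_occ if `TRUE`, the gap region is kept in the target at
#'   occupancy 0 instead of being deleted.
#' @param b_blur,spacing map recipe (see [synthesize_map()]).
#' @param map_noise_snr signal-to-noise ratio of Gaussian noise added to
#'   the map (Inf = noise-free).
#' @param zero_map_over_gap if `TRUE`, the map is zeroed within 3 A of the
#'   ground-truth gap atoms.
#' @param chain chain id.
#' @param b_factor base B factor (angstrom^2).
#' @param seed integer seed; all fixture randomness flows from it.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(sequence, plan = NULL, gap_start = 0, gap_len = 0,
                         n_homologs = 3, noise = 0.2, mutations = 0,
                         b_scale = 1, zero_occ = FALSE,
                         b_blur = 15, spacing = 0.7, map_noise_snr = Inf,
                         zero_map_over_gap = FALSE,
                         chain = "A", b_factor = 20, seed = 1) {
  n <- nchar(sequence)
  if (is.null(plan)) plan <- strrep("H", n)
  stopifnot(nchar(plan) == n)
  structure(list(sequence = toupper(sequence), plan = plan,
                 gap_start = gap_start, gap_len = gap_len,
                 n_homologs = n_homologs, noise = noise,
                 mutations = mutations, b_scale = b_scale,
                 zero_occ = zero_occ, b_blur = b_blur, spacing = spacing,
                 map_noise_snr = map_noise_snr,
                 zero_map_over_gap = zero_map_over_gap, chain = chain,
                 b_factor = b_factor, seed = seed),
            class = "fixture_spec")
}

plan_phi_psi <- function(plan) {
  n <- nchar(plan)
  letters_ <- strsplit(plan, "")[[1]]
  loop_palette <- rbind(c(-63, -42), c(-120, 140), c(-85, 130), c(-70, -20))
  phi <- numeric(n); psi <- numeric(n)
  li <- 0
  for (i in seq_len(n)) {
    if (letters_[i] == "H") { phi[i] <- -63; psi[i] <- -42 }
    else if (letters_[i] == "E") { phi[i] <- -120; psi[i] <- 135 }
    else {
      li <- li + 1
      p <- loop_palette[(li - 1) %% nrow(loop_palette) + 1, ]
      phi[i] <- p[1]; psi[i] <- p[2]
    }
  }
  list(phi = phi, psi = psi)
}

#' Build an ideal-geometry ground-truth structure
#'
#' Grows a backbone from the bundled ideal bond lengths and angles along
#' the phi/psi plan (all omegas trans), attaches side chains at one
#' canonical rotamer per residue type, sets all occupancies to 1 and a
#' flat B factor, and wraps the chain in a generously padded P1 cell.
#'
#' @param spec a [fixture_spec()].
#' @return a [structure_model()].
#' @export
build_ground_truth <- function(spec) {
  seq1 <- strsplit(spec$sequence, "")[[1]]
  res3 <- unname(aa_1to3[seq1])
  if (any(is.na(res3))) stop("unknown residue letter in sequence")
  n <- length(res3)
  ang <- plan_phi_psi(spec$plan)
  geom <- protein_geometry()
  bt <- function(a, b) geom$bonds$target[geom$bonds$a == a & geom$bonds$b == b]
  at <- function(a, b, c)
    geom$angles$target[geom$angles$a == a & geom$angles$b == b &
                         geom$angles$c == c]
  # backbone
  bbN <- matrix(0, n, 3); bbCA <- matrix(0, n, 3)
  bbC <- matrix(0, n, 3); bbO <- matrix(0, n, 3)
  bbN[1, ] <- c(0, 0, 0)
  bbCA[1, ] <- c(bt("N", "CA"), 0, 0)
  a_nac <- at("N", "CA", "C") * pi / 180
  bbC[1, ] <- bbCA[1, ] + bt("CA", "C") *
    c(-cos(a_nac), sin(a_nac), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      bbN[i, ] <- place_atom(bbN[i - 1, ], bbCA[i - 1, ], bbC[i - 1, ],
                             bt("C", "N+"), at("CA", "C", "N+"),
                             ang$psi[i - 1])
      bbCA[i, ] <- place_atom(bbCA[i - 1, ], bbC[i - 1, ], bbN[i, ],
                              bt("N", "CA"), at("C-", "N", "CA"), 180)
      bbC[i, ] <- place_atom(bbC[i - 1, ], bbN[i, ], bbCA[i, ],
                             bt("CA", "C"), at("N", "CA", "C"), ang$phi[i])
    }
    bbO[i, ] <- place_atom(bbN[i, ], bbCA[i, ], bbC[i, ],
                           bt("C", "O"), at("CA", "C", "O"),
                           ang$psi[i] + 180)
  }
  rows <- list()
  for (i in seq_len(n)) {
    pos <- list(N = bbN[i, ], CA = bbCA[i, ], C = bbC[i, ], O = bbO[i, ])
    names_i <- c("N", "CA", "C", "O")
    elems_i <- c("N", "C", "C", "O")
    tmpl <- sidechain_template(res3[i])
    if (!is.null(tmpl)) {
      for (j in seq_len(nrow(tmpl))) {
        tr <- tmpl[j, ]
        pos[[tr$name]] <- place_atom(pos[[tr$a]], pos[[tr$b]], pos[[tr$c]],
                                     tr$bond, tr$angle, tr$tors)
        names_i <- c(names_i, tr$name)
        elems_i <- c(elems_i, tr$el)
      }
    }
    xyz <- do.call(rbind, pos[names_i])
    rows[[i]] <- tibble::tibble(
      record = "ATOM", eleno = 0L, name = names_i, alt = "",
      resname = res3[i], chain = spec$chain, resno = i, insert = "",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
      b = spec$b_factor, element = elems_i)
  }
  atoms <- dplyr::bind_rows(rows)
  atoms$eleno <- seq_len(nrow(atoms))
  # P1 cell with 12 A padding; shift the chain inside
  xyz <- coords(atoms)
  lo <- apply(xyz, 2, min); hi <- apply(xyz, 2, max)
  pad <- 12
  atoms <- set_coords(atoms, sweep(xyz, 2, lo - pad, "-"))
  cell <- c(hi - lo + 2 * pad, 90, 90, 90)
  structure_model(atoms, cell = cell, sym_ops = list(sym_identity()),
                  spacegroup = "P 1")
}

# smooth low-frequency displacement field: per-residue, shared by all
# atoms of a residue, RMS amplitude ~ sigma
smooth_displacement <- function(n_res, sigma) {
  s <- seq_len(n_res) / n_res
  disp <- matrix(0, n_res, 3)
  if (sigma <= 0) return(disp)
  for (ax in 1:3) {
    f <- sample(1:3, 1)
    ph <- stats::runif(1, 0, 2 * pi)
    disp[, ax] <- sigma * sqrt(2 / 3) * sin(2 * pi * f * s + ph)
  }
  disp
}

mutate_residue <- function(atoms, resno_i, new_res3) {
  # replace the side chain with the new type's template on the same
  # backbone; backbone atoms and CB geometry come from the template
  keep <- !(atoms$resno == resno_i &
              !(atoms$name %in% c("N", "CA", "C", "O")))
  out <- atoms[keep, ]
  bb <- atoms[atoms$resno == resno_i & atoms$name %in% c("N", "CA", "C", "O"), ]
  pos <- list(N = as.numeric(bb[bb$name == "N", c("x", "y", "z")]),
              CA = as.numeric(bb[bb$name == "CA", c("x", "y", "z")]),
              C = as.numeric(bb[bb$name == "C", c("x", "y", "z")]),
              O = as.numeric(bb[bb$name == "O", c("x", "y", "z")]))
  out$resname[out$resno == resno_i] <- new_res3
  tmpl <- sidechain_template(new_res3)
  if (!is.null(tmpl)) {
    add <- list()
    for (j in seq_len(nrow(tmpl))) {
      tr <- tmpl[j, ]
      pos[[tr$name]] <- place_atom(pos[[tr$a]], pos[[tr$b]], pos[[tr$c]],
                                   tr$bond, tr$angle, tr$tors)
      add[[j]] <- tibble::tibble(
        record = "ATOM", eleno = 0L, name = tr$name, alt = "",
        resname = new_res3, chain = bb$chain[1], resno = resno_i,
        insert = "", x = pos[[tr$name]][1], y = pos[[tr$name]][2],
        z = pos[[tr$name]][3], occ = 1, b = mean(bb$b), element = tr$el)
    }
    out <- dplyr::bind_rows(out, dplyr::bind_rows(add))
  }
  out <- out[order(out$resno), ]  # stable: backbone stays ahead of side chain
  out$eleno <- seq_len(nrow(out))
  out
}

#' Derive the target, homologs and map from a ground truth
#'
#' The target is the ground truth with the gap region removed (or kept at
#' occupancy 0 for the zero-occupancy case). Homologs are copies of the
#' truth with a smooth seeded displacement field, optional point
#' mutations, a random rigid transform and B-factor scaling. The map is
#' synthesized from the ground truth, optionally with noise or with the
#' density zeroed over the gap.
#'
#' @param spec a [fixture_spec()].
#' @return list with `truth`, `target`, `homologs` (list of
#'   [structure_model()]), `map`, `construct` (named sequence), `spec`.
#' @export
make_fixture <- function(spec) {
  with_seed(spec$seed, {
    truth <- build_ground_truth(spec)
    n <- nchar(spec$sequence)
    gpos <- if (spec$gap_len > 0)
      spec$gap_start:(spec$gap_start + spec$gap_len - 1) else integer(0)

    target <- truth
    if (length(gpos) > 0) {
      if (spec$zero_occ) {
        target$atoms$occ[target$atoms$resno %in% gpos] <- 0
      } else {
        target$atoms <- target$atoms[!(target$atoms$resno %in% gpos), ]
      }
    }

    homologs <- vector("list", spec$n_homologs)
    for (h in seq_len(spec$n_homologs)) {
      hm <- truth
      disp <- smooth_displacement(n, spec$noise)
      xyz <- coords(hm$atoms) + disp[hm$atoms$resno, , drop = FALSE]
      hm$atoms <- set_coords(hm$atoms, xyz)
      if (spec$mutations > 0) {
        muts <- sample(setdiff(seq_len(n), c(1, n)), spec$mutations)
        for (m in muts) {
          cur <- hm$atoms$resname[hm$atoms$resno == m][1]
          if (cur %in% c("GLY", "PRO")) next
          new3 <- sample(setdiff(c("ALA", "SER", "LEU", "ASN", "THR"), cur), 1)
          hm$atoms <- mutate_residue(hm$atoms, m, new3)
        }
      }
      rot <- random_rotation()
      tr <- stats::runif(3, -8, 8)
      hm$atoms <- set_coords(hm$atoms,
                             sweep(coords(hm$atoms) %*% t(rot), 2, tr, "+"))
      hm$atoms$b <- hm$atoms$b * spec$b_scale
      hm$cell <- NULL
      homologs[[h]] <- structure_model(hm$atoms, cell = NULL,
                                       spacegroup = "P 1")
    }

    map <- synthesize_map(truth, b_blur = spec$b_blur,
                          spacing = spec$spacing)
    if (is.finite(spec$map_noise_snr)) {
      noise_sd <- stats::sd(as.numeric(map$values)) / spec$map_noise_snr
      map$values <- map$values +
        array(stats::rnorm(length(map$values), 0, noise_sd), dim = map$dim)
    }
    if (spec$zero_map_over_gap && length(gpos) > 0) {
      ga <- truth$atoms[truth$atoms$resno %in% gpos, ]
      mask <- map_mask(map, coords(ga), 3.0)
      map$values[mask] <- 0
    }
    construct <- stats::setNames(spec$sequence, spec$chain)
    list(truth = truth, target = target, homologs = homologs, map = map,
         construct = construct, spec = spec)
  })
}

#' Write a fixture to disk (PDB + FASTA + CCP4)
#'
#' @param fx a fixture from [make_fixture()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_structure(fx$target, file.path(dir, "target.pdb"))
  write_fasta_sequences(fx$construct, file.path(dir, "construct.fasta"))
  for (i in seq_along(fx$homologs))
    write_structure(fx$homologs[[i]],
                    file.path(dir, sprintf("homolog_%02d.pdb", i)))
  write_ccp4(fx$map, file.path(dir, "map.ccp4"))
  invisible(dir)
}

# Ideal fragment with every backbone bond inflated by exactly +1 sigma
# while all angles stay at target: the analytic construction for checking
# RMSZ calibration (each bond then scores Z = 1 by design).
build_sigma_inflated_fragment <- function(n = 6) {
  geom <- protein_geometry()
  bt <- function(a, b) geom$bonds[geom$bonds$a == a & geom$bonds$b == b, ]
  at <- function(a, b, c)
    geom$angles$target[geom$angles$a == a & geom$angles$b == b &
                         geom$angles$c == c]
  phi <- rep(-63, n); psi <- rep(-42, n)
  bN <- bt("N", "CA"); bC <- bt("CA", "C"); bO <- bt("C", "O")
  bCN <- bt("C", "N+")
  lN <- bN$target + bN$sigma; lC <- bC$target + bC$sigma
  lO <- bO$target + bO$sigma; lCN <- bCN$target + bCN$sigma
  N <- matrix(0, n, 3); CA <- matrix(0, n, 3)
  C <- matrix(0, n, 3); O <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0); CA[1, ] <- c(lN, 0, 0)
  ang <- at("N", "CA", "C") * pi / 180
  C[1, ] <- CA[1, ] + lC * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], lCN,
                           at("CA", "C", "N+"), psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], lN,
                            at("C-", "N", "CA"), 180)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], lC,
                           at("N", "CA", "C"), phi[i])
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], lO, at("CA", "C", "O"),
                         psi[i] + 180)
  }
  rows <- list()
  for (i in seq_len(n)) {
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    rows[[i]] <- tibble::tibble(
      record = "ATOM", eleno = 0L, name = c("N", "CA", "C", "O"),
      alt = "", resname = "GLY", chain = "A", resno = i, insert = "",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = 20,
      element = c("N", "C", "C", "O"))
  }
  dplyr::bind_rows(rows)
}
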