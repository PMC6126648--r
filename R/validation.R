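# Geometry validation: restraint Z scores (bonds, angles, chirality,
# planes, torsions), peptide omega handling, the Ramachandran Z score and
# the Grubbs outlier comparison used to veto poorly scoring candidates.

#' Geometry restraint Z scores for a fragment
#'
#' Z per restraint is (observed - target) / sigma from the bundled
#' geometry table; the RMSZ per restraint class is the root mean square
#' over the fragment. Scored restraints cover the main chain (+CB):
#' backbone bonds and angles, the C-alpha chiral volume, peptide-plane
#' deviations and the omega torsions. Alternate locations beyond the first
#' are ignored.
#'
#' @param atoms atom tibble of one chain fragment with consecutive
#'   residues (complete N, CA, C, O per residue).
#' @return a `geometry_scores` list: rmsz_bond, rmsz_angle, rmsz_chir,
#'   rmsz_plane, rmsz_torsion, omega_devs (degrees from the nearest of 0
#'   or 180), cis_flags, peptide_gaps (C-N distances outside [1.2, 1.5]
#'   angstrom), n_residues.
#' @export
geometry_scores <- function(atoms) {
  geom <- protein_geometry()
  res <- split_fragment_residues(atoms)
  n <- length(res)
  # check required backbone atoms
  missing <- character(0)
  for (r in res) {
    have <- BACKBONE_NAMES %in% r$atoms$name
    if (!all(have))
      missing <- c(missing, paste0(r$resname, r$resno, ":",
                                   paste(BACKBONE_NAMES[!have], collapse = "+")))
  }
  if (length(missing) > 0)
    stop("missing backbone atoms: ", paste(missing, collapse = ", "))

  gp <- function(r, nm) {
    i <- which(r$atoms$name == nm)[1]
    if (is.na(i)) return(NULL)
    as.numeric(r$atoms[i, c("x", "y", "z")])
  }
  zb <- c(); za <- c(); zc <- c(); zp <- c(); zt <- c()
  omega_devs <- c(); cis_flags <- c(); pept_dist <- c()

  btab <- geom$bonds; atab <- geom$angles
  bond_z <- function(p, q, a, b) {
    t <- btab[btab$a == a & btab$b == b, ]
    (vnorm(q - p) - t$target[1]) / t$sigma[1]
  }
  angle_z <- function(p, q, r, a, b, c) {
    t <- atab[atab$a == a & atab$b == b & atab$c == c, ]
    (point_angle(p, q, r) - t$target[1]) / t$sigma[1]
  }

  for (i in seq_len(n)) {
    r <- res[[i]]
    N <- gp(r, "N"); CA <- gp(r, "CA"); C <- gp(r, "C"); O <- gp(r, "O")
    CB <- gp(r, "CB")
    zb <- c(zb, bond_z(N, CA, "N", "CA"), bond_z(CA, C, "CA", "C"),
            bond_z(C, O, "C", "O"))
    za <- c(za, angle_z(N, CA, C, "N", "CA", "C"),
            angle_z(CA, C, O, "CA", "C", "O"))
    if (!is.null(CB) && r$resname != "GLY") {
      zb <- c(zb, bond_z(CA, CB, "CA", "CB"))
      za <- c(za, angle_z(N, CA, CB, "N", "CA", "CB"),
              angle_z(CB, CA, C, "CB", "CA", "C"))
      zc <- c(zc, (chiral_volume(CA, N, C, CB) - geom$chiral_target) /
                geom$sigma_chiral)
    }
    if (i < n) {
      r2 <- res[[i + 1]]
      N2 <- gp(r2, "N"); CA2 <- gp(r2, "CA")
      d <- vnorm(N2 - C)
      pept_dist <- c(pept_dist, d)
      zb <- c(zb, bond_z(C, N2, "C", "N+"))
      za <- c(za, angle_z(CA, C, N2, "CA", "C", "N+"),
              angle_z(O, C, N2, "O", "C", "N+"),
              angle_z(C, N2, CA2, "C-", "N", "CA"))
      # peptide plane CA(i), C(i), O(i), N(i+1), CA(i+1)
      pl <- rbind(CA, C, O, N2, CA2)
      zp <- c(zp, plane_deviations(pl) / geom$sigma_plane)
      om <- point_dihedral(CA, C, N2, CA2)
      dev <- min(abs(om), abs(180 - abs(om)))
      omega_devs <- c(omega_devs, dev)
      cis_flags <- c(cis_flags, abs(om) < 90)
      zt <- c(zt, dev / geom$sigma_omega)
    }
  }
  rmsz <- function(z) if (length(z) == 0) 0 else sqrt(mean(z^2))
  structure(list(
    rmsz_bond = rmsz(zb), rmsz_angle = rmsz(za), rmsz_chir = rmsz(zc),
    rmsz_plane = rmsz(zp), rmsz_torsion = rmsz(zt),
    omega_devs = omega_devs, cis_flags = cis_flags,
    peptide_gaps = pept_dist < 1.2 | pept_dist > 1.5,
    peptide_dists = pept_dist,
    n_residues = n
  ), class = "geometry_scores")
}

#' @export
print.geometry_scores <- function(x, ...) {
  cat(sprintf(paste0("<geometry_scores> %d residues | RMSZ bond %.2f ",
                     "angle %.2f chir %.2f plane %.2f torsion %.2f\n"),
              x$n_residues, x$rmsz_bond, x$rmsz_angle, x$rmsz_chir,
              x$rmsz_plane, x$rmsz_torsion))
  invisible(x)
}

# split a fragment atom tibble into an ordered residue list (first altloc
# per atom name)
split_fragment_residues <- function(atoms) {
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$insert), ]
  keys <- residue_key(atoms)
  out <- list()
  for (k in unique(keys)) {
    g <- atoms[keys == k, ]
    g <- g[!duplicated(g$name), ]
    out[[k]] <- list(resno = g$resno[1], resname = g$resname[1], atoms = g)
  }
  out
}

#' Geometry-based accept/reject filter for a refined candidate loop
#'
#' Rejects candidates that did not converge in refinement, that have any
#' consecutive-residue C-N distance outside peptide-bond range, whose
#' restraint RMSZ values exceed the documented gates (bond or angle 1.2,
#' chirality 1.5, plane or torsion 2.0), that have two or more sequential
#' omega deviations greater than 30 degrees (a single distortion is
#' allowed), or that contain a cis-peptide at a position where the source
#' homolog loop is not also cis.
#'
#' @param scores a [geometry_scores()] result.
#' @param converged logical, did the real-space minimization converge.
#' @param source_cis logical vector of cis flags of the source homolog
#'   loop (same peptide order), or `NULL` when no source applies (e.g. a
#'   promoted zero-occupancy loop, which vouches for its own cis peptides).
#' @param max_rmsz_bond,max_rmsz_angle,max_rmsz_chir,max_rmsz_plane,max_rmsz_torsion,max_omega_dev
#'   filter gates.
#' @return list(accept = logical, reasons = character vector).
#' @export
geometry_filter <- function(scores, converged = TRUE, source_cis = NULL,
                            max_rmsz_bond = 1.2, max_rmsz_angle = 1.2,
                            max_rmsz_chir = 1.5, max_rmsz_plane = 2.0,
                            max_rmsz_torsion = 2.0, max_omega_dev = 30) {
  reasons <- character(0)
  if (!converged) reasons <- c(reasons, "not_converged")
  if (any(scores$peptide_gaps)) reasons <- c(reasons, "broken_peptide_bond")
  if (scores$rmsz_bond > max_rmsz_bond) reasons <- c(reasons, "rmsz_bond")
  if (scores$rmsz_angle > max_rmsz_angle) reasons <- c(reasons, "rmsz_angle")
  if (scores$rmsz_chir > max_rmsz_chir) reasons <- c(reasons, "rmsz_chir")
  if (scores$rmsz_plane > max_rmsz_plane) reasons <- c(reasons, "rmsz_plane")
  if (scores$rmsz_torsion > max_rmsz_torsion) reasons <- c(reasons, "rmsz_torsion")
  bad <- scores$omega_devs > max_omega_dev
  if (length(bad) >= 2 && any(bad[-1] & bad[-length(bad)]))
    reasons <- c(reasons, "sequential_omega_distortion")
  if (any(scores$cis_flags)) {
    if (is.null(source_cis)) {
      # no source to vouch: only reject if the candidate introduced cis
      # peptides without provenance information is unavailable -> accept
    } else {
      sc <- rep(FALSE, length(scores$cis_flags))
      sc[seq_len(min(length(source_cis), length(sc)))] <-
        source_cis[seq_len(min(length(source_cis), length(sc)))]
      if (any(scores$cis_flags & !sc))
        reasons <- c(reasons, "cis_peptide_not_in_source")
    }
  }
  list(accept = length(reasons) == 0, reasons = reasons)
}

# ---------------------------------------------------------------------------
# Ramachandran Z score
#
# Reference phi/psi distributions are generated in code from a parametric
# wrapped-Gaussian mixture over the canonical basins for five residue
# classes (general, Gly, Pro, pre-Pro, Ile/Val), binned at 2 degrees. They
# are a synthetic, reproducible stand-in for tables derived from a curated
# high-resolution torsion library; reference moments (mean and sd of the
# per-residue log-density under the distribution itself) are computed by
# exact summation over the bins.

RAMA_CLASSES <- c("general", "gly", "pro", "prepro", "ileval")

rama_mixture <- function(class) {
  # columns: phi0, psi0, sd_phi, sd_psi, weight
  comps <- switch(class,
    general = rbind(
      c(-63, -42, 11, 11, 0.42),
      c(-120, 135, 25, 25, 0.40),
      c(-90, 70, 18, 25, 0.08),
      c(62, 42, 13, 13, 0.05)),
    gly = rbind(
      c(-63, -42, 13, 13, 0.28),
      c(63, 42, 13, 13, 0.28),
      c(-100, 160, 30, 25, 0.20),
      c(100, -160, 30, 25, 0.19)),
    pro = rbind(
      c(-61, -35, 9, 12, 0.50),
      c(-65, 145, 9, 15, 0.45)),
    prepro = rbind(
      c(-120, 140, 25, 20, 0.55),
      c(-63, -40, 12, 12, 0.30),
      c(-90, 70, 18, 25, 0.10)),
    ileval = rbind(
      c(-115, 125, 18, 20, 0.55),
      c(-63, -45, 10, 10, 0.40))
  )
  eps <- 3e-5
  w <- comps[, 5]
  comps[, 5] <- w / sum(w) * (1 - eps)
  list(comps = comps, eps = eps)
}

wrap180 <- function(x) ((x + 180) %% 360) - 180

# package-level cache for the binned tables
.loopgraft_env <- new.env(parent = emptyenv())

#' Bundled Ramachandran reference tables
#'
#' Returns (and caches) the 2-degree-binned log-density tables and
#' reference moments per residue class. Bin centers are at
#' -179, -177, ..., 179 degrees.
#'
#' @param class one of "general", "gly", "pro", "prepro", "ileval".
#' @return list with `logp` (180 x 180 matrix, phi x psi), `mu`, `sd`.
#' @export
rama_reference <- function(class = RAMA_CLASSES) {
  class <- match.arg(class)
  key <- paste0("rama_", class)
  if (!is.null(.loopgraft_env[[key]])) return(.loopgraft_env[[key]])
  mix <- rama_mixture(class)
  centers <- seq(-179, 179, by = 2)
  ph <- matrix(centers, 180, 180)
  ps <- matrix(centers, 180, 180, byrow = TRUE)
  dens <- matrix(mix$eps / (360 * 360), 180, 180)
  for (i in seq_len(nrow(mix$comps))) {
    cp <- mix$comps[i, ]
    dph <- wrap180(ph - cp[1]); dps <- wrap180(ps - cp[2])
    dens <- dens + cp[5] / (2 * pi * cp[3] * cp[4]) *
      exp(-dph^2 / (2 * cp[3]^2) - dps^2 / (2 * cp[4]^2))
  }
  p <- dens * 4  # bin probability (2 x 2 degree bins)
  p <- p / sum(p)
  logp <- log(p)
  mu <- sum(p * logp)
  sdv <- sqrt(sum(p * logp^2) - mu^2)
  out <- list(logp = logp, mu = mu, sd = sdv, centers = centers)
  .loopgraft_env[[key]] <- out
  out
}

rama_bin <- function(angle) {
  pmin(180L, pmax(1L, as.integer(floor((wrap180(angle) + 180) / 2)) + 1L))
}

rama_class_of <- function(resname, next_resname = NA) {
  if (!is.na(next_resname) && next_resname == "PRO" && resname != "PRO")
    return("prepro")
  switch(resname, GLY = "gly", PRO = "pro", ILE = "ileval", VAL = "ileval",
         "general")
}

#' Backbone phi/psi dihedrals of a fragment
#'
#' @param atoms atom tibble of consecutive residues of one chain.
#' @return tibble: resno, resname, phi, psi (NA where undefined), omega
#'   (omega of the peptide bond preceding the residue).
#' @export
backbone_dihedrals <- function(atoms) {
  res <- split_fragment_residues(atoms)
  n <- length(res)
  gp <- function(r, nm) {
    i <- which(r$atoms$name == nm)[1]
    if (is.na(i)) return(NULL)
    as.numeric(r$atoms[i, c("x", "y", "z")])
  }
  out <- tibble::tibble(resno = integer(n), resname = character(n),
                        phi = NA_real_, psi = NA_real_, omega = NA_real_)
  for (i in seq_len(n)) {
    r <- res[[i]]
    out$resno[i] <- r$resno; out$resname[i] <- r$resname
    N <- gp(r, "N"); CA <- gp(r, "CA"); C <- gp(r, "C")
    if (i > 1) {
      rp <- res[[i - 1]]
      Cp <- gp(rp, "C"); CAp <- gp(rp, "CA")
      if (!is.null(Cp) && !is.null(N) && !is.null(CA) && !is.null(C)) {
        out$phi[i] <- point_dihedral(Cp, N, CA, C)
        out$omega[i] <- point_dihedral(CAp, Cp, N, CA)
      }
    }
    if (i < n) {
      rn <- res[[i + 1]]
      Nn <- gp(rn, "N")
      if (!is.null(N) && !is.null(CA) && !is.null(C) && !is.null(Nn))
        out$psi[i] <- point_dihedral(N, CA, C, Nn)
    }
  }
  out
}

#' Ramachandran Z score of a fragment or model
#'
#' Each residue with defined phi/psi is scored by the log-density of its
#' (phi, psi) under the bundled reference distribution for its class and
#' standardized against the class reference moments; the aggregate Z is
#' the mean of the per-residue standardized scores. Scores below -5
#' indicate backbone conformations far outside the reference basins.
#'
#' @param x a [structure_model()] or an atom tibble of consecutive
#'   residues.
#' @return a `rama_score` list: `z` (aggregate), `per_residue` tibble
#'   (resno, resname, class, phi, psi, logp, z).
#' @export
rama_z <- function(x) {
  atoms <- if (inherits(x, "structure_model"))
    x$atoms[is_protein_row(x$atoms), ] else x
  chains <- unique(atoms$chain)
  per <- list()
  for (ch in chains) {
    a <- atoms[atoms$chain == ch, ]
    dih <- backbone_dihedrals(a)
    n <- nrow(dih)
    if (n == 0) next
    for (i in seq_len(n)) {
      if (is.na(dih$phi[i]) || is.na(dih$psi[i])) next
      cls <- rama_class_of(dih$resname[i],
                           if (i < n) dih$resname[i + 1] else NA)
      ref <- rama_reference(cls)
      lp <- ref$logp[rama_bin(dih$phi[i]), rama_bin(dih$psi[i])]
      per[[length(per) + 1]] <- tibble::tibble(
        chain = ch, resno = dih$resno[i], resname = dih$resname[i],
        class = cls, phi = dih$phi[i], psi = dih$psi[i],
        logp = lp, z = (lp - ref$mu) / ref$sd)
    }
  }
  if (length(per) == 0) stop("no scoreable residue (phi/psi undefined)")
  per <- dplyr::bind_rows(per)
  structure(list(z = mean(per$z), per_residue = per), class = "rama_score")
}

#' @export
print.rama_score <- function(x, ...) {
  cat(sprintf("<rama_score> Z = %.2f over %d residues\n",
              x$z, nrow(x$per_residue)))
  invisible(x)
}

#' Sample phi/psi pairs from a bundled reference distribution
#'
#' @param class residue class.
#' @param n number of pairs.
#' @return n x 2 matrix of (phi, psi) in degrees.
#' @export
rama_sample <- function(class, n) {
  mix <- rama_mixture(class)
  k <- nrow(mix$comps)
  probs <- c(mix$comps[, 5], mix$eps)
  pick <- sample.int(k + 1, n, replace = TRUE, prob = probs)
  out <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    if (pick[i] > k) {
      out[i, ] <- stats::runif(2, -180, 180)
    } else {
      cp <- mix$comps[pick[i], ]
      out[i, ] <- wrap180(c(stats::rnorm(1, cp[1], cp[3]),
                            stats::rnorm(1, cp[2], cp[4])))
    }
  }
  colnames(out) <- c("phi", "psi")
  out
}

# score a matrix of (phi, psi) pairs directly against a class table
rama_score_angles <- function(angles, class = "general") {
  ref <- rama_reference(class)
  lp <- ref$logp[cbind(rama_bin(angles[, 1]), rama_bin(angles[, 2]))]
  (lp - ref$mu) / ref$sd
}

#' Grubbs-style outlier veto for a candidate's Ramachandran Z
#'
#' Invoked only when the candidate scores below `poor_z` (default -5).
#' The candidate is rejected when it is more than `k` (default 2) standard
#' deviations below the mean of either comparison population: the other
#' candidates' Z scores, or the Z scores of the source loop in the
#' homologs. Populations smaller than 3 provide insufficient evidence and
#' are skipped.
#'
#' @param candidate_z candidate's aggregate Z.
#' @param peer_zs numeric vector of other candidates' Z scores.
#' @param source_zs numeric vector of homolog source-loop Z scores.
#' @param poor_z trigger threshold (default -5).
#' @param k outlier multiple (default 2).
#' @return list(accept = logical, reason = character).
#' @export
rama_outlier_filter <- function(candidate_z, peer_zs = numeric(0),
                                source_zs = numeric(0), poor_z = -5, k = 2) {
  if (is.na(candidate_z) || candidate_z >= poor_z)
    return(list(accept = TRUE, reason = ""))
  is_outlier <- function(pop) {
    pop <- pop[is.finite(pop)]
    if (length(pop) < 3) return(FALSE)
    s <- stats::sd(pop)
    if (s < 1e-12) return(FALSE)
    (mean(pop) - candidate_z) / s > k
  }
  if (is_outlier(peer_zs))
    return(list(accept = FALSE, reason = "rama_outlier_vs_candidates"))
  if (is_outlier(source_zs))
    return(list(accept = FALSE, reason = "rama_outlier_vs_source"))
  list(accept = TRUE, reason = "")
}
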