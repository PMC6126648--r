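# Restrained real-space regularization of a grafted region: a
# quasi-Newton (L-BFGS) minimization of harmonic restraint Z-square terms
# (bonds, angles, planarity/omega torsions, chirality, torsion tethers to
# the start conformation, a Ramachandran term) minus a weighted sum of
# interpolated map density at atom centers. Gradients are analytic.

#' Move junction backbone N atoms into an open gap
#'
#' After grafting there may be small gaps between the loop termini and the
#' existing model. Where a consecutive-residue C-N distance exceeds 1.6
#' angstrom, the N atom is moved along the C-N line toward the junction
#' midpoint (final distance clamped to [1.33, 1.45] angstrom). This can
#' transiently distort the N atom's other bonds; the subsequent
#' minimization resolves them.
#'
#' @param region_atoms atom tibble of the contiguous refinement region.
#' @return the atom tibble with junction N atoms moved.
#' @export
close_gap_pregame <- function(region_atoms) {
  a <- region_atoms[order(region_atoms$resno), ]
  resnos <- sort(unique(a$resno))
  for (i in seq_len(length(resnos) - 1)) {
    if (resnos[i + 1] - resnos[i] != 1) next
    ci <- which(a$resno == resnos[i] & a$name == "C")
    ni <- which(a$resno == resnos[i + 1] & a$name == "N")
    if (length(ci) == 0 || length(ni) == 0) next
    cpos <- as.numeric(a[ci[1], c("x", "y", "z")])
    npos <- as.numeric(a[ni[1], c("x", "y", "z")])
    d <- vnorm(npos - cpos)
    if (d <= 1.6) next
    newd <- min(max(d / 2, 1.33), 1.45)
    newn <- cpos + newd * (npos - cpos) / d
    a$x[ni[1]] <- newn[1]; a$y[ni[1]] <- newn[2]; a$z[ni[1]] <- newn[3]
  }
  a
}

# ---------------------------------------------------------------------------
# Restraint construction

# Build index-based restraint tables for a contiguous region. `atoms` are
# free; `static_atoms` (may be empty) are boundary atoms included in
# restraints but never moved. Indices address rbind(atoms, static_atoms).
build_restraints <- function(atoms, static_atoms = NULL, w_rama = 0.05) {
  geom <- protein_geometry()
  all_atoms <- if (is.null(static_atoms) || nrow(static_atoms) == 0)
    atoms else dplyr::bind_rows(atoms, static_atoms)
  keys <- paste(all_atoms$resno, all_atoms$name)
  idx <- function(resno, name) {
    i <- match(paste(resno, name), keys)
    i
  }
  resnos <- sort(unique(all_atoms$resno))
  restype <- vapply(resnos, function(rn)
    all_atoms$resname[all_atoms$resno == rn][1], "")

  bt <- function(a, b) {
    r <- geom$bonds[geom$bonds$a == a & geom$bonds$b == b, ]
    c(r$target[1], r$sigma[1])
  }
  at <- function(a, b, c) {
    r <- geom$angles[geom$angles$a == a & geom$angles$b == b &
                       geom$angles$c == c, ]
    c(r$target[1], r$sigma[1])
  }
  bonds <- list(); angles <- list(); torsions <- list(); chirals <- list()
  rama <- list()
  addb <- function(i, j, t, s) {
    if (!any(is.na(c(i, j))))
      bonds[[length(bonds) + 1]] <<- c(i, j, t, s)
  }
  adda <- function(i, j, k, t, s) {
    if (!any(is.na(c(i, j, k))))
      angles[[length(angles) + 1]] <<- c(i, j, k, t, s)
  }
  addt <- function(i, j, k, l, t, s) {
    if (!any(is.na(c(i, j, k, l))))
      torsions[[length(torsions) + 1]] <<- c(i, j, k, l, t, s)
  }
  cur_tors <- function(i, j, k, l) {
    point_dihedral(as.numeric(all_atoms[i, c("x", "y", "z")]),
                   as.numeric(all_atoms[j, c("x", "y", "z")]),
                   as.numeric(all_atoms[k, c("x", "y", "z")]),
                   as.numeric(all_atoms[l, c("x", "y", "z")]))
  }

  for (ri in seq_along(resnos)) {
    rn <- resnos[ri]
    rt <- restype[ri]
    N <- idx(rn, "N"); CA <- idx(rn, "CA"); C <- idx(rn, "C")
    O <- idx(rn, "O"); CB <- idx(rn, "CB")
    v <- bt("N", "CA"); addb(N, CA, v[1], v[2])
    v <- bt("CA", "C"); addb(CA, C, v[1], v[2])
    v <- bt("C", "O"); addb(C, O, v[1], v[2])
    v <- at("N", "CA", "C"); adda(N, CA, C, v[1], v[2])
    v <- at("CA", "C", "O"); adda(CA, C, O, v[1], v[2])
    if (!is.na(CB) && rt != "GLY") {
      v <- bt("CA", "CB"); addb(CA, CB, v[1], v[2])
      v <- at("N", "CA", "CB"); adda(N, CA, CB, v[1], v[2])
      v <- at("CB", "CA", "C"); adda(CB, CA, C, v[1], v[2])
      chirals[[length(chirals) + 1]] <-
        c(CA, N, C, CB, geom$chiral_target, geom$sigma_chiral)
    }
    # side-chain restraints from the template (bond + angle + chi tether)
    tmpl <- sidechain_template(rt)
    if (!is.null(tmpl)) {
      for (j in seq_len(nrow(tmpl))) {
        tr <- tmpl[j, ]
        if (tr$name == "CB") next
        D <- idx(rn, tr$name)
        if (is.na(D)) next
        A <- idx(rn, tr$a); B <- idx(rn, tr$b); Cc <- idx(rn, tr$c)
        addb(Cc, D, tr$bond, geom$sigma_bond_generic)
        adda(B, Cc, D, tr$angle, geom$sigma_angle_generic)
        if (!any(is.na(c(A, B, Cc))))
          addt(A, B, Cc, D, cur_tors(A, B, Cc, D), 15)
      }
    }
    # inter-residue terms to the following residue
    if (ri < length(resnos) && resnos[ri + 1] - rn == 1) {
      rn2 <- resnos[ri + 1]
      N2 <- idx(rn2, "N"); CA2 <- idx(rn2, "CA"); C2 <- idx(rn2, "C")
      v <- bt("C", "N+"); addb(C, N2, v[1], v[2])
      v <- at("CA", "C", "N+"); adda(CA, C, N2, v[1], v[2])
      v <- at("O", "C", "N+"); adda(O, C, N2, v[1], v[2])
      v <- at("C-", "N", "CA"); adda(C, N2, CA2, v[1], v[2])
      # omega to the nearest of 0/180, plus the carbonyl-O improper,
      # together enforcing peptide planarity
      if (!any(is.na(c(CA, C, N2, CA2)))) {
        om <- cur_tors(CA, C, N2, CA2)
        om_t <- if (abs(om) < 90) 0 else 180
        addt(CA, C, N2, CA2, om_t, geom$sigma_omega)
        if (!is.na(O))
          addt(O, C, N2, CA2, wrap180(om_t - 180), geom$sigma_omega)
      }
      # phi/psi tethers to the start conformation (torsion-angle
      # restraints in the grafted frame)
      if (!any(is.na(c(C, N2, CA2, C2))))
        addt(C, N2, CA2, C2, cur_tors(C, N2, CA2, C2), 10)
      if (!any(is.na(c(N, CA, C, N2))))
        addt(N, CA, C, N2, cur_tors(N, CA, C, N2), 10)
      # Ramachandran term for residue rn2 (needs C- and N+)
      if (ri + 1 < length(resnos) && resnos[ri + 2] - rn2 == 1 &&
          w_rama > 0) {
        N3 <- idx(resnos[ri + 2], "N")
        if (!any(is.na(c(C, N2, CA2, C2, N3))))
          rama[[length(rama) + 1]] <-
            list(i = c(C, N2, CA2, C2, N3),
                 class = rama_class_of(restype[ri + 1],
                                       restype[min(ri + 2, length(restype))]))
      }
    }
  }
  mk <- function(l, n) if (length(l) == 0) matrix(0, 0, n) else do.call(rbind, l)
  list(bonds = mk(bonds, 4), angles = mk(angles, 5),
       torsions = mk(torsions, 6), chirals = mk(chirals, 6),
       rama = rama, n_free = nrow(atoms), n_all = nrow(all_atoms),
       static_xyz = if (is.null(static_atoms) || nrow(static_atoms) == 0)
         matrix(0, 0, 3) else coords(static_atoms))
}

# ---------------------------------------------------------------------------
# Vectorized energy and gradient

vcross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

acc_grad <- function(G, idx, M) {
  A <- rowsum(M, idx)
  rows <- as.integer(rownames(A))
  G[rows, ] <- G[rows, ] + A
  G
}

# continuous Ramachandran mixture density and d(log f)/d(phi, psi)
rama_mix_logf <- function(phi, psi, class) {
  mix <- rama_mixture(class)
  f <- mix$eps / (360 * 360)
  dfdphi <- 0; dfdpsi <- 0
  for (i in seq_len(nrow(mix$comps))) {
    cp <- mix$comps[i, ]
    dph <- wrap180(phi - cp[1]); dps <- wrap180(psi - cp[2])
    g <- cp[5] / (2 * pi * cp[3] * cp[4]) *
      exp(-dph^2 / (2 * cp[3]^2) - dps^2 / (2 * cp[4]^2))
    f <- f + g
    dfdphi <- dfdphi - g * dph / cp[3]^2
    dfdpsi <- dfdpsi - g * dps / cp[4]^2
  }
  list(logf = log(f), dphi = dfdphi / f, dpsi = dfdpsi / f)
}

region_energy <- function(par, rs, map, w_geom = 1, w_map = 3,
                          w_rama = 0.05, occ = NULL, want_grad = TRUE) {
  X <- matrix(par, ncol = 3, byrow = TRUE)
  A <- rbind(X, rs$static_xyz)
  E <- 0
  G <- matrix(0, nrow(A), 3)

  if (nrow(rs$bonds) > 0) {
    I <- rs$bonds[, 1]; J <- rs$bonds[, 2]
    dv <- A[I, , drop = FALSE] - A[J, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    z <- (d - rs$bonds[, 3]) / rs$bonds[, 4]
    E <- E + w_geom * sum(z^2)
    if (want_grad) {
      coef <- w_geom * 2 * z / (rs$bonds[, 4] * pmax(d, 1e-9))
      G <- acc_grad(G, I, coef * dv)
      G <- acc_grad(G, J, -coef * dv)
    }
  }
  if (nrow(rs$angles) > 0) {
    I <- rs$angles[, 1]; J <- rs$angles[, 2]; K <- rs$angles[, 3]
    u <- A[I, , drop = FALSE] - A[J, , drop = FALSE]
    v <- A[K, , drop = FALSE] - A[J, , drop = FALSE]
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    uh <- u / nu; vh <- v / nv
    cth <- pmin(1 - 1e-10, pmax(-1 + 1e-10, rowSums(uh * vh)))
    th <- acos(cth)
    z <- (th * 180 / pi - rs$angles[, 4]) / rs$angles[, 5]
    E <- E + w_geom * sum(z^2)
    if (want_grad) {
      sth <- sqrt(1 - cth^2)
      dEdth <- w_geom * 2 * z / rs$angles[, 5] * 180 / pi
      gi <- (cth * uh - vh) / (nu * sth) * dEdth
      gk <- (cth * vh - uh) / (nv * sth) * dEdth
      G <- acc_grad(G, I, gi)
      G <- acc_grad(G, K, gk)
      G <- acc_grad(G, J, -(gi + gk))
    }
  }
  if (nrow(rs$torsions) > 0) {
    tg <- torsion_batch(A, rs$torsions[, 1:4, drop = FALSE],
                        want_grad = want_grad)
    dev <- wrap180(tg$phi - rs$torsions[, 5])
    z <- dev / rs$torsions[, 6]
    E <- E + w_geom * sum(z^2)
    if (want_grad) {
      dEdphi <- w_geom * 2 * z / rs$torsions[, 6] * 180 / pi
      for (m in 1:4)
        G <- acc_grad(G, rs$torsions[, m], dEdphi * tg$grad[[m]])
    }
  }
  if (nrow(rs$chirals) > 0) {
    C0 <- rs$chirals[, 1]; P1 <- rs$chirals[, 2]
    P2 <- rs$chirals[, 3]; P3 <- rs$chirals[, 4]
    av <- A[P1, , drop = FALSE] - A[C0, , drop = FALSE]
    bv <- A[P2, , drop = FALSE] - A[C0, , drop = FALSE]
    cv <- A[P3, , drop = FALSE] - A[C0, , drop = FALSE]
    vol <- rowSums(vcross_rows(av, bv) * cv)
    z <- (vol - rs$chirals[, 5]) / rs$chirals[, 6]
    E <- E + w_geom * sum(z^2)
    if (want_grad) {
      coef <- w_geom * 2 * z / rs$chirals[, 6]
      g1 <- coef * vcross_rows(bv, cv)
      g2 <- coef * vcross_rows(cv, av)
      g3 <- coef * vcross_rows(av, bv)
      G <- acc_grad(G, P1, g1)
      G <- acc_grad(G, P2, g2)
      G <- acc_grad(G, P3, g3)
      G <- acc_grad(G, C0, -(g1 + g2 + g3))
    }
  }
  if (w_rama > 0 && length(rs$rama) > 0) {
    for (rr in rs$rama) {
      i <- rr$i
      tphi <- torsion_batch(A, matrix(i[1:4], 1), want_grad = want_grad)
      tpsi <- torsion_batch(A, matrix(i[2:5], 1), want_grad = want_grad)
      lf <- rama_mix_logf(tphi$phi, tpsi$phi, rr$class)
      E <- E - w_rama * lf$logf
      if (want_grad) {
        for (m in 1:4) {
          G[i[m], ] <- G[i[m], ] - w_rama * lf$dphi * tphi$grad[[m]] * 180 / pi
          G[i[m + 1], ] <- G[i[m + 1], ] -
            w_rama * lf$dpsi * tpsi$grad[[m]] * 180 / pi
        }
      }
    }
  }
  if (!is.null(map) && w_map > 0) {
    if (is.null(occ)) occ <- rep(1, rs$n_free)
    ip <- interpolate_cubic(map, X, gradient = want_grad)
    if (want_grad) {
      E <- E - w_map * sum(occ * ip$value)
      G[seq_len(rs$n_free), ] <- G[seq_len(rs$n_free), ] -
        w_map * occ * ip$grad
    } else E <- E - w_map * sum(occ * ip)
  }
  if (!is.finite(E))
    stop("non-finite energy in real-space regularization")
  if (want_grad) list(E = E, G = G[seq_len(rs$n_free), , drop = FALSE])
  else E
}

# batch torsion angles (degrees) and, optionally, gradients in rad/A for
# each of the four points
torsion_batch <- function(A, quad, want_grad = TRUE) {
  P1 <- A[quad[, 1], , drop = FALSE]; P2 <- A[quad[, 2], , drop = FALSE]
  P3 <- A[quad[, 3], , drop = FALSE]; P4 <- A[quad[, 4], , drop = FALSE]
  b1 <- P2 - P1; b2 <- P3 - P2; b3 <- P4 - P3
  n1 <- vcross_rows(b1, b2); n2 <- vcross_rows(b2, b3)
  nb2 <- sqrt(rowSums(b2^2))
  m1 <- vcross_rows(n1, b2 / nb2)
  x <- rowSums(n1 * n2); y <- rowSums(m1 * n2)
  phi <- atan2(y, x) * 180 / pi
  if (!want_grad) return(list(phi = phi))
  n1sq <- pmax(rowSums(n1^2), 1e-12)
  n2sq <- pmax(rowSums(n2^2), 1e-12)
  t1 <- (nb2 / n1sq) * n1
  t4 <- -(nb2 / n2sq) * n2
  c12 <- rowSums(b1 * b2) / nb2^2
  c32 <- rowSums(b3 * b2) / nb2^2
  t2 <- -(1 + c12) * t1 + c32 * t4
  t3 <- -(1 + c32) * t4 + c12 * t1
  list(phi = phi, grad = list(t1, t2, t3, t4))
}

#' Restrained real-space minimization of a region
#'
#' Minimizes `w_geom * (restraint Z-squares) - w_map * (summed
#' interpolated density)` with L-BFGS-B and analytic gradients. The
#' refinement region is the candidate loop plus one existing residue per
#' side; the next residue out on each side enters the restraints as a
#' fixed boundary.
#'
#' @param region_atoms atom tibble of the free region (contiguous
#'   residues).
#' @param map a [map_grid()], or `NULL` for pure geometry regularization.
#' @param static_atoms boundary atoms held fixed (may be `NULL`).
#' @param w_geom,w_map,w_rama energy weights (defaults 1, 3, 0.05).
#' @param max_iter iteration cap (default 1500).
#' @param tol projected-gradient tolerance passed to the optimizer
#'   (default 1e-3).
#' @return a `refine_result`: `atoms` (refined region), `converged`,
#'   `scores` (a [geometry_scores()] of the refined region), `energy`,
#'   `n_iter`.
#' @export
rsr_minimize <- function(region_atoms, map, static_atoms = NULL,
                         w_geom = 1, w_map = 3, w_rama = 0.05,
                         max_iter = 1500, tol = 1e-3) {
  region_atoms <- region_atoms[order(region_atoms$resno,
                                     match(region_atoms$name,
                                           c(BACKBONE_NAMES, "CB"))), ]
  rs <- build_restraints(region_atoms, static_atoms, w_rama = w_rama)
  occ <- region_atoms$occ
  par0 <- as.numeric(t(coords(region_atoms)))
  # optim calls fn and gr at the same point back to back: cache one eval
  last <- list(par = NULL, val = NULL)
  eval_at <- function(p) {
    if (is.null(last$par) || !identical(p, last$par))
      last <<- list(par = p,
                    val = region_energy(p, rs, map, w_geom, w_map,
                                        w_rama, occ))
    last$val
  }
  fn <- function(p) eval_at(p)$E
  gr <- function(p) as.numeric(t(eval_at(p)$G))
  res <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter, pgtol = tol,
                                     factr = 1e8))
  out_atoms <- set_coords(region_atoms,
                          matrix(res$par, ncol = 3, byrow = TRUE))
  scores <- geometry_scores(out_atoms)
  structure(list(atoms = out_atoms, converged = res$convergence == 0,
                 scores = scores, energy = res$value,
                 n_iter = res$counts[1]),
            class = "refine_result")
}

#' @export
print.refine_result <- function(x, ...) {
  cat(sprintf("<refine_result> E = %.2f, %s after %d evals | bond RMSZ %.2f\n",
              x$energy, if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$scores$rmsz_bond))
  invisible(x)
}
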