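# Real-space density handling: map grids, tricubic interpolation with
# analytic gradients, Gaussian-atom map synthesis, the loop/control density
# ratio, RSCC/RSR, and CCP4/MRC file I/O.

#' Create a density map grid
#'
#' A `map_grid` covers one unit cell periodically: grid node (i, j, k)
#' (0-based) sits at fractional coordinates (i/nx, j/ny, k/nz).
#'
#' @param values 3-D numeric array (nx, ny, nz), finite, each dim >= 4.
#' @param cell numeric(6) cell parameters.
#' @return an object of class `map_grid`.
#' @export
map_grid <- function(values, cell) {
  if (length(dim(values)) != 3) stop("values must be a 3-D array")
  if (any(dim(values) < 4))
    stop("grid dimensions must be at least 4 per axis (cubic support)")
  if (!all(is.finite(values))) stop("map values must be finite")
  structure(list(values = values, dim = dim(values), cell = cell,
                 ortho = orthogonalization_matrix(cell)),
            class = "map_grid")
}

#' @export
print.map_grid <- function(x, ...) {
  cat(sprintf("<map_grid> %d x %d x %d, cell %s A, range [%.3g, %.3g]\n",
              x$dim[1], x$dim[2], x$dim[3],
              paste(sprintf("%.1f", x$cell[1:3]), collapse = " "),
              min(x$values), max(x$values)))
  invisible(x)
}

# 4-point Lagrange cubic weights at offset t in [0,1) over nodes -1,0,1,2.
# Exact at nodes and for polynomials of degree <= 3.
lagrange_w <- function(t) {
  cbind(-t * (t - 1) * (t - 2) / 6,
        (t + 1) * (t - 1) * (t - 2) / 2,
        -(t + 1) * t * (t - 2) / 2,
        (t + 1) * t * (t - 1) / 6)
}

# derivative of the weights with respect to t
lagrange_dw <- function(t) {
  cbind(-(3 * t^2 - 6 * t + 2) / 6,
        (3 * t^2 - 4 * t - 1) / 2,
        -(3 * t^2 - 2 * t - 2) / 2,
        (3 * t^2 - 1) / 6)
}

#' Tricubic interpolation of a map
#'
#' Separable 4-point Lagrange interpolation per axis: exact at grid nodes
#' and exact for per-axis polynomial fields of degree up to three, with
#' periodic wrapping over the cell.
#'
#' @param map a [map_grid()].
#' @param pos n x 3 matrix (or length-3 vector) of cartesian positions.
#' @param gradient if `TRUE`, also return the analytic cartesian gradient.
#' @return numeric(n) of density values, or if `gradient` a list
#'   `list(value, grad)` with `grad` n x 3.
#' @export
interpolate_cubic <- function(map, pos, gradient = FALSE) {
  pos <- if (is.null(dim(pos))) matrix(pos, ncol = 3) else as.matrix(pos)
  if (!all(is.finite(pos))) stop("non-finite position passed to interpolation")
  n <- nrow(pos)
  frac <- t(solve(map$ortho, t(pos)))
  d <- map$dim
  u <- sweep(frac, 2, d, "*")
  fl <- floor(u)
  t_ <- u - fl
  W <- lapply(1:3, function(ax) lagrange_w(t_[, ax]))
  idx <- lapply(1:3, function(ax) {
    # wrap the 4-node stencil fl-1 .. fl+2 into 1-based array indices
    m <- vapply(0:3, function(o) ((fl[, ax] - 1 + o) %% d[ax]) + 1,
                numeric(n))
    if (n == 1) m <- matrix(m, nrow = 1)
    m
  })
  val <- numeric(n)
  if (gradient) {
    dW <- lapply(1:3, function(ax) lagrange_dw(t_[, ax]))
    gu <- matrix(0, n, 3)
  }
  v <- map$values
  nx <- d[1]; ny <- d[2]
  for (a in 1:4) for (b in 1:4) for (cc in 1:4) {
    lin <- idx[[1]][, a] + (idx[[2]][, b] - 1) * nx +
      (idx[[3]][, cc] - 1) * nx * ny
    vv <- v[lin]
    val <- val + W[[1]][, a] * W[[2]][, b] * W[[3]][, cc] * vv
    if (gradient) {
      gu[, 1] <- gu[, 1] + dW[[1]][, a] * W[[2]][, b] * W[[3]][, cc] * vv
      gu[, 2] <- gu[, 2] + W[[1]][, a] * dW[[2]][, b] * W[[3]][, cc] * vv
      gu[, 3] <- gu[, 3] + W[[1]][, a] * W[[2]][, b] * dW[[3]][, cc] * vv
    }
  }
  if (!gradient) return(val)
  # chain rule: d(value)/d(xyz) = t(d(u)/d(xyz)) %*% d(value)/d(u),
  # u = diag(dim) %*% inv(O) %*% xyz
  m <- diag(d) %*% solve(map$ortho)
  list(value = val, grad = gu %*% m)
}

#' Synthesize a density map from a model (Gaussian atoms)
#'
#' Each atom contributes an isotropic Gaussian with width set by its B
#' factor plus `b_blur` and amplitude proportional to its electron count
#' times occupancy, sampled on the grid with periodic wrapping. Used as a
#' stand-in for experimentally derived maps in fixtures and for
#' model-calculated maps in RSCC computation.
#'
#' @param model a [structure_model()] (atoms with occ = 0 contribute
#'   nothing).
#' @param b_blur extra smearing B added to each atom's B factor
#'   (angstrom^2, default 10).
#' @param spacing approximate grid spacing in angstrom (default 0.7).
#' @param cell cell parameters; defaults to the model's cell.
#' @param dim explicit grid dimensions (overrides `spacing`), e.g. to
#'   synthesize on the same grid as an observed map.
#' @return a [map_grid()].
#' @export
synthesize_map <- function(model, b_blur = 10, spacing = 0.7, cell = NULL,
                           dim = NULL) {
  if (spacing <= 0) stop("grid spacing must be positive")
  if (is.null(cell)) cell <- model$cell
  if (is.null(cell)) stop("model has no cell; supply one")
  a <- model$atoms
  if (nrow(a) == 0) stop("model has no atoms")
  d <- if (!is.null(dim)) as.integer(dim)
  else pmax(4L, as.integer(round(cell[1:3] / spacing)))
  vals <- array(0, dim = d)
  ortho <- orthogonalization_matrix(cell)
  frac_all <- t(solve(ortho, t(coords(a))))
  elec <- ELEMENT_ELECTRONS[a$element]
  elec[is.na(elec)] <- 6
  axis_step <- cell[1:3] / d
  for (i in seq_len(nrow(a))) {
    if (a$occ[i] <= 0) next
    bprime <- a$b[i] + b_blur
    # cutoff where the Gaussian falls to 1e-4 of its peak
    rc <- sqrt(bprime * log(1e4)) / (2 * pi)
    hw <- pmin(d - 1, ceiling(rc / axis_step) + 1)
    ctr <- frac_all[i, ] * d
    i0 <- floor(ctr)
    rng <- lapply(1:3, function(ax) (i0[ax] - hw[ax]):(i0[ax] + hw[ax]))
    g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    df <- sweep(g, 2, d, "/") - matrix(frac_all[i, ], nrow(g), 3, byrow = TRUE)
    dxyz <- df %*% t(ortho)
    r2 <- rowSums(dxyz^2)
    amp <- elec[i] * a$occ[i] * (4 * pi / bprime)^1.5
    rho <- amp * exp(-4 * pi^2 * r2 / bprime)
    wrapped <- sweep(g, 2, d, function(x, dd) (x %% dd) + 1)
    lin <- wrapped[, 1] + (wrapped[, 2] - 1) * d[1] +
      (wrapped[, 3] - 1) * d[1] * d[2]
    # accumulate (indices may repeat after wrapping in tiny cells)
    acc <- rowsum(rho, lin)
    vals[as.integer(rownames(acc))] <- vals[as.integer(rownames(acc))] + acc
  }
  map_grid(vals, cell)
}

#' Loop-to-control density ratio
#'
#' Mean interpolated density over the main-chain atoms (N, CA, C, O) of a
#' candidate loop, divided by the mean over a control set of reliably
#' ordered main-chain atoms: target main-chain atoms at construct
#' positions modeled in every supplied homolog. If the control set has
#' fewer than 30 atoms, all non-loop main-chain atoms of the model are
#' used instead. The candidate is acceptable when the ratio exceeds
#' `min_ratio`.
#'
#' @param candidate a `candidate_loop` (or an atom tibble of loop atoms).
#' @param model the target [structure_model()].
#' @param control_positions tibble with columns `chain`, `pos`, `resno` of
#'   positions ordered in all homologs, or `NULL` to use the fallback set.
#' @param map a [map_grid()].
#' @param min_ratio acceptance threshold (default 0.25).
#' @return a `density_fit_report` tibble row: loop_mean, control_mean,
#'   ratio, control_set_size, used_fallback, acceptable.
#' @export
density_ratio <- function(candidate, model, control_positions, map,
                          min_ratio = 0.25) {
  loop_atoms <- if (inherits(candidate, "candidate_loop"))
    candidate$atoms else candidate
  la <- loop_atoms[loop_atoms$name %in% BACKBONE_NAMES, ]
  loop_mean <- mean(interpolate_cubic(map, coords(la)))

  a <- model$atoms
  mc <- a[is_protein_row(a) & a$name %in% BACKBONE_NAMES, ]
  loop_keys <- unique(residue_key(loop_atoms))
  used_fallback <- FALSE
  ctrl <- NULL
  if (!is.null(control_positions) && nrow(control_positions) > 0) {
    keys <- paste(control_positions$chain, control_positions$resno, "")
    ctrl <- mc[residue_key(mc) %in% setdiff(keys, loop_keys), ]
  }
  if (is.null(ctrl) || nrow(ctrl) < 30) {
    used_fallback <- TRUE
    ctrl <- mc[!(residue_key(mc) %in% loop_keys), ]
  }
  if (nrow(ctrl) == 0) stop("empty density control set")
  control_mean <- mean(interpolate_cubic(map, coords(ctrl)))
  ratio <- if (control_mean > 0) loop_mean / control_mean else NA_real_
  out <- tibble::tibble(
    loop_mean = loop_mean, control_mean = control_mean, ratio = ratio,
    control_set_size = nrow(ctrl), used_fallback = used_fallback,
    acceptable = !is.na(ratio) && ratio > min_ratio
  )
  class(out) <- c("density_fit_report", class(out))
  out
}

#' Real-space correlation coefficient and R factor
#'
#' Pearson correlation (RSCC) and real-space R factor
#' RSR = sum|obs - calc| / sum|obs + calc| between two maps on the same
#' grid, over grid points within `radius` of any of the given atoms.
#'
#' @param atoms atom tibble (rows define the mask).
#' @param obs_map,calc_map [map_grid()]s on identical grids.
#' @param radius mask radius around atoms in angstrom (default 2.0).
#' @return tibble with `rscc`, `rsr`, `n_points`.
#' @export
rscc <- function(atoms, obs_map, calc_map, radius = 2.0) {
  if (!all(obs_map$dim == calc_map$dim))
    stop("maps must be on commensurate grids")
  mask <- map_mask(obs_map, coords(atoms), radius)
  o <- obs_map$values[mask]
  c_ <- calc_map$values[mask]
  if (stats::sd(o) < 1e-12 || stats::sd(c_) < 1e-12)
    stop("undefined correlation: zero-variance region")
  tibble::tibble(
    rscc = stats::cor(o, c_),
    rsr = sum(abs(o - c_)) / sum(abs(o + c_)),
    n_points = sum(mask)
  )
}

# logical index of grid points within radius of any atom position
map_mask <- function(map, xyz, radius) {
  d <- map$dim
  mask <- logical(prod(d))
  ortho <- map$ortho
  frac <- t(solve(ortho, t(xyz)))
  axis_step <- map$cell[1:3] / d
  hw <- pmin(d - 1, ceiling(radius / axis_step) + 1)
  for (i in seq_len(nrow(xyz))) {
    ctr <- frac[i, ] * d
    i0 <- floor(ctr)
    rng <- lapply(1:3, function(ax) (i0[ax] - hw[ax]):(i0[ax] + hw[ax]))
    g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    df <- sweep(g, 2, d, "/") - matrix(frac[i, ], nrow(g), 3, byrow = TRUE)
    r2 <- rowSums((df %*% t(ortho))^2)
    keep <- r2 <= radius^2
    if (!any(keep)) next
    w <- sweep(g[keep, , drop = FALSE], 2, d, function(x, dd) (x %% dd) + 1)
    mask[w[, 1] + (w[, 2] - 1) * d[1] + (w[, 3] - 1) * d[1] * d[2]] <- TRUE
  }
  mask
}

# ---------------------------------------------------------------------------
# CCP4/MRC map I/O (mode 2, axis order X Y Z, full-cell maps)

#' Write a map to CCP4/MRC format (mode 2)
#' @param map a [map_grid()].
#' @param path output file.
#' @export
write_ccp4 <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- map$dim
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                 # NC NR NS
  wi(2)                 # MODE
  wi(c(0, 0, 0))        # start
  wi(d)                 # sampling
  wf(map$cell)
  wi(c(1, 2, 3))        # axis order
  wf(c(min(map$values), max(map$values), mean(map$values)))
  wi(1)                 # ISPG
  wi(0)                 # NSYMBT
  wi(rep(0, 27))        # words 26-52
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # machine stamp (LE)
  wf(stats::sd(as.numeric(map$values)))
  wi(0)                 # NLABL
  wi(rep(0, 200))       # labels
  wf(as.numeric(map$values))
  invisible(path)
}

#' Read a CCP4/MRC map (mode 2, axis order X Y Z, zero origin)
#' @param path map file.
#' @return a [map_grid()].
#' @export
read_ccp4 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("unsupported CCP4 mode: ", mode)
  start <- ri(3)
  if (any(start != 0)) stop("only zero-origin maps are supported")
  samp <- ri(3)
  if (any(samp != d)) stop("only full-cell maps are supported")
  cell <- rf(6)
  axes <- ri(3)
  if (any(axes != c(1, 2, 3))) stop("only X,Y,Z axis order is supported")
  rf(3)  # min/max/mean
  ri(1); nsymbt <- ri(1)
  ri(27)
  readChar(con, 4, useBytes = TRUE)
  readBin(con, "raw", n = 4)
  rf(1); ri(1); ri(200)
  if (nsymbt > 0) readBin(con, "raw", n = nsymbt)
  vals <- rf(prod(d))
  map_grid(array(vals, dim = d), cell)
}
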