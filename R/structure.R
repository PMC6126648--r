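#' Structure model container
#'
#' A `structure_model` holds a crystallographic model as a tidy atom table
#' plus the cell parameters and symmetry operators. The atom table is a
#' tibble with one row per atom: `record` (ATOM/HETATM), `eleno`, `name`,
#' `alt` (alternate-location id, "" if none), `resname`, `chain`, `resno`,
#' `insert`, `x`, `y`, `z` (angstrom), `occ`, `b` (angstrom^2), `element`.
#'
#' @param atoms atom tibble (see details).
#' @param cell numeric(6) cell parameters (a, b, c, alpha, beta, gamma) or
#'   `NULL` when no cell is known (treated as identity-only symmetry).
#' @param sym_ops list of symmetry operators, each `list(R = 3x3, t = numeric(3))`
#'   acting on fractional coordinates. Always contains the identity.
#' @param spacegroup space-group symbol (informational).
#' @return an object of class `structure_model`.
#' @export
structure_model <- function(atoms, cell = NULL, sym_ops = NULL,
                            spacegroup = "P 1") {
  atoms <- tibble::as_tibble(atoms)
  required <- c("record", "eleno", "name", "alt", "resname", "chain",
                "resno", "insert", "x", "y", "z", "occ", "b", "element")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0)
    stop("atom table missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(!is.finite(atoms$occ)) || any(atoms$occ < 0 | atoms$occ > 1))
    stop("occupancies must lie in [0, 1]")
  if (any(!is.finite(atoms$b)) || any(atoms$b < 0))
    stop("B factors must be non-negative")
  if (any(!nzchar(atoms$name))) stop("atom names must be nonempty")
  if (is.null(sym_ops)) sym_ops <- list(sym_identity())
  if (!is.null(cell)) cell <- unname(cell)
  structure(list(atoms = atoms, cell = cell, sym_ops = sym_ops,
                 spacegroup = spacegroup),
            class = "structure_model")
}

sym_identity <- function() list(R = diag(3), t = c(0, 0, 0))

#' @export
print.structure_model <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat(sprintf("<structure_model> %d atoms, %d chain(s): %s\n",
              nrow(x$atoms), length(ch), paste(ch, collapse = " ")))
  if (!is.null(x$cell))
    cat(sprintf("  cell %s  %s  (%d sym ops)\n",
                paste(sprintf("%.2f", x$cell[1:3]), collapse = " "),
                paste(sprintf("%.1f", x$cell[4:6]), collapse = " "),
                length(x$sym_ops)))
  invisible(x)
}

#' @method as_tibble structure_model
#' @export
as_tibble.structure_model <- function(x, ...) x$atoms

#' Coordinate matrix of an atom table or model
#' @param x a `structure_model` or atom tibble.
#' @return n x 3 matrix.
#' @export
coords <- function(x) {
  a <- if (inherits(x, "structure_model")) x$atoms else x
  as.matrix(a[, c("x", "y", "z")])
}

set_coords <- function(atoms, xyz) {
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

is_protein_row <- function(atoms) {
  # MSE is conventionally a HETATM but is part of the polypeptide
  (atoms$record == "ATOM" | atoms$resname == "MSE") &
    atoms$resname %in% names(aa_3to1)
}

is_water_row <- function(atoms) atoms$resname %in% WATER_CODES

#' Mean B factor over protein atoms
#' @param model a `structure_model`.
#' @export
model_mean_b <- function(model) {
  a <- model$atoms
  mean(a$b[is_protein_row(a)])
}

# unique residue key (chain + file numbering + insertion code)
residue_key <- function(atoms) paste(atoms$chain, atoms$resno, atoms$insert)

# ---------------------------------------------------------------------------
# Reading

#' Read a structure from PDB or mmCIF
#'
#' Coordinates, occupancies, B factors and alternate-location ids of all
#' ATOM/HETATM records are kept. For PDB files the CRYST1 cell and any
#' REMARK 290 SMTRY symmetry operators are parsed; for mmCIF the `_cell`
#' items are read. When no cell/symmetry information is present the model
#' gets identity-only symmetry.
#'
#' @param path file path.
#' @param dialect "pdb", "mmcif", or "auto" (default; by file extension).
#' @return a [structure_model()].
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "pdb") read_structure_pdb(path) else read_structure_cif(path)
}

read_structure_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  atom_idx <- grep("^(ATOM  |HETATM)", lines)
  for (i in atom_idx) {
    ln <- lines[i]
    if (nchar(ln) < 54 ||
        is.na(suppressWarnings(as.numeric(substr(ln, 31, 38)))) ||
        is.na(suppressWarnings(as.numeric(substr(ln, 39, 46)))) ||
        is.na(suppressWarnings(as.numeric(substr(ln, 47, 54)))))
      stop(sprintf("parse error in %s at line %d: malformed %s record",
                   path, i, substr(ln, 1, 6)))
  }
  p <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                error = function(e) stop("parse error reading ", path, ": ",
                                         conditionMessage(e)))
  a <- p$atom
  blank <- function(v) ifelse(is.na(v), "", v)
  elem <- blank(a$elesy)
  elem[!nzchar(elem)] <- vapply(a$elety[!nzchar(elem)], element_of, "")
  atoms <- tibble::tibble(
    record = ifelse(a$type == "HETATM", "HETATM", "ATOM"),
    eleno = a$eleno,
    name = a$elety,
    alt = blank(a$alt),
    resname = a$resid,
    chain = blank(a$chain),
    resno = a$resno,
    insert = blank(a$insert),
    x = a$x, y = a$y, z = a$z,
    occ = pmin(1, pmax(0, a$o)),
    b = pmax(0, a$b),
    element = toupper(elem)
  )
  cr <- grep("^CRYST1", lines, value = TRUE)
  cell <- NULL; sg <- "P 1"
  if (length(cr) >= 1) {
    cell <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                         substr(cr[1], 25, 33), substr(cr[1], 34, 40),
                         substr(cr[1], 41, 47), substr(cr[1], 48, 54)))
    sg <- trimws(substr(cr[1], 56, 66))
    if (!nzchar(sg)) sg <- "P 1"
  }
  sym_ops <- parse_smtry(lines)
  structure_model(atoms, cell = cell, sym_ops = sym_ops, spacegroup = sg)
}

# REMARK 290   SMTRY1   1  1.000000  0.000000  0.000000        0.00000
parse_smtry <- function(lines) {
  sm <- grep("^REMARK 290   SMTRY", lines, value = TRUE)
  if (length(sm) == 0) return(list(sym_identity()))
  fields <- lapply(strsplit(trimws(sub("^REMARK 290 *", "", sm)), " +"),
                   identity)
  rows <- do.call(rbind, lapply(fields, function(f) {
    c(as.numeric(substr(f[1], 6, 6)), as.numeric(f[2]),
      as.numeric(f[3:6]))
  }))
  ops <- list()
  for (id in sort(unique(rows[, 2]))) {
    r <- rows[rows[, 2] == id, , drop = FALSE]
    r <- r[order(r[, 1]), , drop = FALSE]
    if (nrow(r) != 3) next
    ops[[length(ops) + 1]] <- list(R = r[, 3:5], t = r[, 6])
  }
  if (length(ops) == 0) ops <- list(sym_identity())
  ops
}

# Minimal mmCIF reader: parses the _atom_site loop (any column order) and
# the _cell items. Quoted values are not expected inside atom_site rows.
read_structure_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (length(hdr_idx) == 0)
    stop("parse error reading ", path, ": no _atom_site loop found")
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body_start <- max(hdr_idx) + 1
  body <- character(0)
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("^(#|loop_|_|data_)", ln)) break
    body <- c(body, ln)
  }
  toks <- strsplit(body, "\\s+")
  bad <- which(vapply(toks, length, 1L) != length(fields))
  if (length(bad) > 0)
    stop(sprintf("parse error in %s at atom_site row %d: expected %d fields",
                 path, bad[1], length(fields)))
  m <- do.call(rbind, toks)
  colnames(m) <- fields
  get <- function(...) {
    for (f in c(...)) if (f %in% fields) return(m[, f])
    rep(NA_character_, nrow(m))
  }
  blank <- function(v) ifelse(is.na(v) | v == "?" | v == ".", "", v)
  num <- function(v) suppressWarnings(as.numeric(v))
  name <- blank(get("auth_atom_id", "label_atom_id"))
  elem <- blank(get("type_symbol"))
  elem[!nzchar(elem)] <- vapply(name[!nzchar(elem)], element_of, "")
  occ <- num(get("occupancy")); occ[is.na(occ)] <- 1
  b <- num(get("B_iso_or_equiv")); b[is.na(b)] <- 0
  atoms <- tibble::tibble(
    record = ifelse(get("group_PDB") == "HETATM", "HETATM", "ATOM"),
    eleno = as.integer(num(get("id"))),
    name = name,
    alt = blank(get("label_alt_id")),
    resname = blank(get("auth_comp_id", "label_comp_id")),
    chain = blank(get("auth_asym_id", "label_asym_id")),
    resno = as.integer(num(get("auth_seq_id", "label_seq_id"))),
    insert = blank(get("pdbx_PDB_ins_code")),
    x = num(get("Cartn_x")), y = num(get("Cartn_y")), z = num(get("Cartn_z")),
    occ = pmin(1, pmax(0, occ)),
    b = pmax(0, b),
    element = toupper(elem)
  )
  if (any(is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z)))
    stop("parse error reading ", path, ": non-numeric coordinates")
  grab <- function(tag) {
    ln <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
    if (length(ln) == 0) return(NA_real_)
    suppressWarnings(as.numeric(strsplit(trimws(ln[1]), "\\s+")[[1]][2]))
  }
  cell <- c(grab("_cell.length_a"), grab("_cell.length_b"),
            grab("_cell.length_c"), grab("_cell.angle_alpha"),
            grab("_cell.angle_beta"), grab("_cell.angle_gamma"))
  if (any(is.na(cell))) cell <- NULL
  sgl <- grep("^_symmetry.space_group_name_H-M", lines, value = TRUE)
  sg <- if (length(sgl) > 0)
    gsub("['\"]", "", trimws(sub("^\\S+\\s+", "", sgl[1]))) else "P 1"
  structure_model(atoms, cell = cell, sym_ops = list(sym_identity()),
                  spacegroup = sg)
}

# ---------------------------------------------------------------------------
# Writing

#' Write a structure to PDB and/or mmCIF
#'
#' @param model a [structure_model()].
#' @param path output file path.
#' @param dialect "pdb", "mmcif" or "auto" (by extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  if (dialect == "pdb") write_structure_pdb(model, path)
  else write_structure_cif(model, path)
  invisible(path)
}

format_atom_name <- function(name, element) {
  # single-letter elements with short names are indented one column
  if (nchar(name) >= 4) return(substr(name, 1, 4))
  if (nchar(element) == 1) sprintf(" %-3s", name) else sprintf("%-4s", name)
}

write_structure_pdb <- function(model, path) {
  a <- model$atoms
  out <- character(0)
  if (!is.null(model$cell)) {
    out <- c(out, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                          model$cell[1], model$cell[2], model$cell[3],
                          model$cell[4], model$cell[5], model$cell[6],
                          model$spacegroup, length(model$sym_ops)))
    for (i in seq_along(model$sym_ops)) {
      op <- model$sym_ops[[i]]
      for (r in 1:3) {
        out <- c(out, sprintf(
          "REMARK 290   SMTRY%d %3d%10.6f%10.6f%10.6f%15.5f",
          r, i, op$R[r, 1], op$R[r, 2], op$R[r, 3], op$t[r]))
      }
    }
  }
  nm <- vapply(seq_len(nrow(a)),
               function(i) format_atom_name(a$name[i], a$element[i]), "")
  recs <- sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                  a$record, (seq_len(nrow(a)) - 1) %% 99999 + 1, nm,
                  substr(paste0(a$alt, " "), 1, 1),
                  a$resname, substr(paste0(a$chain, " "), 1, 1),
                  a$resno, substr(paste0(a$insert, " "), 1, 1),
                  a$x, a$y, a$z, a$occ, a$b, a$element)
  writeLines(c(out, recs, "END"), path)
}

write_structure_cif <- function(model, path) {
  a <- model$atoms
  out <- c("data_loopgraft", "#")
  if (!is.null(model$cell)) {
    out <- c(out,
             sprintf("_cell.length_a    %.3f", model$cell[1]),
             sprintf("_cell.length_b    %.3f", model$cell[2]),
             sprintf("_cell.length_c    %.3f", model$cell[3]),
             sprintf("_cell.angle_alpha %.2f", model$cell[4]),
             sprintf("_cell.angle_beta  %.2f", model$cell[5]),
             sprintf("_cell.angle_gamma %.2f", model$cell[6]),
             sprintf("_symmetry.space_group_name_H-M '%s'", model$spacegroup),
             "#")
  }
  out <- c(out, "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.label_atom_id", "_atom_site.label_alt_id",
           "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_seq_id", "_atom_site.pdbx_PDB_ins_code",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.type_symbol")
  dotify <- function(v) ifelse(nzchar(v), v, ".")
  out <- c(out, sprintf("%-6s %5d %-4s %s %-3s %s %4d %s %8.3f %8.3f %8.3f %5.2f %6.2f %s",
                        a$record, seq_len(nrow(a)), a$name, dotify(a$alt),
                        a$resname, dotify(a$chain), a$resno, dotify(a$insert),
                        a$x, a$y, a$z, a$occ, a$b, a$element), "#")
  writeLines(out, path)
}
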