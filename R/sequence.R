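# Construct sequences, case-coded completeness and gap detection.
#
# Sequence convention: the crystallized construct is given one sequence per
# chain; a residue is written uppercase when its backbone (N, CA, C, O) is
# completely modeled at occupancy > 0.01 in at least one alternate
# location, lowercase when it is unmodeled or incomplete.

#' Read construct sequences from FASTA
#'
#' Returns a named character vector of sequences (names from the FASTA
#' headers; the first whitespace-separated token is used). Case is
#' preserved.
#'
#' @param path FASTA file.
#' @export
read_fasta_sequences <- function(path) {
  f <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                          forceDNAtolower = FALSE)
  out <- vapply(f, function(s) as.character(s)[1], "")
  names(out) <- vapply(names(f), function(n) strsplit(n, "\\s+")[[1]][1], "")
  out
}

#' Write (case-coded) sequences to FASTA, 80 columns
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta_sequences <- function(seqs, path) {
  seqinr::write.fasta(lapply(seqs, seqinr::s2c), names = names(seqs),
                      file.out = path, nbchar = 80)
  invisible(path)
}

#' Read SEQRES records from a PDB header as construct fallback
#' @param path PDB file.
#' @return named character vector (chain -> 1-letter sequence), empty if no
#'   SEQRES records are present.
#' @export
read_seqres <- function(path) {
  lines <- grep("^SEQRES", readLines(path, warn = FALSE), value = TRUE)
  if (length(lines) == 0) return(character(0))
  chains <- substr(lines, 12, 12)
  out <- character(0)
  for (ch in unique(chains)) {
    res3 <- unlist(strsplit(trimws(substr(lines[chains == ch], 20, 70)), " +"))
    aa <- aa_3to1[res3]
    aa[is.na(aa)] <- "X"
    out[ch] <- paste(aa, collapse = "")
  }
  out
}

# Map a modeled chain onto a construct sequence by a constant numbering
# offset: construct position = resno - offset. Returns the offset or stops
# with an unmapped-chain error.
chain_construct_offset <- function(model, chain, construct) {
  a <- model$atoms
  a <- a[is_protein_row(a) & a$chain == chain, ]
  if (nrow(a) == 0) stop("chain ", chain, " has no protein atoms")
  res <- dplyr::distinct(a, resno, resname)
  len <- nchar(construct)
  letters1 <- strsplit(construct, "")[[1]]
  for (off in (min(res$resno) - len):(max(res$resno) - 1)) {
    pos <- res$resno - off
    if (any(pos < 1 | pos > len)) next
    if (all(toupper(letters1[pos]) == unname(aa_3to1[res$resname])))
      return(off)
  }
  stop("unmapped chain: chain ", chain,
       " cannot be aligned to the supplied construct without mismatches")
}

# Per-construct-position modeling status for one chain.
# Returns a tibble: pos, aa, present (any atoms), bb_complete, zero_occ
# (full backbone present but all backbone occupancies <= 0.01), alt_bb
# (backbone alternates other than CA), any_alt (any alternate in residue).
chain_residue_status <- function(model, chain, construct, offset = NULL) {
  if (is.null(offset)) offset <- chain_construct_offset(model, chain, construct)
  len <- nchar(construct)
  letters1 <- strsplit(toupper(construct), "")[[1]]
  a <- model$atoms
  a <- a[is_protein_row(a) & a$chain == chain, ]
  a$pos <- a$resno - offset
  a <- a[a$pos >= 1 & a$pos <= len, ]
  st <- tibble::tibble(pos = seq_len(len), aa = letters1,
                       present = FALSE, bb_complete = FALSE,
                       zero_occ = FALSE, alt_bb = FALSE, any_alt = FALSE)
  if (nrow(a) == 0) return(st)
  by_pos <- split(a, a$pos)
  for (p in names(by_pos)) {
    g <- by_pos[[p]]
    i <- as.integer(p)
    st$present[i] <- TRUE
    bb <- g[g$name %in% BACKBONE_NAMES, ]
    have <- vapply(BACKBONE_NAMES,
                   function(nm) any(bb$name == nm & bb$occ > 0.01), TRUE)
    have_any <- vapply(BACKBONE_NAMES, function(nm) any(bb$name == nm), TRUE)
    st$bb_complete[i] <- all(have)
    st$zero_occ[i] <- all(have_any) && all(bb$occ <= 0.01)
    st$alt_bb[i] <- any(nzchar(bb$alt) & bb$name != "CA")
    st$any_alt[i] <- any(nzchar(g$alt))
  }
  st
}

#' Case-coded sequences from a model and its construct
#'
#' Positions whose backbone is completely modeled (N, CA, C, O at
#' occupancy > 0.01 in at least one alternate) are uppercase; unmodeled or
#' backbone-incomplete positions are lowercase.
#'
#' @param model a [structure_model()].
#' @param construct named character vector of construct sequences; names
#'   are chain ids, or a single unnamed sequence if the model has one
#'   protein chain. Sequences may themselves be case-coded; case in the
#'   input is ignored.
#' @return a tibble with one row per (chain, position): `chain`, `pos`
#'   (1-based construct position), `resno` (file numbering), `aa`
#'   (case-coded 1-letter code).
#' @export
extract_case_coded_sequence <- function(model, construct) {
  chains <- unique(model$atoms$chain[is_protein_row(model$atoms)])
  if (is.null(names(construct)) || !any(nzchar(names(construct)))) {
    if (length(chains) == 1 && length(construct) == 1) {
      names(construct) <- chains
    } else stop("construct sequences must be named by chain id")
  }
  out <- list()
  for (ch in chains) {
    cs <- construct_for_chain(construct, ch)
    off <- chain_construct_offset(model, ch, cs)
    st <- chain_residue_status(model, ch, cs, off)
    out[[ch]] <- tibble::tibble(
      chain = ch, pos = st$pos, resno = st$pos + off,
      aa = ifelse(st$bb_complete, st$aa, tolower(st$aa))
    )
  }
  dplyr::bind_rows(out)
}

construct_for_chain <- function(construct, chain) {
  if (chain %in% names(construct)) return(toupper(construct[[chain]]))
  # fall back: a chain maps to a construct whose name it is not listed
  # under only when there is exactly one sequence
  if (length(construct) == 1) return(toupper(construct[[1]]))
  stop("unmapped chain: no construct sequence for chain ", chain)
}

#' Collapse a case-coded sequence tibble to named strings
#' @param seq_tbl output of [extract_case_coded_sequence()].
#' @export
sequence_strings <- function(seq_tbl) {
  sp <- split(seq_tbl, seq_tbl$chain)
  vapply(sp, function(g) paste(g$aa[order(g$pos)], collapse = ""), "")
}

#' Detect unmodeled internal loops
#'
#' One gap per internal run of lowercase (unmodeled or backbone-incomplete)
#' positions of length at most `max_len`, requiring at least five
#' consecutive completely modeled residues on both sides. Runs touching a
#' chain terminus are never reported. Gaps whose ten flanking residues
#' contain main-chain alternates other than C-alpha are flagged `skip`
#' (ambiguous alignment target). Stretches fully modeled at occupancy
#' <= 0.01 get `zero_occupancy_modeled = TRUE` so the existing coordinates
#' can be admitted as an extra candidate. Partially modeled residues at the
#' run edges are flagged so they are replaced together with the loop.
#'
#' @param model a [structure_model()].
#' @param construct named character vector of construct sequences.
#' @param max_len maximum loop length attempted (default 30 residues).
#' @return a `loop_gaps` tibble: chain, first, last (construct positions),
#'   length, seq, first_resno, last_resno, n_anchor_before/after,
#'   zero_occupancy_modeled, partial_edge_before/after, skip, skip_reason.
#' @export
find_missing_loops <- function(model, construct, max_len = 30) {
  chains <- unique(model$atoms$chain[is_protein_row(model$atoms)])
  if (is.null(names(construct)) || !any(nzchar(names(construct)))) {
    if (length(chains) == 1 && length(construct) == 1)
      names(construct) <- chains
  }
  gaps <- list()
  for (ch in chains) {
    cs <- construct_for_chain(construct, ch)
    off <- chain_construct_offset(model, ch, cs)
    st <- chain_residue_status(model, ch, cs, off)
    len <- nrow(st)
    r <- rle(!st$bb_complete)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      i1 <- starts[k]; i2 <- ends[k]
      if (i1 == 1 || i2 == len) next                  # terminus, not a loop
      if (i2 - i1 + 1 > max_len) next
      n_before <- run_length_true(rev(st$bb_complete[seq_len(i1 - 1)]))
      n_after <- run_length_true(st$bb_complete[(i2 + 1):len])
      if (n_before < 5 || n_after < 5) next
      flank <- c(max(1, i1 - 5):(i1 - 1), (i2 + 1):min(len, i2 + 5))
      skip <- any(st$alt_bb[flank])
      gaps[[length(gaps) + 1]] <- tibble::tibble(
        chain = ch,
        first = i1, last = i2, length = i2 - i1 + 1,
        seq = substr(paste(st$aa, collapse = ""), i1, i2),
        first_resno = i1 + off, last_resno = i2 + off,
        offset = off,
        n_anchor_before = n_before, n_anchor_after = n_after,
        zero_occupancy_modeled = all(st$zero_occ[i1:i2]),
        partial_edge_before = st$present[i1] && !st$zero_occ[i1],
        partial_edge_after = st$present[i2] && !st$zero_occ[i2],
        skip = skip,
        skip_reason = if (skip) "ambiguous_alternates" else ""
      )
    }
  }
  out <- if (length(gaps) == 0) empty_gap_table() else dplyr::bind_rows(gaps)
  class(out) <- c("loop_gaps", class(out))
  out
}

run_length_true <- function(v) {
  if (length(v) == 0 || !v[1]) return(0L)
  r <- rle(v)
  r$lengths[1]
}

empty_gap_table <- function() {
  tibble::tibble(chain = character(0), first = integer(0), last = integer(0),
                 length = integer(0), seq = character(0),
                 first_resno = integer(0), last_resno = integer(0),
                 offset = integer(0),
                 n_anchor_before = integer(0), n_anchor_after = integer(0),
                 zero_occupancy_modeled = logical(0),
                 partial_edge_before = logical(0),
                 partial_edge_after = logical(0),
                 skip = logical(0), skip_reason = character(0))
}
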