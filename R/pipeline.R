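# Orchestration of the full loop-building flow: per-chain density
# pre-check, per-gap candidate generation, clash adjudication, dedup and
# ranking, junction closing + restrained real-space refinement, geometry
# and Ramachandran filters, density-ratio acceptance, final RSCC check,
# and report assembly.

#' Pipeline configuration
#'
#' All thresholds of the loop-building procedure with their defaults.
#'
#' @param max_loop_len maximum loop length attempted (residues).
#' @param align_rmsd_max anchor-alignment backbone RMSD cutoff (angstrom).
#' @param identity_min loop/anchor sequence identity floor (percent).
#' @param chain_identity_min whole-chain homolog eligibility floor (percent).
#' @param clash_heavy,clash_small clash severity cutoffs (angstrom).
#' @param dedup_rmsd candidate conformational dedup threshold (angstrom).
#' @param top_n candidates refined per gap.
#' @param max_rmsz_bond,max_rmsz_angle,max_rmsz_chir,max_rmsz_plane,max_rmsz_torsion
#'   geometry RMSZ gates.
#' @param max_omega_dev omega distortion threshold (degrees).
#' @param rama_poor_z Ramachandran Z below which the Grubbs comparison is
#'   invoked.
#' @param grubbs_k outlier multiple of the Grubbs comparison.
#' @param density_ratio_min loop/control density-ratio acceptance floor.
#' @param control_min_atoms control-set size below which the fallback set
#'   (all non-loop main-chain atoms) is used.
#' @param rscc_chain_min per-chain RSCC below which no building is
#'   attempted in that chain.
#' @param rscc_final_min per-loop RSCC below which a built loop is
#'   discarded and its deletions restored.
#' @param rscc_radius mask radius for RSCC (angstrom).
#' @param calc_b_blur smearing B for model-calculated maps (angstrom^2).
#' @param w_geom,w_map,w_rama refinement energy weights.
#' @param max_iter,tol refinement iteration cap and gradient tolerance.
#' @param exception_ligands deletable compound codes.
#' @return a named list of class `loopgraft_config`.
#' @export
loopgraft_config <- function(max_loop_len = 30, align_rmsd_max = 2.0,
                             identity_min = 50, chain_identity_min = 70,
                             clash_heavy = 2.1, clash_small = 2.6,
                             dedup_rmsd = 0.1, top_n = 10,
                             max_rmsz_bond = 1.2, max_rmsz_angle = 1.2,
                             max_rmsz_chir = 1.5, max_rmsz_plane = 2.0,
                             max_rmsz_torsion = 2.0, max_omega_dev = 30,
                             rama_poor_z = -5, grubbs_k = 2,
                             density_ratio_min = 0.25,
                             control_min_atoms = 30,
                             rscc_chain_min = 0.80, rscc_final_min = 0.60,
                             rscc_radius = 2.0, calc_b_blur = 15,
                             w_geom = 1, w_map = 3, w_rama = 0.05,
                             max_iter = 1500, tol = 1e-3,
                             exception_ligands = EXCEPTION_LIGAND_CODES) {
  structure(as.list(environment()), class = "loopgraft_config")
}

#' Read a configuration from a YAML file
#' @param path YAML file whose keys match [loopgraft_config()] arguments.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(loopgraft_config, vals[names(vals) %in%
                                   names(formals(loopgraft_config))])
}

# construct positions modeled (complete backbone) in every homolog, per
# target chain: the density-ratio control set
always_ordered_positions <- function(model, construct, homologs) {
  out <- list()
  for (ch in unique(model$atoms$chain[is_protein_row(model$atoms)])) {
    cs <- tryCatch(construct_for_chain(construct, ch),
                   error = function(e) NULL)
    if (is.null(cs)) next
    off <- chain_construct_offset(model, ch, cs)
    tseq <- toupper(cs)
    npos <- nchar(tseq)
    ordered <- rep(TRUE, npos)
    any_h <- FALSE
    for (hm in homologs) {
      for (hch in unique(hm$atoms$chain[is_protein_row(hm$atoms)])) {
        ms <- modeled_sequence(hm, hch)
        pairing <- align_homolog_sequence(tseq, ms$seq)
        if (100 * mean(pairing$match) < 50) next
        any_h <- TRUE
        st <- vapply(seq_len(npos), function(p) {
          hp <- pairing$hpos[match(p, pairing$tpos)]
          if (is.na(hp)) return(FALSE)
          rn <- ms$resno[hp]
          g <- hm$atoms[hm$atoms$chain == hch & hm$atoms$resno == rn &
                          hm$atoms$name %in% BACKBONE_NAMES &
                          hm$atoms$occ > 0.01, ]
          all(BACKBONE_NAMES %in% g$name)
        }, TRUE)
        ordered <- ordered & st
      }
    }
    if (!any_h) next
    pos <- which(ordered)
    if (length(pos) > 0)
      out[[ch]] <- tibble::tibble(chain = ch, pos = pos, resno = pos + off)
  }
  if (length(out) == 0)
    return(tibble::tibble(chain = character(0), pos = integer(0),
                          resno = integer(0)))
  dplyr::bind_rows(out)
}

#' Run the homology loop-building pipeline
#'
#' Detects gaps, generates grafted candidates from the homologs (plus the
#' promoted zero-occupancy loop where applicable), adjudicates clashes
#' (including symmetry copies), deduplicates and ranks, refines the top
#' candidates in real space after closing junction gaps, applies the
#' geometry, Ramachandran and density-ratio filters, selects the
#' candidate with the best loop density, and finally discards built loops
#' whose RSCC against the map falls below the cutoff, restoring any
#' deletions.
#'
#' @param model target [structure_model()].
#' @param construct named construct sequences (required: loop building is
#'   refused without a sequence source).
#' @param homologs list of homolog [structure_model()]s.
#' @param map a [map_grid()] (observed density).
#' @param config a [loopgraft_config()].
#' @return list: `model` (updated), `report` (a `loop_run_report`).
#' @export
build_missing_loops <- function(model, construct, homologs, map,
                          config = loopgraft_config()) {
  if (is.null(construct) || length(construct) == 0)
    stop("loop building refused: a construct sequence source is required")
  work <- model
  chain_rows <- list(); gap_rows <- list(); cand_rows <- list()
  deletions_applied <- list(); restored <- 0L
  side_chain_report <- list()

  # per-chain density pre-check: RSCC of the chain against a calc map
  # synthesized from the chain itself
  chain_ok <- list()
  for (ch in unique(work$atoms$chain[is_protein_row(work$atoms)])) {
    ca <- work$atoms[is_protein_row(work$atoms) & work$atoms$chain == ch, ]
    chain_model <- structure_model(ca, cell = work$cell,
                                   sym_ops = work$sym_ops,
                                   spacegroup = work$spacegroup)
    calc <- synthesize_map(chain_model, b_blur = config$calc_b_blur,
                           cell = map$cell, dim = map$dim)
    r <- tryCatch(rscc(ca, map, calc, radius = config$rscc_radius),
                  error = function(e) tibble::tibble(rscc = NA_real_,
                                                     rsr = NA_real_))
    ok <- !is.na(r$rscc[1]) && r$rscc[1] >= config$rscc_chain_min
    chain_ok[[ch]] <- ok
    chain_rows[[ch]] <- tibble::tibble(chain = ch, rscc = r$rscc[1],
                                       attempted = ok)
    if (!ok)
      warning("chain ", ch, " RSCC ", sprintf("%.2f", r$rscc[1]),
              " below ", config$rscc_chain_min,
              ": chain conformation unreliable, no loops attempted")
  }

  control_pos <- always_ordered_positions(work, construct, homologs)

  gaps <- find_missing_loops(work, construct, max_len = config$max_loop_len)
  for (gi in seq_len(nrow(gaps))) {
    gap <- gaps[gi, ]
    gap_id <- sprintf("%s:%d-%d", gap$chain, gap$first, gap$last)
    if (!isTRUE(chain_ok[[gap$chain]])) {
      gap_rows[[gap_id]] <- gap_status(gap, "chain_rscc_low")
      next
    }
    if (gap$skip) {
      gap_rows[[gap_id]] <- gap_status(gap, gap$skip_reason)
      next
    }
    res <- build_one_gap(work, gap, construct, homologs, map,
                         control_pos, config)
    for (cr in res$cand_rows) cand_rows[[length(cand_rows) + 1]] <- cr
    if (!is.null(res$model)) {
      work <- res$model
      deletions_applied[[gap_id]] <- res$deletions
      side_chain_report[[gap_id]] <- res$incomplete_side_chains
      gap_rows[[gap_id]] <- gap_status(gap, "built", res$fit,
                                       res$chosen_source)
    } else {
      restored <- restored + res$restored
      gap_rows[[gap_id]] <- gap_status(gap, res$status)
    }
  }

  gaps_tbl <- if (length(gap_rows) == 0)
    tibble::tibble(chain = character(0), first = integer(0),
                   last = integer(0), length = integer(0),
                   status = character(0), chosen = character(0),
                   loop_mean = numeric(0), ratio = numeric(0))
  else dplyr::bind_rows(gap_rows)
  report <- structure(list(
    chains = dplyr::bind_rows(chain_rows),
    gaps = gaps_tbl,
    candidates = if (length(cand_rows) == 0) tibble::tibble()
    else dplyr::bind_rows(cand_rows),
    n_gaps = nrow(gaps),
    n_built = sum(gaps_tbl$status == "built"),
    deletions = deletions_applied,
    restored_deletions = restored,
    incomplete_side_chains = unique(unlist(side_chain_report))
  ), class = "loop_run_report")
  list(model = work, report = report)
}

gap_status <- function(gap, status, fit = NULL, chosen = "") {
  tibble::tibble(chain = gap$chain, first = gap$first, last = gap$last,
                 length = gap$length, status = status, chosen = chosen,
                 loop_mean = if (is.null(fit)) NA_real_ else fit$loop_mean,
                 ratio = if (is.null(fit)) NA_real_ else fit$ratio)
}

# process a single gap; returns either an updated model (built) or a
# status describing why nothing was built
build_one_gap <- function(model, gap, construct, homologs, map,
                          control_pos, config) {
  cand_rows <- list()
  log_cand <- function(cand, stage, verdict) {
    cand_rows[[length(cand_rows) + 1]] <<- tibble::tibble(
      gap = sprintf("%s:%d-%d", gap$chain, gap$first, gap$last),
      source = if (is.null(cand$source)) "zero_occupancy"
      else sprintf("homolog_%d%s", cand$source$homolog,
                   if (nzchar(cand$source$alt))
                     paste0(".", cand$source$alt) else ""),
      align_rmsd = cand$align_rmsd, stage = stage, verdict = verdict)
  }

  sources <- collect_sources(gap, construct, homologs,
                             identity_min = config$identity_min,
                             chain_identity_min = config$chain_identity_min)
  cands <- list()
  for (src in sources) {
    hm <- homologs[[src$homolog]]
    tr <- tryCatch(align_source(model, gap, src, hm),
                   error = function(e) NULL)
    if (is.null(tr)) next
    if (tr$rmsd >= config$align_rmsd_max) {
      log_cand(list(source = src, align_rmsd = tr$rmsd),
               "alignment", "reject:align_rmsd")
      next
    }
    cand <- tryCatch(graft_loop(model, gap, src, hm, tr, construct),
                     error = function(e) NULL)
    if (is.null(cand)) next
    cands[[length(cands) + 1]] <- cand
  }
  if (isTRUE(gap$zero_occupancy_modeled))
    cands[[length(cands) + 1]] <- zero_occupancy_candidate(model, gap)
  if (length(cands) == 0)
    return(list(model = NULL, status = "no_candidates", restored = 0L,
                cand_rows = cand_rows))

  # residues excluded from clash search: the replaced span plus the two
  # covalently connected edge residues (their junction bonds to the loop
  # would otherwise register as contacts)
  span_keys <- paste(gap$chain,
                     ((gap$first - 2):(gap$last + 2)) + gap$offset, "")

  # pre-refinement clash adjudication
  survivors <- list()
  for (cand in cands) {
    reports <- find_clashes(cand, model, exclude_keys = span_keys,
                            heavy = config$clash_heavy,
                            small = config$clash_small,
                            exception_ligands = config$exception_ligands)
    dec <- adjudicate(reports, model)
    if (dec$verdict == "discard_candidate") {
      log_cand(cand, "clash", paste0("reject:", dec$reason))
      next
    }
    if (length(dec$crop_loop_resno) > 0) {
      keep <- !(cand$atoms$resno %in% dec$crop_loop_resno) |
        cand$atoms$name %in% MAINCHAIN_CLASH_NAMES
      cand$atoms <- cand$atoms[keep, ]
    }
    cand$deletions <- dec$delete_model_rows
    survivors[[length(survivors) + 1]] <- cand
  }
  if (length(survivors) == 0)
    return(list(model = NULL, status = "clash_discard", restored = 0L,
                cand_rows = cand_rows))

  ranked <- dedup_and_rank(survivors, top_n = config$top_n,
                           dedup_rmsd = config$dedup_rmsd)

  # refine each candidate, then filter
  evaluated <- list()
  for (cand in ranked) {
    r <- refine_candidate(cand, model, gap, map, config)
    cand$atoms <- r$atoms
    cand$scores <- r$scores
    cand$converged <- r$converged
    cand$extra_atoms <- r$extra_atoms
    # post-refinement clash re-check (the loop may have been pulled into
    # the density of other moieties)
    reports <- find_clashes(cand, model, exclude_keys = span_keys,
                            exclude_atoms = cand$deletions,
                            heavy = config$clash_heavy,
                            small = config$clash_small,
                            exception_ligands = config$exception_ligands)
    dec <- adjudicate(reports, model)
    if (dec$verdict == "discard_candidate") {
      log_cand(cand, "post_refine_clash", paste0("reject:", dec$reason))
      next
    }
    cand$deletions <- sort(unique(c(cand$deletions, dec$delete_model_rows)))
    src_cis <- if (is.null(cand$source)) cand$own_cis else cand$source$cis_flags
    gf <- geometry_filter(cand$scores, converged = cand$converged,
                          source_cis = src_cis,
                          max_rmsz_bond = config$max_rmsz_bond,
                          max_rmsz_angle = config$max_rmsz_angle,
                          max_rmsz_chir = config$max_rmsz_chir,
                          max_rmsz_plane = config$max_rmsz_plane,
                          max_rmsz_torsion = config$max_rmsz_torsion,
                          max_omega_dev = config$max_omega_dev)
    if (!gf$accept) {
      log_cand(cand, "geometry", paste0("reject:bad-geometry:",
                                        paste(gf$reasons, collapse = "+")))
      next
    }
    cand$rama <- tryCatch(rama_z(cand$atoms)$z, error = function(e) NA_real_)
    evaluated[[length(evaluated) + 1]] <- cand
  }
  if (length(evaluated) == 0)
    return(list(model = NULL, status = "bad_geometry", restored = 0L,
                cand_rows = cand_rows))

  # Ramachandran outlier veto against peers and the source loops
  peer_zs <- vapply(evaluated, function(c) c$rama, 1)
  source_zs <- vapply(evaluated, function(c)
    if (is.null(c$source)) NA_real_ else c$source$source_rama_z, 1)
  kept <- list()
  for (i in seq_along(evaluated)) {
    rf <- rama_outlier_filter(peer_zs[i], peer_zs[-i],
                              source_zs[!is.na(source_zs)],
                              poor_z = config$rama_poor_z,
                              k = config$grubbs_k)
    if (!rf$accept) {
      log_cand(evaluated[[i]], "rama", paste0("reject:", rf$reason))
      next
    }
    kept[[length(kept) + 1]] <- evaluated[[i]]
  }
  if (length(kept) == 0)
    return(list(model = NULL, status = "bad_geometry", restored = 0L,
                cand_rows = cand_rows))

  # density-ratio acceptance; select the best loop density among survivors
  best <- NULL
  for (cand in kept) {
    fit <- density_ratio(cand, model, control_pos, map,
                         min_ratio = config$density_ratio_min)
    cand$fit <- fit
    if (!fit$acceptable) {
      log_cand(cand, "density", "reject:insufficient-density")
      next
    }
    log_cand(cand, "density", "accept")
    if (is.null(best) || fit$loop_mean > best$fit$loop_mean) best <- cand
  }
  if (is.null(best))
    return(list(model = NULL, status = "insufficient_density",
                restored = 0L, cand_rows = cand_rows))

  # apply the graft to a working copy
  new_model <- apply_candidate(model, gap, best)

  # final per-loop RSCC check against the observed map
  calc <- synthesize_map(new_model, b_blur = config$calc_b_blur,
                         cell = map$cell, dim = map$dim)
  r <- tryCatch(rscc(best$atoms, map, calc, radius = config$rscc_radius),
                error = function(e) tibble::tibble(rscc = NA_real_))
  if (is.na(r$rscc[1]) || r$rscc[1] < config$rscc_final_min) {
    log_cand(best, "final_rscc", "reject:insufficient-density")
    # the working copy is dropped; deletions restored implicitly
    return(list(model = NULL, status = "insufficient_density",
                restored = length(best$deletions), cand_rows = cand_rows))
  }
  log_cand(best, "final_rscc", "built")
  incomplete <- incomplete_side_chain_list(best)
  list(model = new_model, status = "built", fit = best$fit,
       chosen_source = if (is.null(best$source)) "zero_occupancy"
       else sprintf("homolog_%d", best$source$homolog),
       deletions = best$deletions, restored = 0L,
       incomplete_side_chains = incomplete, cand_rows = cand_rows)
}

# refinement of one candidate: region = candidate + one existing residue
# per side (refined too); the next residue out is a fixed boundary
refine_candidate <- function(cand, model, gap, map, config) {
  span <- graft_span(gap)
  extra_pos <- c(min(span) - 1, max(span) + 1) + gap$offset
  static_pos <- c(min(span) - 2, max(span) + 2) + gap$offset
  ma <- model$atoms
  sel <- is_protein_row(ma) & ma$chain == gap$chain
  extra <- ma[sel & ma$resno %in% extra_pos, ]
  first_alt <- sort(unique(extra$alt[nzchar(extra$alt)]))[1]
  extra <- extra[extra$alt %in% c("", first_alt), ]
  extra$alt <- ""
  extra <- extra[!duplicated(paste(extra$resno, extra$name)), ]
  static <- ma[sel & ma$resno %in% static_pos, ]
  static <- static[static$name %in% BACKBONE_NAMES, ]
  static <- static[!duplicated(paste(static$resno, static$name)), ]

  region <- dplyr::bind_rows(cand$atoms, extra)
  region <- close_gap_pregame(region)
  rr <- rsr_minimize(region, map, static_atoms = static,
                     w_geom = config$w_geom, w_map = config$w_map,
                     w_rama = config$w_rama, max_iter = config$max_iter,
                     tol = config$tol)
  loop_resnos <- unique(cand$atoms$resno)
  out_loop <- rr$atoms[rr$atoms$resno %in% loop_resnos, ]
  out_extra <- rr$atoms[!(rr$atoms$resno %in% loop_resnos), ]
  list(atoms = out_loop, extra_atoms = out_extra,
       converged = rr$converged, scores = rr$scores)
}

# install an accepted candidate into the model: delete the replaced span
# and adjudicated deletions, insert the refined loop + moved edge residues
apply_candidate <- function(model, gap, cand) {
  a <- model$atoms
  drop_rows <- integer(0)
  span_keys <- paste(gap$chain, graft_span(gap) + gap$offset, "")
  drop_rows <- c(drop_rows, which(residue_key(a) %in% span_keys &
                                    is_protein_row(a)))
  drop_rows <- c(drop_rows, cand$deletions)
  # the refined edge residues replace their existing counterparts
  if (!is.null(cand$extra_atoms) && nrow(cand$extra_atoms) > 0) {
    ek <- unique(paste(gap$chain, cand$extra_atoms$resno, ""))
    drop_rows <- c(drop_rows, which(residue_key(a) %in% ek &
                                      is_protein_row(a)))
  }
  drop_rows <- sort(unique(drop_rows))
  if (length(drop_rows) > 0) a <- a[-drop_rows, ]
  a <- dplyr::bind_rows(a, cand$atoms, cand$extra_atoms)
  a <- a[order(match(a$chain, unique(a$chain)), a$record == "HETATM",
               a$resno), ]
  a$eleno <- seq_len(nrow(a))
  model$atoms <- a
  model
}

incomplete_side_chain_list <- function(cand) {
  full_names <- function(resname) {
    t <- sidechain_template(resname)
    if (is.null(t)) character(0) else t$name
  }
  out <- character(0)
  for (rn in unique(cand$atoms$resno)) {
    g <- cand$atoms[cand$atoms$resno == rn, ]
    need <- full_names(g$resname[1])
    if (!all(need %in% g$name))
      out <- c(out, sprintf("%s %s %d", g$resname[1], g$chain[1], rn))
  }
  out
}

#' Write the pipeline outputs
#'
#' Writes the updated model (PDB, and mmCIF if requested), the updated
#' case-coded FASTA, the JSON run report and a per-loop summary table.
#'
#' @param model updated [structure_model()].
#' @param report a `loop_run_report`.
#' @param construct named construct sequences.
#' @param dir output directory.
#' @param cif also write an mmCIF copy.
#' @return named vector of written paths, invisibly.
#' @export
finalize_outputs <- function(model, report, construct, dir, cif = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(model = file.path(dir, "model_out.pdb"),
             fasta = file.path(dir, "sequence_out.fasta"),
             report = file.path(dir, "report.json"),
             summary = file.path(dir, "loops.tsv"))
  write_structure(model, paths[["model"]])
  if (cif) {
    paths[["cif"]] <- file.path(dir, "model_out.cif")
    write_structure(model, paths[["cif"]])
  }
  seqs <- sequence_strings(extract_case_coded_sequence(model, construct))
  write_fasta_sequences(seqs, paths[["fasta"]])
  jsonlite::write_json(list(
    chains = report$chains, gaps = report$gaps,
    candidates = report$candidates,
    n_gaps = report$n_gaps, n_built = report$n_built,
    restored_deletions = report$restored_deletions,
    incomplete_side_chains = report$incomplete_side_chains
  ), paths[["report"]], dataframe = "rows", auto_unbox = TRUE, digits = NA)
  utils::write.table(report$gaps, paths[["summary"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' @export
print.loop_run_report <- function(x, ...) {
  cat(sprintf("<loop_run_report> %d gap(s): %d built, %d not built\n",
              x$n_gaps, x$n_built, x$n_gaps - x$n_built))
  if (nrow(x$gaps) > 0) print(x$gaps[, c("chain", "first", "last",
                                         "length", "status", "ratio")])
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-gap outcomes of a run
#' @param x a `loop_run_report`.
#' @param ... unused.
#' @method tidy loop_run_report
#' @export
tidy.loop_run_report <- function(x, ...) x$gaps

#' One-row summary of a run
#' @param x a `loop_run_report`.
#' @param ... unused.
#' @method glance loop_run_report
#' @export
glance.loop_run_report <- function(x, ...) {
  tibble::tibble(
    n_gaps = x$n_gaps, n_built = x$n_built,
    n_rejected = sum(!x$gaps$status %in% c("built", "no_candidates")),
    n_no_candidates = sum(x$gaps$status == "no_candidates"),
    n_deleted_atoms = length(unlist(x$deletions)),
    restored_deletions = x$restored_deletions
  )
}

#' Filter-funnel plot of a run report
#'
#' Bar chart of per-gap outcomes (built / rejection category), the same
#' funnel view used to summarize large-scale runs.
#'
#' @param object a `loop_run_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot loop_run_report
#' @export
autoplot.loop_run_report <- function(object, ...) {
  d <- dplyr::count(object$gaps, .data$status)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$status, -.data$n),
                                  y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "gaps",
                  title = "Loop building outcomes") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Ramachandran plot of a model or fragment
#'
#' @param x a [structure_model()] or atom tibble.
#' @return a ggplot object with the scored phi/psi pairs over the general
#'   reference density.
#' @export
plot_ramachandran <- function(x) {
  rz <- rama_z(x)
  ref <- rama_reference("general")
  bg <- expand.grid(phi = ref$centers, psi = ref$centers)
  bg$logp <- as.numeric(ref$logp)
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = bg,
                         ggplot2::aes(x = .data$phi, y = .data$psi,
                                      fill = .data$logp)) +
    ggplot2::scale_fill_viridis_c(option = "mako") +
    ggplot2::geom_point(data = rz$per_residue,
                        ggplot2::aes(x = .data$phi, y = .data$psi),
                        color = "orange", size = 1.5) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Ramachandran Z = %.2f", rz$z),
                  x = "phi (deg)", y = "psi (deg)") +
    ggplot2::theme_minimal()
}
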