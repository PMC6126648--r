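# Shared fixture helpers. Recovery fixtures use all-helix ground truths
# with modest side chains: a continuous ideal helix cannot fold back onto
# itself, so the ground truth is free of internal steric clashes, and the
# "loop" here is simply an unmodeled stretch (the broad sense: any missing
# internal region regardless of conformation).

TAME_AA <- c("A", "D", "E", "K", "L", "N", "Q", "S", "T", "V", "M", "G")

random_tame_sequence <- function(n, first = "A") {
  paste(c(first, sample(TAME_AA, n - 1, replace = TRUE)), collapse = "")
}

helix_fixture_spec <- function(n = 32, gap_start = 14, gap_len = 4,
                               seed = 1, ...) {
  # sequence drawn under the fixture's own seed for reproducibility
  seq <- withr::with_seed(seed, random_tame_sequence(n))
  fixture_spec(sequence = seq, plan = strrep("H", n),
               gap_start = gap_start, gap_len = gap_len, seed = seed, ...)
}

# independent Kabsch/SVD superposition oracle
kabsch_rmsd <- function(fixed, moving) {
  cf <- colMeans(fixed); cm <- colMeans(moving)
  h <- t(sweep(moving, 2, cm)) %*% sweep(fixed, 2, cf)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cf - as.numeric(rot %*% cm)
  moved <- sweep(moving %*% t(rot), 2, tr, "+")
  sqrt(mean(rowSums((moved - fixed)^2)))
}

# backbone RMSD of a residue range between two models (atom-order safe)
range_backbone_rmsd <- function(m1, m2, resnos) {
  sel <- function(m) {
    a <- m$atoms[m$atoms$resno %in% resnos &
                   m$atoms$name %in% c("N", "CA", "C", "O"), ]
    a[order(a$resno, match(a$name, c("N", "CA", "C", "O"))), ]
  }
  a1 <- sel(m1); a2 <- sel(m2)
  stopifnot(nrow(a1) == nrow(a2))
  sqrt(mean(rowSums((coords(a1) - coords(a2))^2)))
}

# a minimal atom tibble row
atom_row <- function(name, x, y, z, resname = "ALA", chain = "A",
                     resno = 1L, occ = 1, b = 20, record = "ATOM",
                     element = NULL, alt = "") {
  if (is.null(element)) element <- substr(name, 1, 1)
  tibble::tibble(record = record, eleno = 0L, name = name, alt = alt,
                 resname = resname, chain = chain, resno = as.integer(resno),
                 insert = "", x = x, y = y, z = z, occ = occ, b = b,
                 element = element)
}

# analytic +1 sigma bond construction lives in the package
build_sigma_inflated_fragment <- function(n = 6, seed = 1)
  loopgraft:::build_sigma_inflated_fragment(n)
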