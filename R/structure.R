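# ARM-domain conformational comparison: coordinate loading (via bio3d),
# residue pairing, Kabsch superposition with iterative outlier rejection,
# and heavy-atom polar-contact enumeration.

read_structure <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("File not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  # bio3d warns about absent header records (helix/sheet) on minimal files;
  # rm.alt = FALSE keeps all alternate locations so occupancy-based
  # resolution happens here, not in the reader
  if (ext %in% c("cif", "mmcif"))
    suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE))
  else suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE))
}

# altloc resolution: keep highest occupancy, ties broken alphabetically
# (so 'A' wins), applied per (chain, resno, atom name)
resolve_altloc <- function(atoms) {
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  ord <- order(key, -atoms$o, atoms$alt)
  atoms <- atoms[ord, ]
  key <- key[ord]
  atoms[!duplicated(key), ]
}

#' Load ordered C-alpha coordinates from a PDB or mmCIF file
#'
#' Reads a coordinate file (format inferred from the extension), selects one
#' chain and optionally an author-numbered residue interval, resolves
#' alternate locations to the highest-occupancy conformer (ties to 'A'), and
#' returns the C-alpha trace in file order. Author numbering is
#' authoritative throughout.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file.
#' @param chain Chain identifier (single string).
#' @param range Optional `c(first, last)` author residue interval.
#' @return A tibble of class `coord_set` with columns `chain`, `resno`,
#'   `resid`, `x`, `y`, `z` and attribute `source` (the file path).
#' @export
load_calpha <- function(path, chain, range = NULL) {
  pdb <- read_structure(path)
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM") & at$elety == "CA" &
             !(at$resid %in% c("CA")), ] # exclude calcium ions named CA/CA
  if (!chain %in% unique(at$chain))
    abort_config(sprintf("Chain '%s' not present in %s (chains: %s).",
                         chain, basename(path),
                         paste(unique(at$chain), collapse = ", ")))
  at <- at[at$chain == chain, ]
  at <- resolve_altloc(at)
  if (!is.null(range)) {
    if (length(range) != 2L || range[1] > range[2])
      abort_domain("`range` must be c(first, last) with first <= last.")
    at <- at[at$resno >= range[1] & at$resno <= range[2], ]
  }
  if (nrow(at) < 3L)
    abort_config("Fewer than 3 C-alpha records selected.")
  at <- at[order(at$resno), ]
  out <- tibble::tibble(chain = at$chain, resno = at$resno,
                        resid = at$resid, x = at$x, y = at$y, z = at$z)
  attr(out, "source") <- path
  class(out) <- c("coord_set", class(out))
  out
}

#' Load all-atom records for contact analysis
#'
#' @inheritParams load_calpha
#' @param chain Optional chain filter; `NULL` keeps all chains.
#' @param hetero If `TRUE` return only HETATM records (ligands, waters);
#'   if `FALSE` (default) only polymer ATOM records.
#' @param resid Optional residue-name filter (e.g. the ligand code).
#' @return Tibble with columns `chain`, `resno`, `resid`, `elety`,
#'   `element`, `x`, `y`, `z`.
#' @export
load_atoms <- function(path, chain = NULL, hetero = FALSE, resid = NULL) {
  pdb <- read_structure(path)
  at <- pdb$atom
  at <- at[at$type == if (hetero) "HETATM" else "ATOM", ]
  if (!is.null(chain)) at <- at[at$chain %in% chain, ]
  if (!is.null(resid)) at <- at[at$resid %in% resid, ]
  if (!nrow(at)) abort_config("No atoms match the selection.")
  at <- resolve_altloc(at)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(at$elety), 1, 1)
  tibble::tibble(chain = at$chain, resno = at$resno, resid = at$resid,
                 elety = at$elety, element = toupper(trimws(elem)),
                 x = at$x, y = at$y, z = at$z)
}

coords_matrix <- function(cs) as.matrix(cs[, c("x", "y", "z")])

aa_three_to_one <- function(resid) {
  one <- bio3d::aa321(resid)
  one[is.na(one) | one == ""] <- "X"
  one
}

#' Pair residues between two C-alpha sets
#'
#' Pairs by the intersection of author residue numbers. If fewer than 90%
#' of residue names agree on that intersection (e.g. structures from
#' different species with unrelated numbering), falls back to a global
#' sequence alignment of the one-letter sequences and pairs aligned,
#' non-gapped positions.
#'
#' @param a,b `coord_set` objects (one chain each).
#' @return Tibble with columns `idx_a`, `idx_b` (row indices into `a` and
#'   `b`) and `resno_a`, `resno_b`.
#' @export
pair_residues <- function(a, b) {
  stopifnot(inherits(a, "coord_set"), inherits(b, "coord_set"))
  common <- intersect(a$resno, b$resno)
  ia <- match(common, a$resno)
  ib <- match(common, b$resno)
  use_alignment <- FALSE
  if (length(common) >= 3L) {
    ident <- mean(a$resid[ia] == b$resid[ib])
    if (ident < 0.9) use_alignment <- TRUE
  } else use_alignment <- TRUE

  if (use_alignment) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      abort_config("Sequence-alignment fallback requires the Biostrings package.")
    sa <- paste(aa_three_to_one(a$resid), collapse = "")
    sb <- paste(aa_three_to_one(b$resid), collapse = "")
    al <- Biostrings::pairwiseAlignment(sa, sb, type = "global",
                                        gapOpening = 10, gapExtension = 0.5)
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    ps <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    ia <- ib <- integer(0)
    ca <- cb <- 0L
    for (k in seq_along(pa)) {
      if (pa[k] != "-") ca <- ca + 1L
      if (ps[k] != "-") cb <- cb + 1L
      if (pa[k] != "-" && ps[k] != "-") {
        ia <- c(ia, ca); ib <- c(ib, cb)
      }
    }
  }
  if (length(ia) < 3L)
    abort_domain("Fewer than 3 residue pairs; cannot superpose.")
  tibble::tibble(idx_a = ia, idx_b = ib,
                 resno_a = a$resno[ia], resno_b = b$resno[ib])
}

# Closed-form optimal rotation (Kabsch): returns the proper rotation R and
# translation t minimising ||(P %*% t(R) + t) - Q|| over rigid motions,
# mapping mobile P onto reference Q (n x 3 matrices).
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cq - as.vector(R %*% cp)
  dev <- sqrt(rowSums((Pc %*% t(R) - Qc)^2))
  list(rotation = R, translation = t_vec,
       rmsd = sqrt(mean(dev^2)), deviations = dev)
}

#' Optimal rigid-body superposition with iterative outlier rejection
#'
#' Superposes the mobile set `b` onto the reference `a` over residue pairs
#' from [pair_residues()], using the closed-form SVD (Kabsch) rotation with
#' proper-rotation correction. Optionally, outlier pairs are then rejected
#' iteratively: in each cycle, pairs deviating by more than
#' `reject_sigma` times the current RMSD are dropped and the superposition
#' is recomputed, until a fixed point or the cycle limit. This mimics the
#' trimmed-RMSD convention of common structure viewers, where the reported
#' atom count is below the full common length.
#'
#' @param a Reference `coord_set`.
#' @param b Mobile `coord_set`.
#' @param reject_cycles Maximum rejection cycles (0 disables rejection).
#' @param reject_sigma Rejection threshold in multiples of the current RMSD.
#' @return An object of class `superposition`: `rotation` (3x3 proper
#'   orthogonal), `translation` (length-3, Å), `rmsd` (Å), `paired_count`
#'   (pairs retained), `initial_pairs`, `cycles_used`, and the retained
#'   pair table.
#' @examples
#' # a structure superposed on itself is exact
#' @export
superpose <- function(a, b, reject_cycles = 5, reject_sigma = 2.0) {
  pairs <- pair_residues(a, b)
  Q <- coords_matrix(a)[pairs$idx_a, , drop = FALSE]
  P <- coords_matrix(b)[pairs$idx_b, , drop = FALSE]
  keep <- seq_len(nrow(pairs))
  fit <- kabsch(P, Q)
  cycles <- 0L
  if (reject_cycles > 0) {
    for (cyc in seq_len(reject_cycles)) {
      cutoff <- reject_sigma * fit$rmsd
      ok <- fit$deviations <= cutoff | fit$rmsd == 0
      if (all(ok)) break
      if (sum(ok) < 3L)
        abort_fit("Outlier rejection left fewer than 3 pairs.")
      keep <- keep[ok]
      fit <- kabsch(P[keep, , drop = FALSE], Q[keep, , drop = FALSE])
      cycles <- cyc
    }
  }
  structure(list(
    rotation = fit$rotation, translation = fit$translation,
    rmsd = fit$rmsd, paired_count = length(keep),
    initial_pairs = nrow(pairs), cycles_used = cycles,
    pairs = pairs[keep, ]
  ), class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> RMSD %.3f A over %d C-alpha (of %d paired; %d rejection cycle(s))\n",
              x$rmsd, x$paired_count, x$initial_pairs, x$cycles_used))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.superposition <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, paired_count = x$paired_count,
                 initial_pairs = x$initial_pairs,
                 cycles_used = x$cycles_used)
}

#' Apply a superposition transform to coordinates
#'
#' @param coords A `coord_set` or any tibble with `x`, `y`, `z` columns.
#' @param sp A `superposition` result.
#' @return The input with transformed coordinates.
#' @export
apply_transform <- function(coords, sp) {
  stopifnot(inherits(sp, "superposition"))
  M <- as.matrix(coords[, c("x", "y", "z")]) %*% t(sp$rotation)
  M <- sweep(M, 2, sp$translation, `+`)
  coords$x <- M[, 1]; coords$y <- M[, 2]; coords$z <- M[, 3]
  coords
}

#' Enumerate polar contacts between a receptor and a ligand
#'
#' Heavy-atom proxy for hydrogen bonds: every nitrogen/oxygen pair with one
#' atom from the receptor and one from the ligand at distance at most
#' `d_max` (default 3.5 Å). No angular term is applied — crystallographic
#' models at typical resolution carry no hydrogens.
#'
#' @param receptor All-atom tibble (as from [load_atoms()]).
#' @param ligand All-atom tibble of the ligand.
#' @param d_max Distance cutoff, Å.
#' @return Tibble sorted by distance with one row per contact:
#'   receptor residue/atom, ligand atom, `distance`.
#' @export
polar_contacts <- function(receptor, ligand, d_max = 3.5) {
  if (is.null(ligand) || !nrow(ligand))
    abort_domain("No ligand atoms supplied.")
  rp <- receptor[receptor$element %in% c("N", "O"), ]
  lp <- ligand[ligand$element %in% c("N", "O"), ]
  if (!nrow(rp) || !nrow(lp))
    return(tibble::tibble(resno = integer(), resid = character(),
                          protein_atom = character(),
                          ligand_atom = character(), distance = double()))
  D <- outer(rowSums(coords_matrix(rp)^2), rowSums(coords_matrix(lp)^2),
             `+`) - 2 * coords_matrix(rp) %*% t(coords_matrix(lp))
  D <- sqrt(pmax(D, 0))
  hit <- which(D <= d_max, arr.ind = TRUE)
  out <- tibble::tibble(
    resno = rp$resno[hit[, 1]], resid = rp$resid[hit[, 1]],
    protein_atom = rp$elety[hit[, 1]],
    ligand_atom = lp$elety[hit[, 2]],
    distance = D[hit]
  )
  dplyr::arrange(out, .data$distance)
}
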