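# Fixtures are built in code: synthetic coordinate sets, tiny PDB/mmCIF
# files, random rotations, and an independent bisection oracle for the
# binding equilibrium.

# idealised alpha-helix C-alpha trace (rise 1.5 A, 100 deg/residue, r 2.3 A)
helix_coords <- function(n, start_resno = 1, chain = "A") {
  i <- seq_len(n) - 1
  theta <- i * 100 * pi / 180
  out <- tibble::tibble(
    chain = chain,
    resno = start_resno + i,
    resid = rep(c("ALA", "GLY", "SER", "LEU", "LYS"), length.out = n),
    x = 2.3 * cos(theta), y = 2.3 * sin(theta), z = 1.5 * i
  )
  class(out) <- c("coord_set", class(out))
  out
}

random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_dec <- qr(M)
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

transform_coords <- function(cs, R, t) {
  M <- as.matrix(cs[, c("x", "y", "z")]) %*% t(R)
  M <- sweep(M, 2, t, `+`)
  cs$x <- M[, 1]; cs$y <- M[, 2]; cs$z <- M[, 3]
  cs
}

# write a coord_set (plus optional extra raw lines) as a minimal PDB file
write_mini_pdb <- function(cs, path, altloc = rep(" ", nrow(cs)),
                           occ = rep(1, nrow(cs))) {
  lines <- sprintf(
    "ATOM  %5d  CA %1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(cs)), altloc, cs$resid, cs$chain, cs$resno,
    cs$x, cs$y, cs$z, occ, 10.0)
  writeLines(c(lines, "END"), path)
  path
}

write_mini_cif <- function(cs, path) {
  hdr <- c("data_synthetic", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  rows <- sprintf(
    "ATOM %d C CA . %s %s 1 %d ? %.3f %.3f %.3f 1.00 10.00 ? %d %s %s CA 1",
    seq_len(nrow(cs)), cs$resid, cs$chain, seq_len(nrow(cs)),
    cs$x, cs$y, cs$z, cs$resno, cs$resid, cs$chain)
  writeLines(c(hdr, rows), path)
  path
}

# independent equilibrium oracle: bisection on the mass-action equation
# h(mx) = mx^2 - (nM + X + Kd) mx + nM X, which is positive at mx = 0 and
# non-positive at the stoichiometric ceiling, and strictly decreasing on
# [0, min(nM, X)] — so plain sign bisection converges to the physical root
bound_complex_bisect <- function(m_total, x_total, stoich, kd) {
  nm <- stoich * m_total
  if (x_total == 0 || nm == 0) return(0)
  b <- nm + x_total + kd
  h <- function(mx) mx^2 - b * mx + nm * x_total
  lo <- 0; hi <- min(nm, x_total)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (h(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-16 * max(1, hi)) break
  }
  (lo + hi) / 2
}

expect_close <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol),
              label = sprintf("max|diff| = %.3g (tol %.3g)",
                              max(abs(actual - expected)), tol))
}
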