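test_that("C-alpha loading honours chains, ranges, formats and altlocs", {
  cs <- helix_coords(10, start_resno = 370)
  pdb_path <- tempfile(fileext = ".pdb")
  cif_path <- tempfile(fileext = ".cif")
  write_mini_pdb(cs, pdb_path)
  write_mini_cif(cs, cif_path)

  got_pdb <- load_calpha(pdb_path, chain = "A")
  expect_equal(nrow(got_pdb), 10)
  expect_equal(got_pdb$resno, 370:379)
  expect_equal(got_pdb$x, cs$x, tolerance = 1e-3)

  # mmCIF and PDB renderings of the same model are interchangeable
  got_cif <- load_calpha(cif_path, chain = "A")
  expect_equal(got_cif$resno, got_pdb$resno)
  expect_equal(got_cif$x, got_pdb$x, tolerance = 1e-3)
  expect_equal(got_cif$resid, got_pdb$resid)

  # residue-range selection is a closed interval on author numbering
  sub <- load_calpha(pdb_path, chain = "A", range = c(373, 376))
  expect_equal(sub$resno, 373:376)

  expect_error(load_calpha(pdb_path, chain = "B"),
               class = "sarmact_config_error")
  expect_error(load_calpha(pdb_path, chain = "A", range = c(500, 600)),
               class = "sarmact_config_error")
})

test_that("altloc resolution keeps the highest occupancy, ties to A", {
  cs <- helix_coords(3)
  path <- tempfile(fileext = ".pdb")
  # residue 1 has B at higher occupancy; residue 2 has a 50/50 tie
  lines <- c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       9.000   9.000   9.000  0.60 10.00           C",
    "ATOM      3  CA AGLY A   2       2.000   0.000   0.000  0.50 10.00           C",
    "ATOM      4  CA BGLY A   2       8.000   8.000   8.000  0.50 10.00           C",
    "ATOM      5  CA  SER A   3       3.000   0.000   0.000  1.00 10.00           C",
    "END")
  writeLines(lines, path)
  got <- load_calpha(path, chain = "A")
  expect_equal(nrow(got), 3)
  expect_equal(got$x, c(9, 2, 3), tolerance = 1e-3)
})

test_that("residue pairing intersects author numbering and falls back to alignment", {
  a <- helix_coords(40, start_resno = 100)
  b <- helix_coords(40, start_resno = 100)
  p <- pair_residues(a, b)
  expect_equal(nrow(p), 40)

  # deleting interior residues excludes exactly those pairs
  b_del <- b[-(10:14), ]
  p_del <- pair_residues(a, b_del)
  expect_equal(nrow(p_del), 35)
  expect_false(any(p_del$resno_a %in% 109:113))

  # disjoint numbering with identical sequences pairs via alignment
  b_shift <- helix_coords(40, start_resno = 500)
  p_al <- pair_residues(a, b_shift)
  expect_equal(nrow(p_al), 40)
  expect_equal(p_al$idx_a, p_al$idx_b)

  expect_error(pair_residues(a[1:2, ], b[1:2, ]),
               class = "sarmact_domain_error")
})

test_that("superposition is exact for identity and rigid motions", {
  a <- helix_coords(50)
  sp_id <- superpose(a, a)
  expect_lt(sp_id$rmsd, 1e-10)
  expect_equal(sp_id$paired_count, 50)
  expect_equal(det(sp_id$rotation), 1, tolerance = 1e-8)

  set.seed(17)
  for (i in 1:10) {
    R <- random_rotation(); tr <- stats::rnorm(3, sd = 20)
    b <- transform_coords(a, R, tr)
    sp <- superpose(a, b)
    expect_lt(sp$rmsd, 1e-8)
    expect_equal(crossprod(sp$rotation), diag(3), tolerance = 1e-8)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
    # the recovered motion maps the mobile set back onto the reference
    back <- apply_transform(b, sp)
    expect_equal(as.matrix(back[, c("x", "y", "z")]),
                 as.matrix(a[, c("x", "y", "z")]), tolerance = 1e-8)
  }
})

test_that("superposition RMSD is symmetric and matches bio3d on perturbed pairs", {
  set.seed(23)
  a <- helix_coords(60)
  b <- a
  noise <- matrix(stats::rnorm(180, sd = 0.6), ncol = 3)
  b$x <- b$x + noise[, 1]; b$y <- b$y + noise[, 2]; b$z <- b$z + noise[, 3]
  b <- transform_coords(b, random_rotation(), stats::rnorm(3, sd = 10))

  sp_ab <- superpose(a, b, reject_cycles = 0)
  sp_ba <- superpose(b, a, reject_cycles = 0)
  expect_equal(sp_ab$rmsd, sp_ba$rmsd, tolerance = 1e-9)

  # independent cross-check: bio3d's least-squares fit on the same pairs
  xyz_a <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  xyz_b <- as.vector(t(as.matrix(b[, c("x", "y", "z")])))
  rmsd_bio3d <- bio3d::rmsd(xyz_a, xyz_b, fit = TRUE)
  expect_equal(sp_ab$rmsd, rmsd_bio3d, tolerance = 1e-3)
})

test_that("Kabsch equals brute-force rotation-grid minimisation on toy instances", {
  # 4-point instances; minimisation over rotations parameterised by Euler
  # angles — a coarse exhaustive grid followed by generic Nelder-Mead
  # refinement, never touching the SVD path under test
  euler_R <- function(ang) {
    a <- ang[1]; b <- ang[2]; g <- ang[3]
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
                 byrow = TRUE)
    Rz2 <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  brute_rmsd <- function(P, Q) {
    Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
    obj <- function(ang)
      sqrt(mean(rowSums((Pc %*% t(euler_R(ang)) - Qc)^2)))
    steps <- seq(0, 2 * pi, length.out = 19)[-19]
    half <- seq(0, pi, length.out = 10)
    grid <- as.matrix(expand.grid(steps, half, steps))
    vals <- apply(grid, 1, obj)
    best0 <- grid[which.min(vals), ]
    opt <- stats::optim(best0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    opt$value
  }
  set.seed(31)
  for (i in 1:3) {
    Q <- matrix(stats::rnorm(12, sd = 3), ncol = 3)
    P <- Q %*% t(random_rotation()) +
      matrix(stats::rnorm(12, sd = 0.2), ncol = 3)
    a <- helix_coords(4); b <- helix_coords(4)
    a$x <- Q[, 1]; a$y <- Q[, 2]; a$z <- Q[, 3]
    b$x <- P[, 1]; b$y <- P[, 2]; b$z <- P[, 3]
    sp <- superpose(a, b, reject_cycles = 0)
    expect_equal(sp$rmsd, brute_rmsd(P, Q), tolerance = 1e-3)
  }
})

test_that("outlier rejection lowers RMSD monotonically and reports counts", {
  set.seed(41)
  a <- helix_coords(80)
  b <- a
  b$x <- b$x + stats::rnorm(80, sd = 0.2)
  # plant 6 gross outliers
  out_idx <- c(5, 20, 33, 47, 61, 75)
  b$x[out_idx] <- b$x[out_idx] + 15
  sp_all <- superpose(a, b, reject_cycles = 0)
  sp_rej <- superpose(a, b, reject_cycles = 5, reject_sigma = 2)
  expect_lte(sp_rej$rmsd, sp_all$rmsd)
  expect_lt(sp_rej$paired_count, 80)
  expect_gt(sp_rej$paired_count, 60)
  expect_false(any(out_idx %in% sp_rej$pairs$idx_a))
})

test_that("polar contacts apply the element filter and distance boundary", {
  mk_atoms <- function(df) tibble::as_tibble(df)
  receptor <- mk_atoms(data.frame(
    chain = "A", resno = c(1, 1, 2), resid = "SER",
    elety = c("OG", "CB", "N"), element = c("O", "C", "N"),
    x = c(0, 0, 10), y = 0, z = 0))
  # ligand N at 2.9 A from receptor OG; ligand O at 2.9 A from receptor CB
  ligand <- mk_atoms(data.frame(
    chain = "X", resno = 900, resid = "LIG",
    elety = c("N1", "O1"), element = c("N", "O"),
    x = c(2.9, 0.0), y = c(0, 0), z = c(0, -2.9)))
  hits <- polar_contacts(receptor, ligand)
  # the C...O pair is excluded by the element filter; OG sees both ligand
  # polar atoms within 3.5 A (N1 at 2.9, O1 at 2.9)
  expect_true(all(hits$protein_atom == "OG"))
  expect_equal(nrow(hits), 2)
  expect_equal(hits$distance, c(2.9, 2.9), tolerance = 1e-9)

  # boundary: 3.4 in, 3.6 out
  lig2 <- mk_atoms(data.frame(
    chain = "X", resno = 900, resid = "LIG",
    elety = c("N1", "N2"), element = "N",
    x = c(3.4, 3.6), y = 0, z = 0))
  rec1 <- receptor[receptor$elety == "OG", ]
  hits2 <- polar_contacts(rec1, lig2, d_max = 3.5)
  expect_equal(nrow(hits2), 1)
  expect_equal(hits2$ligand_atom, "N1")

  # distant ligand: empty result, not an error
  far <- mk_atoms(data.frame(chain = "X", resno = 1, resid = "LIG",
                             elety = "O1", element = "O",
                             x = 100, y = 100, z = 100))
  expect_equal(nrow(polar_contacts(receptor, far)), 0)
  expect_error(polar_contacts(receptor, far[0, ]),
               class = "sarmact_domain_error")
})
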