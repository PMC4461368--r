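test_that("radius of gyration matches closed-form fixtures", {
  two <- atom_tbl(c("C1", "C2"), 1:2, c(-1, 1), 0, 0, element = "C",
                  mass = c(1, 1))
  expect_equal(radius_of_gyration(two), 1)
  one <- atom_tbl("CA", 1, 3.2, -1.1, 0.4)
  expect_equal(radius_of_gyration(one), 0)
  corners <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  cube <- atom_tbl(paste0("C", 1:8), 1:8, corners$x, corners$y, corners$z,
                   element = "C", mass = rep(1, 8))
  expect_equal(radius_of_gyration(cube), sqrt(3))
})

test_that("radius of gyration is invariant under rigid motions", {
  set.seed(14)
  atoms <- atom_tbl(paste0("C", 1:30), 1:30, rnorm(30, sd = 5),
                    rnorm(30, sd = 5), rnorm(30, sd = 5), element = "C")
  rg <- radius_of_gyration(atoms)
  for (rep in 1:5) {
    rot <- random_rotation()
    shift <- rnorm(3, sd = 50)
    xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% rot
    moved <- atoms
    moved$x <- xyz[, 1] + shift[1]
    moved$y <- xyz[, 2] + shift[2]
    moved$z <- xyz[, 3] + shift[3]
    expect_equal(radius_of_gyration(moved), rg, tolerance = 1e-9)
  }
})

test_that("contacts follow the 6.5 Angstrom non-sequential CA rule", {
  mk <- function(positions, resno = seq_along(positions)) {
    atom_tbl(rep("CA", length(positions)), resno,
             vapply(positions, `[`, numeric(1), 1),
             vapply(positions, `[`, numeric(1), 2),
             vapply(positions, `[`, numeric(1), 3), element = "C")
  }
  # residues 1 and 4 at 6.4 A: contact; adjacent pair at 3.8 A: not
  frame <- mk(list(c(0, 0, 0), c(3.8, 0, 0), c(40, 0, 0), c(6.4, 0, 0)))
  pairs <- torsionfel:::contact_pairs(frame)
  expect_true(any(pairs$res_i == 1 & pairs$res_j == 4))
  expect_false(any(pairs$res_i == 1 & pairs$res_j == 2))
  # prevalence 2/3 across three reference models
  near <- mk(list(c(0, 0, 0), c(30, 0, 0), c(5, 0, 0)))
  far <- mk(list(c(0, 0, 0), c(30, 0, 0), c(20, 0, 0)))
  native <- define_native_set(list(near, near, far))
  expect_equal(nrow(native), 1L)
  expect_equal(c(native$res_i, native$res_j), c(1, 3))
  expect_equal(native_contacts(near, native), 1L)
  expect_equal(native_contacts(far, native), 0L)
  # renumbering offsets leave the count unchanged
  shifted <- mk(list(c(0, 0, 0), c(30, 0, 0), c(5, 0, 0)),
                resno = c(101, 102, 103))
  native_s <- define_native_set(list(shifted, shifted, shifted))
  expect_equal(nrow(native_s), 1L)
  expect_error(native_contacts(atom_tbl("CB", 1, 0, 0, 0), native), "CA")
})

test_that("hydrogen bonds need both the distance and the bend angle", {
  hb_frame <- function(acceptor_xyz) {
    atom_tbl(c("N", "HN", "O"), c(1, 1, 5),
             c(0, 1, acceptor_xyz[1]), c(0, 0, acceptor_xyz[2]),
             c(0, 0, acceptor_xyz[3]),
             element = c("N", "H", "O"))
  }
  expect_equal(hydrogen_bonds(hb_frame(c(3.4, 0, 0))), 1L)  # 3.4 A, 180 deg
  expect_equal(hydrogen_bonds(hb_frame(c(3.6, 0, 0))), 0L)  # too far
  # D-H-A angle of 120 degrees at 2.65 A: too bent
  expect_equal(hydrogen_bonds(hb_frame(c(2.0, 1.7320508, 0))), 0L)
  no_h <- atom_tbl(c("N", "O"), c(1, 5), c(0, 3), 0, 0,
                   element = c("N", "O"))
  expect_error(hydrogen_bonds(no_h), "distance_only")
  expect_equal(hydrogen_bonds(no_h, distance_only = TRUE), 1L)
})

test_that("SASA matches the isolated-sphere closed form and buries fully", {
  lone <- atom_tbl("C", 1, 0, 0, 0, element = "C")
  a <- sasa(lone, probe_radius = 1.4, n_points = 960)
  expect_equal(a, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  # the same atom inside a dense shell is fully buried
  shell_pts <- torsionfel:::sphere_points(100) * 2
  shell <- atom_tbl(paste0("C", 1:101), rep(1, 101),
                    c(0, shell_pts[, 1]), c(0, shell_pts[, 2]),
                    c(0, shell_pts[, 3]), element = "C")
  buried <- sasa(shell, probe_radius = 1.4, n_points = 960)[1]
  expect_lt(buried, 0.01 * 4 * pi * 3.1^2)
  expect_error(sasa(atom_tbl("X1", 1, 0, 0, 0, element = "X", mass = 1)),
               "radius")
})

test_that("default sampling agrees with dense sampling on a two-atom system", {
  two <- atom_tbl(c("C1", "O1"), 1:2, c(0, 2.2), 0, 0,
                  element = c("C", "O"))
  coarse <- sasa(two, n_points = 960)
  dense <- sasa(two, n_points = 20000)
  expect_equal(coarse, dense, tolerance = 0.02)
})

test_that("occlusion is monotone: neighbors never increase exposed area", {
  base <- atom_tbl(c("C1", "C2"), 1:2, c(0, 3), 0, 0, element = "C")
  with_occluder <- atom_tbl(c("C1", "C2", "C3"), 1:3, c(0, 3, 1.6), 0, 0,
                            element = "C")
  a0 <- sasa(base)
  a1 <- sasa(with_occluder)
  expect_lte(a1[1], a0[1] + 1e-9)
  expect_lte(a1[2], a0[2] + 1e-9)
})

test_that("hydrophobic SASA sums only the hydrophobic residues", {
  atoms <- atom_tbl(c("C1", "C2"), 1:2, c(0, 50), 0, 0, element = "C",
                    residue_name = c("LEU", "SER"))
  h <- hydrophobic_sasa(atoms)
  full <- sum(sasa(atoms))
  expect_equal(h, full / 2, tolerance = 1e-9)
})

test_that("Kabsch RMSD agrees with an independent superposition oracle", {
  skip_if_not_installed("bio3d")
  expect_equal(kabsch_rmsd(diag(3), diag(3)), 0)
  set.seed(3)
  a <- matrix(rnorm(60, sd = 4), ncol = 3)
  rot <- random_rotation()
  b <- a %*% rot + matrix(rep(c(5, -3, 2), each = 20), ncol = 3)
  expect_lt(kabsch_rmsd(a, b), 1e-9)  # pure rigid motion
  for (rep in 1:5) {
    p <- matrix(rnorm(45, sd = 3), ncol = 3)
    q <- p + matrix(rnorm(45, sd = 0.6), ncol = 3)
    fitted <- suppressWarnings(
      bio3d::fit.xyz(fixed = as.vector(t(q)),
                     mobile = matrix(as.vector(t(p)), nrow = 1)))
    fm <- matrix(fitted, ncol = 3, byrow = TRUE)
    oracle <- sqrt(sum((fm - q)^2) / nrow(q))
    expect_equal(kabsch_rmsd(p, q), oracle, tolerance = 1e-6)
  }
  expect_equal(kabsch_rmsd(a, b), kabsch_rmsd(b, a), tolerance = 1e-9)
  expect_error(kabsch_rmsd(a[1:2, ], b[1:2, ]), "3 atoms")
})

test_that("pairwise RMSD distributions are grouped intra vs inter", {
  set.seed(23)
  ref <- matrix(rnorm(30, sd = 3), ncol = 3)
  frames <- c(
    lapply(1:4, function(i) ref + rnorm(30, sd = 0.05)),
    lapply(1:4, function(i) ref + 2 + rnorm(30, sd = 0.05))
  )
  # cluster 2 is translated only: superposition removes the offset, so use a
  # deformed second cluster instead
  deform <- ref
  deform[1:3, ] <- deform[1:3, ] + 3
  frames[5:8] <- lapply(1:4, function(i) deform + rnorm(30, sd = 0.05))
  labels <- rep(c("c1", "c2"), each = 4)
  pw <- pairwise_rmsd(frames, labels, max_pairs = 50, seed = 2)
  expect_setequal(unique(pw$pair_type), c("intra", "inter"))
  expect_true(all(pw$rmsd >= 0))
  expect_gt(mean(pw$rmsd[pw$pair_type == "inter"]),
            mean(pw$rmsd[pw$pair_type == "intra"]))
})

test_that("synthetic multi-model PDB fixtures round-trip", {
  m1 <- atom_tbl(c("N", "CA", "C"), c(1, 1, 1), c(0, 1.5, 2.9),
                 c(0, 0.2, -0.3), c(0, 0, 0.5),
                 element = c("N", "C", "C"), residue_name = "ALA")
  m2 <- m1
  m2$x <- m2$x + 0.25
  f <- tempfile(fileext = ".pdb")
  write_pdb_models(list(m1, m2), f)
  back <- read_pdb_models(f)
  expect_length(back, 2)
  expect_equal(back[[1]]$x, m1$x, tolerance = 1e-3)
  expect_equal(back[[2]]$x, m2$x, tolerance = 1e-3)
  expect_equal(back[[1]]$atom_name, m1$atom_name)
  skip_if_not_installed("bio3d")
  pdb <- bio3d::read.pdb(f, multi = TRUE, verbose = FALSE)
  expect_equal(nrow(pdb$atom), 3)
  expect_equal(dim(pdb$xyz)[1], 2)
  unlink(f)
})

test_that("structure_properties assembles the per-frame record", {
  frame <- atom_tbl(c("N", "HN", "CA", "O"), c(1, 1, 1, 3),
                    c(0, 1, 1.5, 3.4), c(0, 0, 1.2, 0), c(0, 0, 0, 0),
                    element = c("N", "H", "C", "O"),
                    residue_name = c("LEU", "LEU", "LEU", "SER"))
  props <- structure_properties(list(frame))
  expect_equal(names(props), c("frame", "R_g", "nHB", "nNC", "hSASA"))
  expect_equal(props$nHB, 1L)
  expect_true(props$R_g > 0, props$hSASA > 0)
})
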