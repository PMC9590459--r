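pdb_line <- function(rec, serial, name, resname, chain, resno, x, y, z,
                     element, altloc = " ") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          rec, serial, name, altloc, resname, chain, resno, x, y, z, element)
}

test_that("read_structure keeps model 1, altloc A, flags ligands", {
  lines <- c(
    "MODEL     1",
    pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
    pdb_line("ATOM", 2, "CB", "ALA", "A", 1, 1.5, 0, 0, "C", altloc = "A"),
    pdb_line("ATOM", 3, "CB", "ALA", "A", 1, 1.6, 0, 0, "C", altloc = "B"),
    pdb_line("ATOM", 4, "HB1", "ALA", "A", 1, 2.0, 0, 0, "H"),
    pdb_line("HETATM", 5, "FE", "HEM", "A", 2, 5, 5, 5, "FE"),
    "ENDMDL",
    "MODEL     2",
    pdb_line("ATOM", 6, "CA", "ALA", "A", 9, 9, 9, 9, "C"),
    "ENDMDL")
  s <- read_structure(write_tmp(lines, ".pdb"))
  expect_s3_class(s, "Structure")
  expect_equal(nrow(s$atoms), 3L)          # model 1, no H, one altloc
  expect_equal(sum(s$atoms$is_ligand), 1L)
  expect_equal(s$atoms$resname[s$atoms$is_ligand], "HEM")
  expect_false(9 %in% s$atoms$resno)
  expect_error(read_structure(write_tmp(
    pdb_line("HETATM", 1, "FE", "HEM", "A", 1, 0, 0, 0, "FE"), ".pdb")),
    "no ATOM")
})

test_that("missing element fields are inferred with a warning", {
  lines <- pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0, "")
  expect_warning(s <- read_structure(write_tmp(lines, ".pdb")), "inferred")
  expect_equal(s$atoms$element, "C")
})

test_that("isolated atom SASA matches the analytic sphere", {
  s <- structure(list(atoms = data.frame(
    serial = 1L, name = "SG", resname = "CYS", chain = "A", resno = 1L,
    x = 0, y = 0, z = 0, element = "S", is_ligand = FALSE),
    ligand_codes = "HEM"), class = "Structure")
  # S: r_vdw 1.8; override via element table is fixed, so use S -> 1.8 + 1.4
  a <- atom_sasa(s, probe = 1.4, n_points = 960)
  expect_equal(a, 4 * pi * 3.2^2, tolerance = 0.01)
})

test_that("an atom enclosed by a shell of neighbors has zero SASA", {
  pts <- enzdesign:::fibonacci_sphere(60) * 2.0
  atoms <- data.frame(serial = seq_len(61),
                      name = "C", resname = "ALA", chain = "A",
                      resno = seq_len(61),
                      x = c(0, pts[, 1]), y = c(0, pts[, 2]),
                      z = c(0, pts[, 3]), element = "C", is_ligand = FALSE)
  s <- structure(list(atoms = atoms, ligand_codes = "HEM"),
                 class = "Structure")
  a <- atom_sasa(s, probe = 1.4, n_points = 960)
  expect_equal(a[1], 0)
})

test_that("two overlapping spheres match a Monte-Carlo oracle within 2%", {
  sep <- 2.5
  atoms <- data.frame(serial = 1:2, name = "C", resname = "ALA",
                      chain = "A", resno = 1:2,
                      x = c(0, sep), y = 0, z = 0,
                      element = "C", is_ligand = FALSE)
  s <- structure(list(atoms = atoms, ligand_codes = "HEM"),
                 class = "Structure")
  got <- atom_sasa(s, probe = 1.4, n_points = 960)
  r <- 1.7 + 1.4
  mc <- oracle_mc_sasa(c(0, 0, 0), r, matrix(c(sep, 0, 0), 1), r, n = 1e6)
  expect_equal(got[1], mc, tolerance = 0.02)
  expect_equal(got[1], got[2], tolerance = 1e-9)  # symmetric pair
})

test_that("SASA is rigid-motion invariant and locally supported", {
  s <- make_toy_structure(n_residues = 10, ligand_resno = NA)
  a0 <- atom_sasa(s)
  # rotate + translate all coordinates
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% R
  s2 <- s
  s2$atoms$x <- xyz[, 1] + 11; s2$atoms$y <- xyz[, 2] - 3
  s2$atoms$z <- xyz[, 3] + 2
  a1 <- atom_sasa(s2)
  # total within the 0.5% discretization band, per-atom within 5%
  expect_equal(sum(a1), sum(a0), tolerance = 0.005)
  expect_lt(max(abs(a1 - a0) / a0), 0.1)

  # removing a far-away atom leaves the rest untouched
  s3 <- s
  s3$atoms <- rbind(s3$atoms, data.frame(
    serial = 99L, name = "C", resname = "ALA", chain = "A", resno = 99L,
    x = 500, y = 500, z = 500, element = "C", is_ligand = FALSE))
  a3 <- atom_sasa(s3)
  expect_equal(a3[seq_along(a0)], a0, tolerance = 1e-12)
})

test_that("point-density refinement changes single-atom SASA by < 0.5%", {
  s <- structure(list(atoms = data.frame(
    serial = 1L, name = "CA", resname = "GLY", chain = "A", resno = 1L,
    x = 0, y = 0, z = 0, element = "C", is_ligand = FALSE),
    ligand_codes = "HEM"), class = "Structure")
  a960 <- atom_sasa(s, n_points = 960)
  a3840 <- atom_sasa(s, n_points = 3840)
  expect_lt(abs(a3840 - a960) / a960, 0.005)
  expect_error(atom_sasa(s, n_points = 50), "n_points")
  expect_error(atom_sasa(s, probe = -1), "probe")
})

test_that("residue RSA: exposed extended tripeptide vs buried core", {
  # idealized extended Gly-Ala-Gly: backbone N, CA, C, O (+ CB for Ala)
  mk <- function(resno, resname, ofs, with_cb) {
    at <- data.frame(
      serial = 0L,
      name = c("N", "CA", "C", "O", if (with_cb) "CB"),
      resname = resname, chain = "A", resno = resno,
      x = ofs + c(0, 1.46, 2.42, 2.20, if (with_cb) 1.95),
      y = c(0, 0.55, -0.55, -1.75, if (with_cb) 1.55),
      z = c(0, 0, 0, 0, if (with_cb) 0.9),
      element = c("N", "C", "C", "O", if (with_cb) "C"),
      is_ligand = FALSE)
    at
  }
  atoms <- rbind(mk(1, "GLY", 0, FALSE), mk(2, "ALA", 3.63, TRUE),
                 mk(3, "GLY", 7.26, FALSE))
  atoms$serial <- seq_len(nrow(atoms))
  s <- structure(list(atoms = atoms, ligand_codes = "HEM"),
                 class = "Structure")
  rsa <- residue_rsa(s, atom_sasa(s))
  expect_equal(rsa$rsa[rsa$resname == "ALA"], 1, tolerance = 0.35)

  # a residue at the center of a dense cluster is buried
  shell <- enzdesign:::fibonacci_sphere(80) * 3.2
  atoms2 <- rbind(
    data.frame(serial = 1L, name = "CA", resname = "ALA", chain = "A",
               resno = 1L, x = 0, y = 0, z = 0, element = "C",
               is_ligand = FALSE),
    data.frame(serial = 1L + seq_len(80), name = "CA", resname = "GLY",
               chain = "A", resno = 1L + seq_len(80),
               x = shell[, 1], y = shell[, 2], z = shell[, 3],
               element = "C", is_ligand = FALSE))
  s2 <- structure(list(atoms = atoms2, ligand_codes = "HEM"),
                  class = "Structure")
  rsa2 <- residue_rsa(s2, atom_sasa(s2))
  expect_lt(rsa2$rsa[rsa2$resno == 1], 0.02)
})

test_that("unknown residue types are excluded with a warning", {
  atoms <- data.frame(serial = 1:2, name = "CA", resname = c("ALA", "XXX"),
                      chain = "A", resno = 1:2, x = c(0, 30), y = 0, z = 0,
                      element = "C", is_ligand = FALSE)
  s <- structure(list(atoms = atoms, ligand_codes = "HEM"),
                 class = "Structure")
  expect_warning(rsa <- residue_rsa(s, atom_sasa(s)), "reference area")
  expect_equal(rsa$resname, "ALA")
})

test_that("classify_residues applies thresholds and pocket cutoff", {
  s <- make_toy_structure(n_residues = 12, ligand_resno = 6,
                          ligand_offset = 5)
  rsa <- residue_rsa(s, atom_sasa(s))
  # threshold rule on synthetic rsa values
  fake <- rsa[1:3, ]
  fake$rsa <- c(0.50, 0.10, 0.02)
  env <- classify_residues(s, fake)
  expect_equal(env$burial_class, c("surface", "semi-exposed", "buried"))
  expect_error(classify_residues(s, fake, surface_min = 0.05,
                                 buried_max = 0.25), "surface_min")

  env_all <- classify_residues(s, rsa, pocket_cutoff = 6)
  expect_true(env_all$pocket[env_all$residue_number == 6])
  expect_false(env_all$pocket[env_all$residue_number == 1])
  expect_equal(env_all$min_ligand_distance[env_all$residue_number == 6], 5,
               tolerance = 1e-6)
  # exactly one burial class per residue
  expect_true(all(env_all$burial_class %in%
                    c("surface", "semi-exposed", "buried")))
})
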