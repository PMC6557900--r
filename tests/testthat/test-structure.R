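test_that("toy structures round-trip identically through PDB and mmCIF", {
  m <- gen_toy_complex("hbond_pair")
  p_pdb <- withr::local_tempfile(fileext = ".pdb")
  p_cif <- withr::local_tempfile(fileext = ".cif")
  write_structure(m, p_pdb)
  write_structure(m, p_cif)
  m1 <- read_structure(p_pdb)
  m2 <- read_structure(p_cif)
  cols <- c("chain", "resno", "resid", "atom", "element", "x", "y", "z")
  expect_equal(m1$atoms[cols], m2$atoms[cols])
  expect_equal(m1$atoms$x, m$atoms$x)
  expect_equal(nrow(m1$atoms), 4)
})

test_that("altloc filtering keeps the highest-occupancy conformer", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "END"), path)
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 1)
  expect_equal(m$atoms$x, 0)
  expect_equal(m$atoms$altloc, "A")

  # the policy follows occupancy, not alphabetical order
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.30  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.70  0.00           C",
    "END"), path2)
  m2 <- read_structure(path2)
  expect_equal(nrow(m2$atoms), 1)
  expect_equal(m2$atoms$altloc, "B")
})

test_that("phosphotyrosine is a peptide residue; waters are flagged", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  CA  PTR A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O   HOH A 101       5.000   0.000   0.000  1.00  0.00           O",
    "END"), path)
  m <- read_structure(path)
  expect_false(m$atoms$is_het[m$atoms$resid == "PTR"])
  expect_true(m$atoms$is_water[m$atoms$resid == "HOH"])
  # waters excluded from SASA by default
  sasa <- compute_sasa(m)
  expect_true(is.na(sasa[m$atoms$resid == "HOH"]))
})

test_that("single-sphere SASA equals the analytic area", {
  m <- gen_toy_complex("single_sphere")
  a <- sum(compute_sasa(m), na.rm = TRUE)
  analytic <- 4 * pi * (1.70 + 1.4)^2
  expect_lt(abs(a - analytic) / analytic, 0.005)
  # a 1.9 A radius element via a custom radius table
  a19 <- sum(compute_sasa(m, radii = c(C = 1.9)), na.rm = TRUE)
  expect_lt(abs(a19 - 4 * pi * 3.3^2) / (4 * pi * 3.3^2), 0.005)
})

test_that("distant atoms contribute independent spheres", {
  m <- gen_toy_complex("far_dimer")
  a <- sum(compute_sasa(m), na.rm = TRUE)
  expect_equal(a, 2 * 4 * pi * 3.1^2, tolerance = 1e-6)
})

test_that("overlapping spheres agree with the Monte-Carlo oracle", {
  m <- gen_toy_complex("touching_dimer")
  a <- sum(compute_sasa(m), na.rm = TRUE)
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
  a_mc <- oracle_mc_sasa(xyz, radii = rep(1.70, 4), n_mc = 2e5, seed = 99)
  expect_lt(abs(a - a_mc) / a_mc, 0.02)
})

test_that("SASA is rotation and translation invariant", {
  m <- gen_toy_complex("touching_dimer")
  a0 <- sum(compute_sasa(m), na.rm = TRUE)
  th <- 0.83
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% rot
  m2 <- m
  m2$atoms$x <- xyz[, 1] + 13.7
  m2$atoms$y <- xyz[, 2] - 5.1
  m2$atoms$z <- xyz[, 3] + 2.2
  a1 <- sum(compute_sasa(m2), na.rm = TRUE)
  expect_lt(abs(a1 - a0) / a0, 0.005)
})

test_that("SASA converges with point density", {
  m <- gen_toy_complex("touching_dimer")
  a960 <- sum(compute_sasa(m, n_points = 960), na.rm = TRUE)
  a3840 <- sum(compute_sasa(m, n_points = 3840), na.rm = TRUE)
  expect_lt(abs(a960 - a3840) / a3840, 0.01)
})

test_that("buried surface area is consistent and vanishes at distance", {
  far <- buried_surface_area(gen_toy_complex("far_dimer"), "A", "B")
  expect_equal(far$bsa_peptide, 0, tolerance = 1e-9)
  expect_equal(far$interface_area, 0, tolerance = 1e-9)

  m <- gen_toy_complex("touching_dimer")
  rep <- buried_surface_area(m, "A", "B")
  expect_gt(rep$bsa_peptide, 0)
  # identity: side areas sum to SASA(A)+SASA(B)-SASA(AB)
  sub <- function(sel) structure_model(m$atoms[m$atoms$chain %in% sel, ])
  total_delta <- sum(compute_sasa(sub("A")), na.rm = TRUE) +
    sum(compute_sasa(sub("B")), na.rm = TRUE) -
    sum(compute_sasa(m), na.rm = TRUE)
  expect_equal(rep$bsa_peptide + rep$bsa_receptor, total_delta,
               tolerance = 1e-9)
  # per-atom buried areas match a direct atom-by-atom difference
  sasa_a <- compute_sasa(sub("A"))
  sasa_ab <- compute_sasa(m)
  direct <- sasa_a - sasa_ab[m$atoms$chain == "A"]
  expect_equal(rep$per_atom$buried[rep$per_atom$chain == "A"], direct)
  expect_error(buried_surface_area(m, "A", "A"), "disjoint")
  expect_error(buried_surface_area(m, "A", "Z"), "empty")
})

test_that("residue distances are Euclidean and symmetric", {
  atoms <- data.frame(chain = c("A", "B"), resno = c(1, 2),
                      resid = "PTR", atom = "CA", element = "C",
                      x = c(0, 0), y = c(0, 0), z = c(0, 23))
  m <- structure_model(atoms)
  expect_equal(residue_distance(m, "A", 1, "B", 2), 23)
  expect_equal(residue_distance(m, "B", 2, "A", 1), 23)
  expect_error(residue_distance(m, "A", 1, "B", 2, atom_name = "CB"),
               "not found")
})

test_that("contact detection applies distance and angle criteria", {
  hb <- list_contacts(gen_toy_complex("hbond_pair"), "A", "B")
  expect_equal(nrow(hb$hbonds), 1)
  expect_equal(hb$hbonds$distance, 2.9, tolerance = 1e-6)
  expect_equal(hb$hbonds$geometry, "heavy_atom_angle")

  hp <- list_contacts(gen_toy_complex("touching_dimer"), "A", "B")
  expect_equal(nrow(hp$hydrophobic), 1)  # only the 3.5 A CG-CB pair
  expect_equal(nrow(hp$hbonds), 0)

  none <- list_contacts(gen_toy_complex("far_dimer"), "A", "B")
  expect_equal(nrow(none$hbonds) + nrow(none$hydrophobic), 0)

  # symmetry under selection swap
  sw <- list_contacts(gen_toy_complex("hbond_pair"), "B", "A")
  expect_equal(nrow(sw$hbonds), 1)
  expect_equal(sw$hbonds$distance, hb$hbonds$distance)
})
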