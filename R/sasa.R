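#' Van der Waals radii used for surface calculations
#'
#' A fixed published heavy-atom set: C 1.70, N 1.55, O 1.52, S 1.80,
#' P 1.80 Angstrom.
#'
#' @return Named numeric vector of radii (Angstrom).
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
}

# Deterministic quasi-uniform points on the unit sphere (golden-spiral /
# Fibonacci lattice); fixed n_points -> identical point set every call.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom solvent-accessible surface area by the Shrake-Rupley rolling
#' probe method with a deterministic golden-spiral point set: each atom's
#' sphere of radius (vdW + probe) is sampled at `n_points` points, and the
#' accessible fraction is the fraction of points outside every neighbour's
#' expanded sphere.  Hydrogens are ignored; waters and heteroatoms are
#' excluded by default.
#'
#' @param model A `structure_model`, or a data frame of atoms.
#' @param probe_radius Solvent probe radius (Angstrom, default 1.4).
#' @param n_points Sphere sample points per atom (default 960); results are
#'   deterministic given `n_points`.
#' @param radii Named vdW radius set (Angstrom); see [vdw_radii()].
#' @param default_radius Radius for elements missing from `radii`
#'   (Angstrom); used with a warning.
#' @param include_het,include_water Include heteroatoms / waters?
#' @return Numeric vector of per-atom areas (Angstrom^2) aligned with the
#'   model's atom table; excluded atoms get `NA`.
#' @examples
#' m <- gen_toy_complex("single_sphere")
#' sum(compute_sasa(m), na.rm = TRUE)  # 4*pi*(1.7+1.4)^2
#' @export
compute_sasa <- function(model, probe_radius = 1.4, n_points = 960,
                         radii = vdw_radii(), default_radius = 1.70,
                         include_het = FALSE, include_water = FALSE) {
  atoms <- if (inherits(model, "structure_model")) model$atoms else model
  keep <- atoms$element != "H"
  if (!include_het) keep <- keep & !atoms$is_het
  if (!include_water) keep <- keep & !atoms$is_water
  out <- rep(NA_real_, nrow(atoms))
  a <- atoms[keep, ]
  n <- nrow(a)
  if (n == 0) return(out)

  r_atom <- radii[a$element]
  unknown <- is.na(r_atom)
  if (any(unknown)) {
    warning("unknown element(s) ",
            paste(unique(a$element[unknown]), collapse = ", "),
            "; using default radius ", default_radius, " A")
    r_atom[unknown] <- default_radius
  }
  r_ext <- unname(r_atom) + probe_radius
  xyz <- cbind(a$x, a$y, a$z)
  pts <- sphere_points(n_points)

  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r_ext[i] + r_ext)^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      area[i] <- 4 * pi * r_ext[i]^2
      next
    }
    p <- pts * r_ext[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & dj2 > r_ext[j]^2
      if (!any(free)) break
    }
    area[i] <- 4 * pi * r_ext[i]^2 * sum(free) / n_points
  }
  out[keep] <- area
  out
}

#' Buried surface area of a two-selection interface
#'
#' Computes, for two disjoint chain selections A and B, the
#' solvent-accessible area each side loses upon complex formation:
#' `bsa_A = SASA(A alone) - SASA(A in the complex)`, and analogously for B.
#' The averaged interface area `(bsa_A + bsa_B)/2` is also reported, since
#' deposition-service conventions differ.  For a substrate-peptide complex,
#' selection A is conventionally the peptide, making `bsa_peptide` the
#' headline number.
#'
#' @param model A `structure_model` containing both selections.
#' @param chains_a,chains_b Chain id vectors for the two sides; must be
#'   disjoint and non-empty.
#' @param ... Passed to [compute_sasa()].
#' @return An object of class `interface_report`: list with `bsa_peptide`
#'   (A side, Angstrom^2), `bsa_receptor` (B side), `interface_area`,
#'   `per_atom` (data frame of per-atom buried areas in the complex
#'   frame).
#' @export
buried_surface_area <- function(model, chains_a, chains_b, ...) {
  atoms <- model$atoms
  if (length(intersect(chains_a, chains_b))) {
    stop("selections must be disjoint")
  }
  in_a <- atoms$chain %in% chains_a
  in_b <- atoms$chain %in% chains_b
  if (!any(in_a) || !any(in_b)) stop("empty selection")

  sub_model <- function(sel) {
    structure(list(atoms = atoms[sel, ], model_id = model$model_id),
              class = "structure_model")
  }
  sasa_a <- compute_sasa(sub_model(in_a), ...)
  sasa_b <- compute_sasa(sub_model(in_b), ...)
  sasa_ab <- compute_sasa(sub_model(in_a | in_b), ...)

  ab_atoms <- atoms[in_a | in_b, ]
  ab_in_a <- ab_atoms$chain %in% chains_a
  bsa_a <- sum(sasa_a, na.rm = TRUE) - sum(sasa_ab[ab_in_a], na.rm = TRUE)
  bsa_b <- sum(sasa_b, na.rm = TRUE) - sum(sasa_ab[!ab_in_a], na.rm = TRUE)

  per_atom <- ab_atoms[, c("chain", "resno", "resid", "atom")]
  # per-atom buried area: sasa alone-in-its-side minus sasa in the complex
  alone <- rep(NA_real_, nrow(ab_atoms))
  alone[ab_in_a] <- sasa_a
  alone[!ab_in_a] <- sasa_b
  per_atom$buried <- alone - sasa_ab

  out <- list(bsa_peptide = bsa_a, bsa_receptor = bsa_b,
              interface_area = (bsa_a + bsa_b) / 2, per_atom = per_atom)
  class(out) <- "interface_report"
  out
}

#' @export
print.interface_report <- function(x, digits = 4, ...) {
  cat("Interface report:\n")
  cat("  buried area, peptide side (A):  ",
      format(x$bsa_peptide, digits = digits), " A^2\n", sep = "")
  cat("  buried area, receptor side (B): ",
      format(x$bsa_receptor, digits = digits), " A^2\n", sep = "")
  cat("  interface area (mean of sides): ",
      format(x$interface_area, digits = digits), " A^2\n", sep = "")
  invisible(x)
}

#' List polar and hydrophobic contacts across an interface
#'
#' Heavy-atom contact detection between two chain selections.  A hydrogen
#' bond is a donor/acceptor pair (N or O) within `hbond_cutoff` whose
#' antecedent geometry (covalently bonded heavy neighbour - donor -
#' acceptor angle) reaches `hbond_angle` degrees; when no antecedent is
#' available for either atom the distance-only criterion is used and the
#' contact flagged `geometry = "distance_only"`.  A hydrophobic contact is
#' a pair of apolar carbons (carbon with no covalently bonded N or O)
#' within `hydrophobic_cutoff`.  Output ordering is deterministic.
#'
#' @param model A `structure_model`.
#' @param chains_a,chains_b Chain id vectors of the two sides.
#' @param hbond_cutoff Donor--acceptor distance cutoff (Angstrom, default
#'   3.5).
#' @param hbond_angle Minimum antecedent-donor-acceptor angle (degrees,
#'   default 120).
#' @param hydrophobic_cutoff Carbon--carbon cutoff (Angstrom, default 4.5).
#' @return List with data frames `hbonds` and `hydrophobic`.
#' @export
list_contacts <- function(model, chains_a, chains_b, hbond_cutoff = 3.5,
                          hbond_angle = 120, hydrophobic_cutoff = 4.5) {
  atoms <- model$atoms
  atoms <- atoms[!atoms$is_water & atoms$element != "H", ]
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  in_a <- atoms$chain %in% chains_a
  in_b <- atoms$chain %in% chains_b

  dmat <- as.matrix(stats::dist(xyz))
  covalent <- dmat > 0 & dmat < 1.8

  # apolar carbon: C with no covalently bonded N or O
  polar_nb <- covalent %*% (atoms$element %in% c("N", "O"))
  apolar_c <- atoms$element == "C" & polar_nb == 0

  angle_at <- function(d_idx, a_idx) {
    # best antecedent-donor-acceptor angle over covalent neighbours of donor
    ante <- which(covalent[d_idx, ])
    if (length(ante) == 0) return(NA_real_)
    v1 <- xyz[a_idx, ] - xyz[d_idx, ]
    best <- -Inf
    for (k in ante) {
      v2 <- xyz[k, ] - xyz[d_idx, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      best <- max(best, ang)
    }
    best
  }

  polar_a <- which(in_a & atoms$element %in% c("N", "O"))
  polar_b <- which(in_b & atoms$element %in% c("N", "O"))
  hb <- list()
  for (i in polar_a) for (j in polar_b) {
    d <- dmat[i, j]
    if (d > hbond_cutoff) next
    ang_i <- angle_at(i, j)
    ang_j <- angle_at(j, i)
    if (is.na(ang_i) && is.na(ang_j)) {
      geom <- "distance_only"; ok <- TRUE
    } else {
      ok <- (!is.na(ang_i) && ang_i >= hbond_angle) ||
        (!is.na(ang_j) && ang_j >= hbond_angle)
      geom <- "heavy_atom_angle"
    }
    if (ok) {
      hb[[length(hb) + 1]] <- data.frame(
        chain_a = atoms$chain[i], resno_a = atoms$resno[i],
        atom_a = atoms$atom[i], chain_b = atoms$chain[j],
        resno_b = atoms$resno[j], atom_b = atoms$atom[j],
        distance = d, geometry = geom, stringsAsFactors = FALSE)
    }
  }
  hbonds <- if (length(hb)) do.call(rbind, hb) else
    data.frame(chain_a = character(), resno_a = integer(),
               atom_a = character(), chain_b = character(),
               resno_b = integer(), atom_b = character(),
               distance = numeric(), geometry = character())

  hyd_a <- which(in_a & apolar_c)
  hyd_b <- which(in_b & apolar_c)
  hp <- list()
  for (i in hyd_a) for (j in hyd_b) {
    if (dmat[i, j] <= hydrophobic_cutoff) {
      hp[[length(hp) + 1]] <- data.frame(
        chain_a = atoms$chain[i], resno_a = atoms$resno[i],
        atom_a = atoms$atom[i], chain_b = atoms$chain[j],
        resno_b = atoms$resno[j], atom_b = atoms$atom[j],
        distance = dmat[i, j], stringsAsFactors = FALSE)
    }
  }
  hydrophobic <- if (length(hp)) do.call(rbind, hp) else
    data.frame(chain_a = character(), resno_a = integer(),
               atom_a = character(), chain_b = character(),
               resno_b = integer(), atom_b = character(),
               distance = numeric())

  ord <- function(d) d[order(d$chain_a, d$resno_a, d$atom_a, d$chain_b,
                             d$resno_b, d$atom_b), , drop = FALSE]
  list(hbonds = ord(hbonds), hydrophobic = ord(hydrophobic))
}
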