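#' Read a macromolecular structure (PDB or mmCIF)
#'
#' Parses a coordinate file into a flat atom table.  Only the first model
#' of multi-model files is kept; alternate locations are reduced to the
#' highest-occupancy conformer per atom.  Waters and heteroatoms are
#' flagged rather than dropped, and phosphotyrosine (residue name `PTR`) is
#' treated as a peptide residue even though it is deposited as a
#' heteroatom.
#'
#' @param path Path to the coordinate file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return An object of class `structure_model`: list with `atoms` (data
#'   frame: `chain`, `resno`, `resid`, `atom`, `element`, `x`, `y`, `z`,
#'   `occupancy`, `altloc`, `is_het`, `is_water`) and `model_id`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "pdb") bio3d::read.pdb(path, multi = FALSE,
                                           rm.alt = FALSE, verbose = FALSE)
      else bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                           verbose = FALSE)),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e)))
  a <- parsed$atom
  element <- a$elesy
  if (is.null(element)) element <- rep("", nrow(a))
  guess <- toupper(substr(gsub("[^A-Za-z].*", "", a$elety), 1, 1))
  element <- ifelse(is.na(element) | element == "", guess, toupper(trimws(element)))
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno,
    resid = a$resid,
    atom = a$elety,
    element = element,
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    altloc = ifelse(is.na(a$alt) | a$alt == "", "", a$alt),
    is_het = a$type == "HETATM" & a$resid != "PTR",
    is_water = a$resid %in% c("HOH", "WAT", "DOD"),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x + atoms$y + atoms$z))) {
    stop("non-finite coordinates in ", path)
  }
  atoms <- resolve_altloc(atoms)
  structure(list(atoms = atoms, model_id = basename(path)),
            class = "structure_model")
}

# keep the highest-occupancy altloc per (chain, resno, atom); ties -> first
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$resid, atoms$atom, sep = "|")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, ]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$resid,
                                   atoms$atom, sep = "|")), ]
  atoms[order(atoms$chain, atoms$resno, atoms$atom), ]
}

#' Build a structure model from an atom table
#'
#' Lightweight constructor used by the toy-complex generator and tests.
#'
#' @param atoms Data frame with at least `chain`, `resno`, `resid`, `atom`,
#'   `element`, `x`, `y`, `z`; `occupancy`, `altloc`, `is_het`, `is_water`
#'   are filled with defaults if absent.
#' @param model_id Identifier string.
#' @return A `structure_model`.
#' @export
structure_model <- function(atoms, model_id = "model") {
  need <- c("chain", "resno", "resid", "atom", "element", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$is_het)) atoms$is_het <- FALSE
  if (is.null(atoms$is_water)) atoms$is_water <- atoms$resid %in% c("HOH", "WAT")
  if (any(!is.finite(atoms$x + atoms$y + atoms$z))) {
    stop("coordinates must be finite")
  }
  xyz <- paste(atoms$x, atoms$y, atoms$z)
  if (anyDuplicated(xyz)) stop("overlapping identical atom coordinates")
  structure(list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
                 model_id = model_id),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("Structure model [", x$model_id, "]: ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$chain)), " chain(s)\n", sep = "")
  invisible(x)
}

#' Write a structure model to PDB or mmCIF
#'
#' Minimal writers sufficient for round-tripping toy models through
#' [read_structure()]; not intended for deposition-grade output.
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  a <- model$atoms
  if (format == "pdb") {
    rec <- ifelse(a$is_het | a$is_water, "HETATM", "ATOM  ")
    name4 <- ifelse(nchar(a$atom) < 4, sprintf(" %-3s", a$atom),
                    sprintf("%-4s", a$atom))
    lines <- sprintf("%s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rec, seq_len(nrow(a)), name4, a$altloc, a$resid,
                     a$chain, a$resno, a$x, a$y, a$z, a$occupancy, 0,
                     a$element)
    writeLines(c(lines, "END"), path)
  } else {
    hdr <- c(paste0("data_", gsub("[^A-Za-z0-9]", "_", model$model_id)),
             "#", "loop_",
             "_atom_site.group_PDB", "_atom_site.id",
             "_atom_site.type_symbol", "_atom_site.label_atom_id",
             "_atom_site.label_alt_id", "_atom_site.label_comp_id",
             "_atom_site.label_asym_id", "_atom_site.label_entity_id",
             "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
             "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
             "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
             "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
             "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
             "_atom_site.pdbx_PDB_model_num")
    rec <- ifelse(a$is_het | a$is_water, "HETATM", "ATOM")
    alt <- ifelse(a$altloc == "", ".", a$altloc)
    rows <- sprintf("%s %d %s %s %s %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
                    rec, seq_len(nrow(a)), a$element, a$atom, alt, a$resid,
                    a$chain, a$resno, a$x, a$y, a$z, a$occupancy, 0,
                    a$resno, a$resid, a$chain, a$atom)
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}

#' Distance between two named atoms
#'
#' Euclidean distance (Angstrom) between one atom in each of two residues,
#' e.g. the C-alpha--C-alpha separation of two phosphotyrosines.
#'
#' @param model A `structure_model`.
#' @param chain_a,resno_a Chain id and residue number of the first residue.
#' @param chain_b,resno_b Chain id and residue number of the second.
#' @param atom_name Atom name (default `"CA"`).
#' @return Distance in Angstrom.
#' @export
residue_distance <- function(model, chain_a, resno_a, chain_b, resno_b,
                             atom_name = "CA") {
  pick <- function(ch, rn) {
    a <- model$atoms
    hit <- a[a$chain == ch & a$resno == rn & a$atom == atom_name, ]
    if (nrow(hit) == 0) {
      stop("atom ", atom_name, " not found in residue ", ch, "/", rn)
    }
    c(hit$x[1], hit$y[1], hit$z[1])
  }
  sqrt(sum((pick(chain_a, resno_a) - pick(chain_b, resno_b))^2))
}
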