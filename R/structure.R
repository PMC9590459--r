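# Minimal fixed-column PDB handling and Shrake-Rupley solvent accessibility.
# Only the fields the pipeline consumes are parsed; the first model is kept,
# alternate locations other than '' / 'A' and hydrogens are dropped.

# Van der Waals radii (Angstrom) by element; heme iron gets 2.0.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               FE = 2.00, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
VDW_DEFAULT <- 1.70

# Theoretical maximum accessible surface areas (Angstrom^2) per residue type
# (Tien et al. 2013, theoretical column), used as RSA denominators.
MAX_ASA <- c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0,
             CYS = 167.0, GLN = 225.0, GLU = 223.0, GLY = 104.0,
             HIS = 224.0, ILE = 197.0, LEU = 201.0, LYS = 236.0,
             MET = 224.0, PHE = 240.0, PRO = 159.0, SER = 155.0,
             THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records of the first model; keeps altloc `''` or `'A'`
#' only and ignores hydrogens. HETATM residues whose name is in
#' `ligand_codes` are flagged as ligand atoms (heme `HEM` by default; add the
#' substrate code for docked models). Elements missing from columns 77-78
#' are inferred from the atom name with a warning.
#'
#' @param path PDB file path.
#' @param ligand_codes Character vector of HETATM residue names treated as
#'   ligands.
#' @return Object of class `Structure`: data.frame `atoms` with columns
#'   `serial`, `name`, `resname`, `chain`, `resno`, `x`, `y`, `z`,
#'   `element`, `is_ligand`.
#' @export
read_structure <- function(path, ligand_codes = c("HEM")) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl) > 0L) lines <- lines[seq_len(endmdl[1L] - 1L)]
  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | rec == "HETATM"
  lines <- lines[keep]
  if (length(lines) == 0L || !any(rec == "ATOM  ")) {
    stop("no ATOM records in ", path)
  }
  fx <- function(a, b) trimws(substr(lines, a, b))
  atoms <- data.frame(
    record = fx(1, 6),
    serial = as.integer(fx(7, 11)),
    name = fx(13, 16),
    altloc = fx(17, 17),
    resname = fx(18, 20),
    chain = fx(22, 22),
    resno = as.integer(fx(23, 26)),
    x = as.numeric(fx(31, 38)),
    y = as.numeric(fx(39, 46)),
    z = as.numeric(fx(47, 54)),
    element = toupper(fx(77, 78)))
  atoms <- atoms[atoms$altloc %in% c("", "A"), , drop = FALSE]
  miss <- !nzchar(atoms$element)
  if (any(miss)) {
    warning(sprintf("%d atom(s) lack an element field; inferred from name",
                    sum(miss)))
    atoms$element[miss] <- element_from_name(atoms$name[miss])
  }
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in ", path)
  }
  atoms$is_ligand <- atoms$record == "HETATM" & atoms$resname %in% ligand_codes
  atoms$record <- NULL
  atoms$altloc <- NULL
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, ligand_codes = ligand_codes),
            class = "Structure")
}

element_from_name <- function(name) {
  two <- toupper(substr(name, 1, 2))
  one <- toupper(substr(gsub("^[0-9]", "", name), 1, 1))
  ifelse(two %in% c("FE", "CL", "BR"), two, one)
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms (%d ligand), %d residues\n",
              nrow(x$atoms), sum(x$atoms$is_ligand),
              length(unique(paste(x$atoms$chain,
                                  x$atoms$resno)[!x$atoms$is_ligand]))))
  invisible(x)
}

#' Write a structure as PDB
#'
#' @param s A `Structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "Structure"))
  a <- s$atoms
  rec <- ifelse(a$is_ligand, "HETATM", "ATOM  ")
  lines <- sprintf(
    "%s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, a$serial, a$name, a$resname, a$chain, a$resno,
    a$x, a$y, a$z, 1, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# Quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' For each atom, the fraction of `n_points` quasi-uniform sphere points at
#' radius `r_vdw + probe` not inside any neighbor's expanded sphere, times
#' the analytic sphere area. By default ligand atoms are excluded as
#' occluders so the result is protein-only accessibility (the pocket would
#' otherwise appear buried under the docked substrate); set
#' `ligand_occluders = TRUE` to include them. SASA is still reported for
#' ligand atoms themselves.
#'
#' @param s A `Structure`.
#' @param probe Probe radius in Angstrom; default 1.4 (water).
#' @param n_points Sphere points per atom (>= 100); default 960.
#' @param ligand_occluders Should ligand atoms occlude? Default `FALSE`.
#' @param radii Optional per-atom van der Waals radii overriding the element
#'   table (recycled to the atom count).
#' @return Numeric vector, one SASA (Angstrom^2) per atom row of `s$atoms`.
#' @export
atom_sasa <- function(s, probe = 1.4, n_points = 960,
                      ligand_occluders = FALSE, radii = NULL) {
  stopifnot(inherits(s, "Structure"))
  if (probe <= 0) stop("probe radius must be positive")
  if (n_points < 100) stop("n_points must be >= 100")
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- if (is.null(radii)) vdw_radius(a$element) else
    rep_len(radii, nrow(a))
  rad <- rad + probe
  occ <- if (ligand_occluders) rep(TRUE, nrow(a)) else !a$is_ligand
  pts <- fibonacci_sphere(n_points)
  n <- nrow(a)
  out <- numeric(n)
  rmax <- max(rad)
  for (k in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[k, ])^2)
    nb <- which(occ & d2 < (rad[k] + rmax)^2 & seq_len(n) != k)
    nb <- nb[d2[nb] < (rad[k] + rad[nb])^2]
    if (length(nb) == 0L) {
      out[k] <- 4 * pi * rad[k]^2
      next
    }
    sp <- pts * rad[k]
    sp <- sweep(sp, 2L, xyz[k, ], "+")
    # point accessible iff outside every neighbor's expanded sphere
    acc <- rep(TRUE, n_points)
    for (m in nb) {
      if (!any(acc)) break
      dd <- (sp[acc, 1L] - xyz[m, 1L])^2 + (sp[acc, 2L] - xyz[m, 2L])^2 +
        (sp[acc, 3L] - xyz[m, 3L])^2
      acc[acc] <- dd >= rad[m]^2
    }
    out[k] <- 4 * pi * rad[k]^2 * sum(acc) / n_points
  }
  out
}

#' Per-residue relative solvent accessibility
#'
#' RSA of a residue is the sum of its atoms' SASA divided by the theoretical
#' maximum accessible area for that residue type (Tien et al. values).
#' Ligand residues are skipped; residue types without a reference value are
#' excluded with a warning. RSA may slightly exceed 1 for terminal or
#' unusually exposed residues.
#'
#' @param s A `Structure`.
#' @param atom_areas Result of [atom_sasa()] on `s`.
#' @return data.frame `chain`, `resno`, `resname`, `sasa`, `rsa`.
#' @export
residue_rsa <- function(s, atom_areas) {
  stopifnot(inherits(s, "Structure"))
  a <- s$atoms
  if (length(atom_areas) != nrow(a)) {
    stop("atom_areas length does not match atom count")
  }
  prot <- !a$is_ligand
  key <- paste(a$chain[prot], a$resno[prot], sep = "|")
  agg <- rowsum(atom_areas[prot], key, reorder = FALSE)
  first <- !duplicated(key)
  df <- data.frame(chain = a$chain[prot][first], resno = a$resno[prot][first],
                   resname = a$resname[prot][first],
                   sasa = agg[match(unique(key), rownames(agg)), 1L])
  ref <- MAX_ASA[df$resname]
  unknown <- is.na(ref)
  if (any(unknown)) {
    warning(sprintf("residue type(s) %s lack a reference area; excluded",
                    paste(unique(df$resname[unknown]), collapse = ", ")))
  }
  df$rsa <- df$sasa / unname(ref)
  df <- df[!unknown, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Classify residues by burial and active-pocket membership
#'
#' Burial class: `surface` if RSA >= `surface_min`, `buried` if RSA <=
#' `buried_max`, else `semi-exposed`. A residue is in the pocket when any of
#' its heavy atoms lies within `pocket_cutoff` of any ligand atom;
#' `min_ligand_distance` is `Inf` when the structure has no ligand.
#'
#' @param s A `Structure`.
#' @param rsa Result of [residue_rsa()].
#' @param surface_min Surface RSA threshold; default 0.25.
#' @param buried_max Buried RSA threshold; default 0.05.
#' @param pocket_cutoff Heavy-atom distance cutoff (Angstrom); default 6.
#' @return data.frame `residue_number`, `chain`, `resname`, `rsa`,
#'   `burial_class`, `pocket`, `min_ligand_distance` (class
#'   `ResidueEnvironment`).
#' @export
classify_residues <- function(s, rsa, surface_min = 0.25, buried_max = 0.05,
                              pocket_cutoff = 6.0) {
  stopifnot(inherits(s, "Structure"))
  if (surface_min <= buried_max) stop("surface_min must exceed buried_max")
  a <- s$atoms
  lig <- as.matrix(a[a$is_ligand, c("x", "y", "z"), drop = FALSE])
  mind <- vapply(seq_len(nrow(rsa)), function(r) {
    sel <- !a$is_ligand & a$chain == rsa$chain[r] & a$resno == rsa$resno[r]
    if (nrow(lig) == 0L) return(Inf)
    xyz <- as.matrix(a[sel, c("x", "y", "z"), drop = FALSE])
    sqrt(min(vapply(seq_len(nrow(xyz)), function(i)
      min(colSums((t(lig) - xyz[i, ])^2)), numeric(1))))
  }, numeric(1))
  cls <- ifelse(rsa$rsa >= surface_min, "surface",
                ifelse(rsa$rsa <= buried_max, "buried", "semi-exposed"))
  out <- data.frame(residue_number = rsa$resno, chain = rsa$chain,
                    resname = rsa$resname, rsa = rsa$rsa,
                    burial_class = cls, pocket = mind <= pocket_cutoff,
                    min_ligand_distance = mind)
  class(out) <- c("ResidueEnvironment", "data.frame")
  out
}

#' Write a residue environment table as TSV
#'
#' @param env A [classify_residues()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_environment <- function(env, path) {
  utils::write.table(as.data.frame(env), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
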