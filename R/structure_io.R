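#' @importFrom stats prcomp qnorm pnorm runif rnorm qbeta dist sd setNames
#' @importFrom utils read.csv write.csv head combn
NULL

# Standard proteinogenic residues and common modified (noncanonical) amino
# acids observed as HETATM polymer components in the PDB. The latter stay in
# the receptor with canonical_flag = FALSE; everything else non-water becomes
# a ligand candidate.
.CANONICAL_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                   "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                   "THR", "TRP", "TYR", "VAL")
.NONCANONICAL_AA <- c("MSE", "SEP", "TPO", "PTR", "CSO", "CSD", "CME", "CSX",
                      "MLY", "M3L", "HYP", "KCX", "PCA", "LLP", "CGU", "OCS",
                      "SMC", "ALY", "FME", "MHO", "NEP", "HIC", "AIB", "DAL")
.WATER <- c("HOH", "WAT", "DOD", "H2O", "DIS")

.AA321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V", MSE = "M", SEP = "S", TPO = "T", PTR = "Y")

# Single-bond covalent radii (Angstrom) used for distance-based bond
# perception of ligands extracted from coordinate-only formats.
.COV_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, P = 1.07,
                S = 1.05, CL = 1.02, BR = 1.20, I = 1.39, B = 0.84, SE = 1.20)

#' Construct a receptor structure
#'
#' A `ReceptorStructure` bundles the polymer part of a parsed coordinate
#' file: a residue table (chain, residue number, 3-letter code, canonical
#' flag) and an atom table referencing those residues by (chain, resno).
#'
#' @param structure_id character identifier (e.g. PDB code or file stem).
#' @param residues data.frame with columns `chain`, `resno`, `resid`,
#'   `canonical`.
#' @param atoms data.frame with columns `chain`, `resno`, `name`, `element`,
#'   `x`, `y`, `z`.
#' @return An object of class `ReceptorStructure`.
#' @export
receptor_structure <- function(structure_id, residues, atoms) {
  stopifnot(is.data.frame(residues), is.data.frame(atoms))
  req_r <- c("chain", "resno", "resid", "canonical")
  req_a <- c("chain", "resno", "name", "element", "x", "y", "z")
  if (!all(req_r %in% names(residues)))
    stop("residues must have columns: ", paste(req_r, collapse = ", "))
  if (!all(req_a %in% names(atoms)))
    stop("atoms must have columns: ", paste(req_a, collapse = ", "))
  if (nrow(residues) == 0) stop("empty receptor: no polymer residues")
  if (anyDuplicated(residues[, c("chain", "resno")]))
    stop("residue numbers must be unique within a chain")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  rkey <- paste(residues$chain, residues$resno)
  akey <- paste(atoms$chain, atoms$resno)
  if (!all(akey %in% rkey))
    stop("every atom must reference an existing residue")
  structure(list(structure_id = structure_id,
                 chains = unique(residues$chain),
                 residues = residues, atoms = atoms),
            class = "ReceptorStructure")
}

#' @export
print.ReceptorStructure <- function(x, ...) {
  cat(sprintf("ReceptorStructure %s: %d chain(s), %d residues, %d atoms (%d noncanonical)\n",
              x$structure_id, length(x$chains), nrow(x$residues),
              nrow(x$atoms), sum(!x$residues$canonical)))
  invisible(x)
}

#' Construct a ligand instance
#'
#' @param comp_id chemical component identifier (uppercased).
#' @param atoms data.frame with columns `name`, `element`, `charge`, `x`,
#'   `y`, `z` (coordinates may be `NA` for topology-only ligands).
#' @param bonds data.frame with columns `a1`, `a2`, `order`, or `NULL`.
#' @param smiles optional SMILES string.
#' @return An object of class `LigandInstance`.
#' @export
ligand_instance <- function(comp_id, atoms, bonds = NULL, smiles = NULL) {
  stopifnot(is.data.frame(atoms))
  req <- c("name", "element", "charge", "x", "y", "z")
  if (!all(req %in% names(atoms)))
    stop("atoms must have columns: ", paste(req, collapse = ", "))
  atoms$element <- toupper(atoms$element)
  if (sum(atoms$element != "H") < 1) stop("ligand must have >= 1 heavy atom")
  if (abs(sum(atoms$charge) - round(sum(atoms$charge))) > 1e-9)
    stop("sum of formal charges must be an integer")
  if (is.null(bonds))
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  if (nrow(bonds) > 0 &&
      (max(bonds$a1, bonds$a2) > nrow(atoms) || min(bonds$a1, bonds$a2) < 1))
    stop("bond indices out of range")
  structure(list(comp_id = toupper(comp_id), atoms = atoms, bonds = bonds,
                 smiles = smiles),
            class = "LigandInstance")
}

#' @export
print.LigandInstance <- function(x, ...) {
  cat(sprintf("LigandInstance %s: %d atoms (%d heavy), %d bonds, net charge %+d\n",
              x$comp_id, nrow(x$atoms), sum(x$atoms$element != "H"),
              nrow(x$bonds), as.integer(round(sum(x$atoms$charge)))))
  invisible(x)
}

#' Heavy-atom coordinate matrix of a ligand
#' @param ligand a `LigandInstance`.
#' @return numeric matrix (n x 3).
#' @export
heavy_coords <- function(ligand) {
  keep <- ligand$atoms$element != "H"
  as.matrix(ligand$atoms[keep, c("x", "y", "z")])
}

#' Exclusion list of chemical components
#'
#' @param comp_ids character vector of component identifiers to reject.
#' @return object of class `ExclusionList`.
#' @export
exclusion_list <- function(comp_ids) {
  comp_ids <- toupper(trimws(comp_ids))
  comp_ids <- comp_ids[nzchar(comp_ids)]
  structure(list(comp_ids = unique(comp_ids)), class = "ExclusionList")
}

#' Default exclusion list shipped with the package
#'
#' Common ions, buffer components and cryoprotectants (one identifier per
#' line in `extdata/exclusion_comp_ids.txt`). Users may substitute any other
#' list, e.g. the one used by modern cofolding pipelines.
#' @return an `ExclusionList`.
#' @export
default_exclusion_list <- function() {
  path <- system.file("extdata", "exclusion_comp_ids.txt", package = "allokin")
  lines <- readLines(path)
  exclusion_list(lines[!grepl("^\\s*#", lines)])
}

# Pick one altloc per (chain, resno, atom name): highest occupancy, ties by
# altloc identifier order.
.resolve_altloc <- function(atom) {
  if (!"alt" %in% names(atom)) return(atom)
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  occ <- if ("o" %in% names(atom)) atom$o else rep(1, nrow(atom))
  occ[is.na(occ)] <- 1
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "\r")
  ord <- order(key, -occ, alt)
  atom <- atom[ord, , drop = FALSE]
  atom[!duplicated(key[ord]), , drop = FALSE]
}

.element_from_name <- function(name) {
  el <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]*", "", name))
  el <- toupper(substr(el, 1, 2))
  two <- c("CL", "BR", "SE", "FE", "ZN", "MG", "MN", "NA", "CA", "CU", "NI", "CO")
  ifelse(el %in% two, el, substr(el, 1, 1))
}

#' Read a macromolecular structure and extract ligand candidates
#'
#' Parses a PDB or mmCIF file, keeps the polymer as a `ReceptorStructure`
#' (noncanonical amino-acid components stay in the polymer, flagged), drops
#' waters, and returns every remaining non-polymer component occurrence as a
#' `LigandInstance`. Two copies of the same compound in the asymmetric unit
#' yield two instances. Alternate locations are resolved to the
#' highest-occupancy conformer.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param renumber optional named integer vector mapping old residue numbers
#'   to new ones (applied to polymer residues).
#' @return list with elements `receptor` (`ReceptorStructure`) and `ligands`
#'   (list of `LigandInstance`).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           renumber = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("unparseable ", format, " file: ",
                             conditionMessage(e)))
  atom <- .resolve_altloc(parsed$atom)
  atom$resid <- toupper(atom$resid)
  atom <- atom[!(atom$resid %in% .WATER), , drop = FALSE]
  el <- if ("elesy" %in% names(atom) && !all(is.na(atom$elesy)))
    toupper(atom$elesy) else .element_from_name(atom$elety)
  el[is.na(el) | !nzchar(el)] <- .element_from_name(atom$elety[is.na(el) | !nzchar(el)])
  atom$element <- el
  atom$chain[is.na(atom$chain)] <- "A"

  is_poly <- atom$type == "ATOM" & atom$resid %in% .CANONICAL_AA
  is_noncan <- atom$resid %in% .NONCANONICAL_AA
  poly <- atom[is_poly | is_noncan, , drop = FALSE]
  het <- atom[!(is_poly | is_noncan), , drop = FALSE]

  if (nrow(poly) == 0) stop("empty receptor: no protein residues in ", path)

  if (!is.null(renumber)) {
    idx <- match(as.character(poly$resno), names(renumber))
    poly$resno[!is.na(idx)] <- unname(renumber[idx[!is.na(idx)]])
  }

  rkey <- !duplicated(paste(poly$chain, poly$resno))
  residues <- data.frame(chain = poly$chain[rkey], resno = poly$resno[rkey],
                         resid = poly$resid[rkey],
                         canonical = poly$resid[rkey] %in% .CANONICAL_AA,
                         stringsAsFactors = FALSE)
  atoms <- data.frame(chain = poly$chain, resno = poly$resno,
                      name = poly$elety, element = poly$element,
                      x = poly$x, y = poly$y, z = poly$z,
                      stringsAsFactors = FALSE)
  receptor <- receptor_structure(
    structure_id = sub("\\.[^.]*$", "", basename(path)),
    residues = residues, atoms = atoms)

  ligands <- list()
  if (nrow(het) > 0) {
    grp <- paste(het$chain, het$resno, het$resid, sep = "\r")
    for (g in unique(grp)) {
      sub <- het[grp == g, , drop = FALSE]
      la <- data.frame(name = sub$elety, element = sub$element,
                       charge = 0, x = sub$x, y = sub$y, z = sub$z,
                       stringsAsFactors = FALSE)
      lig <- ligand_instance(sub$resid[1], la,
                             bonds = perceive_bonds(la))
      lig$chain <- sub$chain[1]
      lig$resno <- sub$resno[1]
      ligands <- c(ligands, list(lig))
    }
  }
  list(receptor = receptor, ligands = ligands)
}

#' Distance-based bond perception
#'
#' Assigns single bonds between atom pairs closer than the sum of their
#' covalent radii plus a tolerance. Used for ligands extracted from
#' coordinate-only records (PDB HETATM without CONECT).
#'
#' @param atoms data.frame with `element`, `x`, `y`, `z`.
#' @param tol tolerance added to the radii sum (default 0.45 A).
#' @return data.frame with columns `a1`, `a2`, `order` (all 1).
#' @export
perceive_bonds <- function(atoms, tol = 0.45) {
  n <- nrow(atoms)
  if (n < 2 || any(is.na(atoms$x)))
    return(data.frame(a1 = integer(0), a2 = integer(0), order = integer(0)))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- .COV_RADII[toupper(atoms$element)]
  rad[is.na(rad)] <- 1.2
  d <- as.matrix(dist(xyz))
  lim <- outer(rad, rad, "+") + tol
  hit <- which(d < lim & upper.tri(d), arr.ind = TRUE)
  data.frame(a1 = hit[, 1], a2 = hit[, 2],
             order = rep(1L, nrow(hit)))
}

#' Write a receptor (and optional ligands) to a PDB file
#'
#' @param receptor a `ReceptorStructure`.
#' @param path output file path.
#' @param ligands optional list of `LigandInstance` written as HETATM.
#' @return `path`, invisibly.
#' @export
write_structure <- function(receptor, path, ligands = NULL) {
  a <- receptor$atoms
  res <- receptor$residues
  resid <- res$resid[match(paste(a$chain, a$resno), paste(res$chain, res$resno))]
  can <- res$canonical[match(paste(a$chain, a$resno), paste(res$chain, res$resno))]
  type <- ifelse(can, "ATOM", "HETATM")
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  resno <- a$resno; chain <- a$chain; elety <- a$name
  if (!is.null(ligands) && length(ligands)) {
    base_res <- max(resno) + 10L
    for (i in seq_along(ligands)) {
      lg <- ligands[[i]]
      hv <- lg$atoms
      xyz <- c(xyz, as.numeric(t(as.matrix(hv[, c("x", "y", "z")]))))
      type <- c(type, rep("HETATM", nrow(hv)))
      resid <- c(resid, rep(lg$comp_id, nrow(hv)))
      resno <- c(resno, rep(base_res + i, nrow(hv)))
      chain <- c(chain, rep("X", nrow(hv)))
      elety <- c(elety, hv$name)
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, type = type, resno = resno,
                   resid = resid, chain = chain, elety = elety,
                   eleno = seq_along(type))
  invisible(path)
}

#' Filter ligand candidates by exclusion list and size
#'
#' Removes components that appear on the exclusion list (ions, buffers,
#' cryoprotectants such as glycerol) or that have fewer heavy atoms than the
#' cutoff. Input order is preserved; the operation is idempotent.
#'
#' @param ligands list of `LigandInstance`.
#' @param excl an `ExclusionList`.
#' @param min_heavy_atoms minimum heavy-atom count (default 6).
#' @return filtered list of `LigandInstance`.
#' @export
filter_ligands <- function(ligands, excl = default_exclusion_list(),
                           min_heavy_atoms = 6) {
  keep <- vapply(ligands, function(l) {
    !(l$comp_id %in% excl$comp_ids) &&
      sum(l$atoms$element != "H") >= min_heavy_atoms
  }, logical(1))
  ligands[keep]
}

#' Ligand extraction manifest
#'
#' @param structure_id structure identifier.
#' @param ligands list of `LigandInstance` (pre-filtering).
#' @param excl an `ExclusionList`.
#' @param min_heavy_atoms size cutoff used by [filter_ligands()].
#' @return data.frame with columns `structure_id`, `comp_id`, `chain`,
#'   `heavy_atoms`, `excluded`, `reason`.
#' @export
ligand_manifest <- function(structure_id, ligands,
                            excl = default_exclusion_list(),
                            min_heavy_atoms = 6) {
  if (!length(ligands))
    return(data.frame(structure_id = character(0), comp_id = character(0),
                      chain = character(0), heavy_atoms = integer(0),
                      excluded = logical(0), reason = character(0)))
  rows <- lapply(ligands, function(l) {
    nh <- sum(l$atoms$element != "H")
    in_excl <- l$comp_id %in% excl$comp_ids
    small <- nh < min_heavy_atoms
    data.frame(structure_id = structure_id, comp_id = l$comp_id,
               chain = if (!is.null(l$chain)) l$chain else NA_character_,
               heavy_atoms = nh, excluded = in_excl || small,
               reason = if (in_excl) "exclusion_list"
                        else if (small) "too_few_heavy_atoms" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Flag ligand proximity to noncanonical residues
#'
#' TRUE iff any ligand heavy atom lies strictly within `cutoff` of any atom
#' belonging to a residue flagged noncanonical.
#'
#' @param receptor a `ReceptorStructure`.
#' @param ligand a `LigandInstance`.
#' @param cutoff distance cutoff in Angstrom (default 5).
#' @return logical scalar.
#' @export
flag_noncanonical_proximity <- function(receptor, ligand, cutoff = 5) {
  stopifnot(cutoff > 0)
  res <- receptor$residues
  nc <- res[!res$canonical, , drop = FALSE]
  if (nrow(nc) == 0) return(FALSE)
  akey <- paste(receptor$atoms$chain, receptor$atoms$resno)
  nckey <- paste(nc$chain, nc$resno)
  rec_xyz <- as.matrix(receptor$atoms[akey %in% nckey, c("x", "y", "z")])
  lig_xyz <- heavy_coords(ligand)
  if (nrow(rec_xyz) == 0 || nrow(lig_xyz) == 0) return(FALSE)
  min(.cross_dist(lig_xyz, rec_xyz)) < cutoff
}

# All pairwise Euclidean distances between two coordinate matrices.
.cross_dist <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

# ---- ligand I/O through ChemmineR / OpenBabel -------------------------------

# Old-style SDF atom-block charge codes.
.SDF_CHG <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L,
              `6` = -2L, `7` = -3L)

# Fallback for V2000 records ChemmineR rejects (e.g. bond-less molecules):
# fixed-column read of the counts/atom/bond lines.
.molfile_to_ligand <- function(lines, comp_id = "LIG", smiles = NULL) {
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3)); nb <- as.integer(substr(counts, 4, 6))
  al <- lines[4 + seq_len(na)]
  atoms <- data.frame(
    name = character(na),
    element = toupper(trimws(substr(al, 32, 34))),
    charge = unname(.SDF_CHG[as.character(as.integer(substr(al, 37, 39)))]),
    x = as.numeric(substr(al, 1, 10)), y = as.numeric(substr(al, 11, 20)),
    z = as.numeric(substr(al, 21, 30)), stringsAsFactors = FALSE)
  atoms$charge[is.na(atoms$charge)] <- 0L
  atoms$name <- paste0(atoms$element, seq_len(na))
  bonds <- if (nb > 0) {
    bl <- lines[4 + na + seq_len(nb)]
    data.frame(a1 = as.integer(substr(bl, 1, 3)),
               a2 = as.integer(substr(bl, 4, 6)),
               order = as.integer(substr(bl, 7, 9)))
  } else data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substring(ln, 7)), "[[:space:]]+")[[1]])
    for (k in seq_len(f[1])) atoms$charge[f[2 * k]] <- f[2 * k + 1]
  }
  ligand_instance(comp_id, atoms, bonds, smiles = smiles)
}

.sdf_to_ligand <- function(sdf, comp_id = "LIG", smiles = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(ab)) || ncol(ab) < 3 ||
      !all(grepl("^[A-Za-z]", rownames(ab))))
    return(.molfile_to_ligand(ChemmineR::sdf2str(sdf), comp_id, smiles))
  if (is.null(dim(ab))) ab <- matrix(ab, nrow = 1, dimnames = list(names(ab)[1], NULL))
  element <- toupper(gsub("_.*$", "", rownames(ab)))
  chg_col <- which(colnames(ab) == "C6")  # atom-block charge-code field
  charge <- if (length(chg_col) == 1) .SDF_CHG[as.character(ab[, chg_col])]
            else rep(0L, nrow(ab))
  charge[is.na(charge)] <- 0L
  # M CHG property lines override atom-block codes
  lines <- ChemmineR::sdf2str(sdf)
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    charge[] <- 0L
    for (ln in chg_lines) {
      f <- as.integer(strsplit(trimws(substring(ln, 7)), "[[:space:]]+")[[1]])
      n <- f[1]
      for (k in seq_len(n)) charge[f[2 * k]] <- f[2 * k + 1]
    }
  }
  atoms <- data.frame(
    name = paste0(element, seq_along(element)),
    element = element, charge = as.integer(charge),
    x = ab[, 1], y = ab[, 2], z = ab[, 3],
    stringsAsFactors = FALSE)
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0)
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  else data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                  order = as.integer(bb[, 3]))
  ligand_instance(comp_id, atoms, bonds, smiles = smiles)
}

#' Build a ligand from a SMILES string
#'
#' Parsed with OpenBabel (via ChemmineOB); 2-D coordinates are generated.
#'
#' @param smiles SMILES string.
#' @param comp_id component identifier for the resulting ligand.
#' @return a `LigandInstance`.
#' @export
ligand_from_smiles <- function(smiles, comp_id = "LIG") {
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e) stop("cannot parse SMILES '", smiles,
                                           "': ", conditionMessage(e)))
  if (suppressWarnings(ChemmineR::validSDF(sdf))[1])
    return(.sdf_to_ligand(sdf[[1]], comp_id = comp_id, smiles = smiles))
  # ChemmineR rejects bond-less records; take the converter's text directly
  txt <- ChemmineOB::convertFormat("SMILES", "SDF", smiles)
  .molfile_to_ligand(strsplit(txt, "\n")[[1]], comp_id = comp_id,
                     smiles = smiles)
}

#' Read ligands from an SDF file
#'
#' @param path SDF/MOL file path (may hold multiple records).
#' @return list of `LigandInstance`, in file order.
#' @export
read_ligands_sdf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- ChemmineR::read.SDFset(path)
  lapply(seq_along(set), function(i) {
    id <- ChemmineR::sdfid(set[i])
    if (is.na(id) || !nzchar(id)) id <- paste0("LIG", i)
    .sdf_to_ligand(set[[i]], comp_id = id)
  })
}

#' Write ligands to an SDF file
#'
#' @param ligands list of `LigandInstance`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ligands_sdf <- function(ligands, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (lg in ligands) {
    a <- lg$atoms
    xyz <- a[, c("x", "y", "z")]
    xyz[is.na(xyz)] <- 0
    writeLines(c(lg$comp_id, "  allokin", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), nrow(lg$bonds)), con)
    chg_code <- c(`3` = 1L, `2` = 2L, `1` = 3L, `0` = 0L, `-1` = 5L,
                  `-2` = 6L, `-3` = 7L)[as.character(a$charge)]
    chg_code[is.na(chg_code)] <- 0L
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                       xyz$x, xyz$y, xyz$z,
                       paste0(substr(a$element, 1, 1),
                              tolower(substr(a$element, 2, 2))), chg_code), con)
    if (nrow(lg$bonds))
      writeLines(sprintf("%3d%3d%3d  0  0  0  0",
                         lg$bonds$a1, lg$bonds$a2, lg$bonds$order), con)
    chg <- which(a$charge != 0)
    if (length(chg))
      writeLines(paste0("M  CHG", sprintf("%3d", length(chg)),
                        paste0(sprintf("%4d%4d", chg, a$charge[chg]),
                               collapse = "")), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}
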