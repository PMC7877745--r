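# IUPAC standard (average) atomic weights; the 1000 Da rule uses the average
# mass, matching the PDB formula-weight convention.
ATOMIC_WEIGHTS <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.098, Ca = 40.078, Mn = 54.938, Fe = 55.845, Co = 58.933, Ni = 58.693,
  Cu = 63.546, Zn = 65.38, As = 74.922, Se = 78.971, Br = 79.904, Mo = 95.95,
  Ru = 101.07, Ag = 107.87, Cd = 112.41, Sn = 118.71, I = 126.90, Pt = 195.08,
  Au = 196.97, Hg = 200.59
)

# Elements a drug-like ligand may contain; anything else disqualifies it.
ALLOWED_ELEMENTS <- c("C", "H", "N", "O", "S", "Br", "Cl", "F", "P", "Si", "B", "Se")

RESNAME_TO_BASE <- c(
  A = "A", C = "C", G = "G", U = "U",
  ADE = "A", CYT = "C", GUA = "G", URA = "U", URI = "U",
  RA = "A", RC = "C", RG = "G", RU = "U"
)

#' Construct a ligand molecule
#'
#' A minimal container for one small-molecule pose: an atom table
#' (element, coordinates in Angstrom, formal charge), a bond table
#' (1-based atom indices, bond order, aromatic flag) and a named character
#' vector of free-form per-pose properties (e.g. \code{E_GAFF}).
#'
#' @param atoms data.frame with columns \code{elem, x, y, z, charge}.
#' @param bonds data.frame with columns \code{i, j, order, aromatic}.
#' @param properties named character vector of pose properties.
#' @param name molecule title.
#' @return An object of class \code{"ligand"}.
#' @export
ligand <- function(atoms, bonds, properties = character(), name = "LIG") {
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  stopifnot(all(c("elem", "x", "y", "z") %in% names(atoms)))
  if (nrow(bonds) > 0) {
    bonds <- as.data.frame(bonds)
    if (is.null(bonds$aromatic)) bonds$aromatic <- bonds$order == 4
    if (any(bonds$i < 1 | bonds$j < 1 | bonds$i > nrow(atoms) | bonds$j > nrow(atoms)))
      stop_data("bond indices out of range in ligand '%s'", name)
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = numeric(),
                        aromatic = logical())
  }
  bad <- !atoms$elem %in% names(ATOMIC_WEIGHTS)
  if (any(bad))
    warning(sprintf("ligand '%s': unknown element symbol(s): %s", name,
                    paste(unique(atoms$elem[bad]), collapse = ", ")))
  structure(list(name = name, atoms = atoms, bonds = bonds,
                 properties = properties),
            class = "ligand")
}

#' @export
print.ligand <- function(x, ...) {
  cat(sprintf("<ligand '%s'> %d atoms (%d heavy), %d bonds, %d properties\n",
              x$name, nrow(x$atoms), sum(x$atoms$elem != "H"),
              nrow(x$bonds), length(x$properties)))
  invisible(x)
}

ligand_coords <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

ligand_set_coords <- function(mol, xyz) {
  mol$atoms[, c("x", "y", "z")] <- xyz
  mol
}

#' Read an RNA receptor structure from a PDB file
#'
#' Keeps the first MODEL of multi-model (NMR-style) files and, for atoms with
#' alternate locations, the first variant encountered.  Residue names are
#' mapped to canonical bases A/C/G/U (common synonyms ADE/CYT/GUA/URA are
#' recognised); anything else is flagged \code{"other"} and later excluded
#' from scoring.
#'
#' @param path PDB file.
#' @return An object of class \code{"rna_structure"}: a list with an
#'   \code{atoms} data.frame (chain, resno, ins, resname, base, atom, x, y, z).
#' @export
read_rna_pdb <- function(path) {
  if (!file.exists(path)) stop_data("cannot read PDB file '%s'", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop_data("format error in '%s': empty file", path)
  # first MODEL only
  endm <- grep("^ENDMDL", lines)
  if (length(endm) > 0) lines <- lines[seq_len(endm[1] - 1)]
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec))
    stop_data("format error in '%s': no ATOM/HETATM records (first line: '%s')",
              path, lines[1])
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- tryCatch(bio3d::read.pdb(tmp, verbose = FALSE),
                  error = function(e)
                    stop_data("format error in '%s': %s", path, conditionMessage(e)))
  at <- pdb$atom
  if (nrow(at) == 0)
    stop_data("format error in '%s': zero residues parsed (first line: '%s')",
              path, lines[1])
  at$insert[is.na(at$insert)] <- ""
  # first-altloc rule: keep the first occurrence of each atom name per residue
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  at <- at[!duplicated(key), , drop = FALSE]
  base <- unname(RESNAME_TO_BASE[at$resid])
  base[is.na(base)] <- "other"
  atoms <- data.frame(chain = at$chain, resno = at$resno, ins = at$insert,
                      resname = at$resid, base = base, atom = at$elety,
                      x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop_data("format error in '%s': non-finite coordinates", path)
  structure(list(atoms = atoms, source = path), class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  rid <- paste(x$atoms$chain, x$atoms$resno, x$atoms$ins)
  cat(sprintf("<rna_structure> %d residues, %d atoms (%d canonical-base residues)\n",
              length(unique(rid)), nrow(x$atoms),
              length(unique(rid[x$atoms$base != "other"]))))
  invisible(x)
}

bond_signature <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0) return(character())
  ord <- ifelse(b$aromatic, "ar", as.character(b$order))
  sort(paste(pmin(b$i, b$j), pmax(b$i, b$j), ord, sep = "-"))
}

#' Read a set of ligand poses
#'
#' One molecule per pose; all poses in a file must share the same bond graph
#' (same atoms in the same order, same bonds), which is checked.  SDF data
#' blocks become the per-pose property map.
#'
#' @param path input file.
#' @param format \code{"sdf"}, \code{"mol2"} or \code{"pdb"} (multi-MODEL);
#'   guessed from the extension when omitted.
#' @return list of \code{ligand} objects, pose order preserved.
#' @export
read_ligand_poses <- function(path, format = NULL) {
  if (!file.exists(path)) stop_data("cannot read ligand file '%s'", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- tolower(format)
  mols <- switch(format,
    sdf = read_poses_sdf(path),
    mol2 = read_poses_mol2(path),
    pdb = read_poses_pdb(path),
    stop_usage("unknown ligand format '%s' (use sdf, mol2 or pdb)", format))
  if (length(mols) == 0) stop_data("no molecules parsed from '%s'", path)
  n0 <- nrow(mols[[1]]$atoms)
  sig0 <- bond_signature(mols[[1]])
  el0 <- mols[[1]]$atoms$elem
  for (i in seq_along(mols)) {
    if (nrow(mols[[i]]$atoms) != n0 || !identical(mols[[i]]$atoms$elem, el0))
      stop_data("inconsistent atom counts/elements across poses in '%s' (pose %d)",
                path, i)
    if (!identical(bond_signature(mols[[i]]), sig0))
      stop_data("inconsistent bond graph across poses in '%s' (pose %d)", path, i)
  }
  mols
}

read_poses_sdf <- function(path) {
  sdfs <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                   error = function(e)
                     stop_data("format error in '%s': %s", path, conditionMessage(e)))
  # ChemmineR does not surface M CHG formal charges: recover them from the text
  raw <- readLines(path, warn = FALSE)
  blocks <- split(raw, cumsum(c(1, head(raw, -1) == "$$$$")))
  charges_per_block <- lapply(blocks, function(bl) {
    chg <- grep("^M  CHG", bl, value = TRUE)
    out <- list()
    for (line in chg) {
      f <- as.integer(strsplit(trimws(substring(line, 7)), "\\s+")[[1]])
      n <- f[1]
      for (k in seq_len(n)) out[[length(out) + 1]] <- f[c(2 * k, 2 * k + 1)]
    }
    out
  })
  lapply(seq_along(sdfs@SDF), function(m) {
    sdf <- sdfs@SDF[[m]]
    ab <- sdf@atomblock
    bb <- sdf@bondblock
    elem <- sub("_.*$", "", rownames(ab))
    atoms <- data.frame(elem = elem, x = ab[, 1], y = ab[, 2], z = ab[, 3],
                        charge = 0L, stringsAsFactors = FALSE, row.names = NULL)
    if (m <= length(charges_per_block))
      for (p in charges_per_block[[m]]) atoms$charge[p[1]] <- p[2]
    bonds <- if (nrow(bb) > 0)
      data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                 order = as.numeric(bb[, 3]), aromatic = bb[, 3] == 4)
    else NULL
    props <- sdf@datablock
    if (is.null(props)) props <- character()
    ligand(atoms, bonds, properties = props, name = sdf@header[["Molecule_Name"]])
  })
}

mol2_order <- function(type) {
  o <- suppressWarnings(as.numeric(type))
  o[type == "ar"] <- 1.5
  o[type == "am"] <- 1
  o[is.na(o)] <- 1
  o
}

read_poses_mol2 <- function(path) {
  m <- tryCatch(bio3d::read.mol2(path),
                error = function(e)
                  stop_data("format error in '%s': %s", path, conditionMessage(e)))
  if (inherits(m, "mol2")) m <- list(m)
  lapply(m, function(one) {
    elem <- sub("\\..*$", "", one$atom$elety)
    atoms <- data.frame(elem = elem, x = one$atom$x, y = one$atom$y,
                        z = one$atom$z, charge = 0L, stringsAsFactors = FALSE)
    bonds <- data.frame(i = as.integer(one$bond$origin),
                        j = as.integer(one$bond$target),
                        order = mol2_order(one$bond$type),
                        aromatic = one$bond$type == "ar")
    ligand(atoms, bonds, name = if (!is.null(one$name)) one$name else "LIG")
  })
}

# Covalent radii for distance-based bond inference in bare multi-MODEL PDB
# pose files (no CONECT trust); generous +0.45 A slack.
COV_RADII <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
               Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Se = 1.2, Br = 1.2, I = 1.39)

read_poses_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop_data("format error in '%s': no ATOM/HETATM records", path)
  model_id <- cumsum(grepl("^MODEL", lines)) + 1L
  if (!any(grepl("^MODEL", lines))) model_id <- rep(1L, length(lines))
  per_model <- split(lines[rec], model_id[rec])
  parse_model <- function(ml) {
    el <- trimws(substring(ml, 77, 78))
    noel <- el == ""
    el[noel] <- sub("[^A-Za-z].*$", "", trimws(substring(ml[noel], 13, 16)))
    el <- paste0(toupper(substring(el, 1, 1)), tolower(substring(el, 2)))
    data.frame(elem = el,
               x = as.numeric(substring(ml, 31, 38)),
               y = as.numeric(substring(ml, 39, 46)),
               z = as.numeric(substring(ml, 47, 54)),
               charge = 0L, stringsAsFactors = FALSE)
  }
  atoms1 <- parse_model(per_model[[1]])
  # infer a shared bond graph from the first model's geometry
  n <- nrow(atoms1)
  xyz <- as.matrix(atoms1[, c("x", "y", "z")])
  r <- COV_RADII[atoms1$elem]; r[is.na(r)] <- 0.77
  bi <- bj <- integer()
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      d <- sqrt(colSums((t(xyz[(i + 1):n, , drop = FALSE]) - xyz[i, ])^2))
      hit <- which(d < r[i] + r[(i + 1):n] + 0.45 & d > 0.4)
      bi <- c(bi, rep(i, length(hit))); bj <- c(bj, i + hit)
    }
  }
  bonds <- data.frame(i = bi, j = bj, order = 1, aromatic = FALSE)
  lapply(per_model, function(ml) ligand(parse_model(ml), bonds, name = "LIG"))
}

#' Write ligand poses to an SDF (V2000) file
#'
#' Formal charges are emitted as \code{M CHG} lines and the property map as
#' SDF data blocks, so a write/read cycle preserves atoms, bonds, charges and
#' properties.
#'
#' @param mols a \code{ligand} or list of them.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_ligand_sdf <- function(mols, path) {
  if (inherits(mols, "ligand")) mols <- list(mols)
  out <- character()
  for (mol in mols) {
    a <- mol$atoms; b <- mol$bonds
    lines <- c(mol$name, "  rligscore", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), nrow(b)))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              a$x, a$y, a$z, a$elem))
    if (nrow(b) > 0)
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", b$i, b$j,
                                ifelse(b$aromatic, 4L, as.integer(round(b$order)))))
    chg <- which(a$charge != 0)
    if (length(chg) > 0)
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                               paste0(sprintf("%4d%4d", chg, a$charge[chg]),
                                      collapse = "")))
    lines <- c(lines, "M  END")
    for (nm in names(mol$properties))
      lines <- c(lines, sprintf(">  <%s>", nm), mol$properties[[nm]], "")
    out <- c(out, lines, "$$$$")
  }
  writeLines(out, path)
  invisible(path)
}

#' Ligand eligibility under the drug-like filters
#'
#' A ligand is eligible when every element is in the allowed set
#' (C, H, N, O, S, Br, Cl, F, P, Si, B, Se), both carbon and hydrogen are
#' present, and the average molecular mass is at most 1000 Da.
#'
#' @param mol a \code{ligand}.
#' @return list with \code{eligible} (logical) and \code{reasons}
#'   (character vector among \code{"element"}, \code{"no_carbon"},
#'   \code{"no_hydrogen"}, \code{"mass"}; empty iff eligible).
#' @export
ligand_eligible <- function(mol) {
  if (nrow(mol$atoms) < 1) stop_data("ligand has no atoms")
  el <- mol$atoms$elem
  reasons <- character()
  if (any(!el %in% ALLOWED_ELEMENTS)) reasons <- c(reasons, "element")
  if (!"C" %in% el) reasons <- c(reasons, "no_carbon")
  if (!"H" %in% el) reasons <- c(reasons, "no_hydrogen")
  w <- ATOMIC_WEIGHTS[el]
  mass <- sum(w, na.rm = TRUE)
  if (mass > 1000) reasons <- c(reasons, "mass")
  list(eligible = length(reasons) == 0, reasons = reasons, mass = mass)
}
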