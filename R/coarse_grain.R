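# Coarse-grained representations: five beads per ribonucleotide, six
# pharmacophore types (with direction vectors for AROM/HDON/HACC) per ligand.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "U")

BEAD_NAMES <- list(
  A = c("P", "C4'", "N9", "C2", "C6"),
  G = c("P", "C4'", "N9", "C2", "C6"),
  C = c("P", "C4'", "N1", "C2", "C4"),
  U = c("P", "C4'", "N1", "C2", "C4")
)

# Ordered triplet of base atoms defining the plane normal (cross-product
# sign is fixed by this ordering).
PLANE_TRIPLET <- list(
  A = c("C2", "C6", "N9"), G = c("C2", "C6", "N9"),
  C = c("C2", "C4", "N1"), U = c("C2", "C4", "N1")
)

PHARM_TYPES <- c("AROM", "HDON", "HACC", "POSC", "NEGC", "LIPO")
DIRECTED_PTYPES <- c("AROM", "HDON", "HACC")

#' Coarse-grain an RNA structure to pseudoatom beads
#'
#' Each canonical residue is reduced to at most five beads whose coordinates
#' are exactly those of the source atoms: P, C4', N9, C2, C6 for purines and
#' P, C4', N1, C2, C4 for pyrimidines.  Missing atoms yield missing beads;
#' nothing is fabricated.  Non-canonical residues are kept but flagged
#' unusable for scoring.
#'
#' @param structure an \code{rna_structure} from \code{\link{read_rna_pdb}}.
#' @return An object of class \code{"rna_cg"}: a list of residues, each with
#'   \code{base}, \code{beads} (matrix, one row per present bead),
#'   \code{plane_normal} (unit vector or NULL) and \code{usable}.
#' @export
coarse_grain_rna <- function(structure) {
  at <- structure$atoms
  rid <- paste(at$chain, at$resno, at$ins, sep = "|")
  rid <- factor(rid, levels = unique(rid))
  res_list <- split(seq_len(nrow(at)), rid)
  skipped <- character()
  out <- lapply(res_list, function(idx) {
    sub <- at[idx, , drop = FALSE]
    base <- sub$base[1]
    info <- list(chain = sub$chain[1], resno = sub$resno[1], ins = sub$ins[1],
                 base = base)
    if (base == "other") {
      skipped <<- c(skipped, paste0(sub$resname[1], sub$resno[1]))
      info$beads <- matrix(numeric(), 0, 3, dimnames = list(NULL, c("x", "y", "z")))
      info$plane_normal <- NULL
      info$usable <- FALSE
      return(info)
    }
    wanted <- BEAD_NAMES[[base]]
    present <- wanted[wanted %in% sub$atom]
    beads <- t(vapply(present, function(nm) {
      row <- sub[match(nm, sub$atom), ]
      c(row$x, row$y, row$z)
    }, numeric(3)))
    colnames(beads) <- c("x", "y", "z")
    info$beads <- beads
    info$usable <- TRUE
    info$plane_normal <- NULL
    info2 <- info
    info2$plane_normal <- base_plane_normal(info)
    info2
  })
  if (length(skipped) > 0)
    warning(sprintf("skipped %d non-canonical residue(s): %s", length(skipped),
                    paste(skipped, collapse = ", ")))
  structure(unname(out), class = "rna_cg")
}

#' @export
print.rna_cg <- function(x, ...) {
  cat(sprintf("<rna_cg> %d residues (%d usable), %d beads total\n",
              length(x), sum(vapply(x, `[[`, TRUE, "usable")),
              sum(vapply(x, function(r) nrow(r$beads), 0L))))
  invisible(x)
}

#' Base-plane normal of a coarse-grained residue
#'
#' The normal is the normalised cross product
#' \eqn{(a_2-a_1)\times(a_3-a_1)} of the ordered base-atom triplet
#' (C2, C6, N9 for purines; C2, C4, N1 for pyrimidines), so its sign is
#' deterministic.  Returns NULL (with a warning for degenerate geometry) when
#' a defining atom is missing or the triplet is collinear.
#'
#' @param residue_cg one residue of an \code{rna_cg}.
#' @return unit numeric(3), or NULL.
#' @export
base_plane_normal <- function(residue_cg) {
  base <- residue_cg$base
  if (!base %in% names(PLANE_TRIPLET)) return(NULL)
  trip <- PLANE_TRIPLET[[base]]
  if (!all(trip %in% rownames(residue_cg$beads))) return(NULL)
  a1 <- residue_cg$beads[trip[1], ]
  a2 <- residue_cg$beads[trip[2], ]
  a3 <- residue_cg$beads[trip[3], ]
  nrm <- cross3(a2 - a1, a3 - a1)
  if (vnorm(nrm) < 1e-10) {
    warning(sprintf("degenerate base-plane geometry in residue %s%s",
                    base, residue_cg$resno))
    return(NULL)
  }
  nrm / vnorm(nrm)
}

# --- ring perception --------------------------------------------------------

ligand_graph <- function(mol, heavy_only = FALSE) {
  keep <- if (heavy_only) which(mol$atoms$elem != "H") else seq_len(nrow(mol$atoms))
  map <- match(seq_len(nrow(mol$atoms)), keep)
  b <- mol$bonds
  sel <- b$i %in% keep & b$j %in% keep
  g <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
  if (any(sel))
    g <- igraph::add_edges(g, rbind(map[b$i[sel]], map[b$j[sel]]))
  list(graph = g, keep = keep, bonds = b[sel, , drop = FALSE], map = map)
}

# Smallest ring through each bond: shortest path between its endpoints in the
# graph minus that bond.  Unique rings up to rotation/reflection, size <= max_size.
find_rings <- function(mol, max_size = 8) {
  b <- mol$bonds
  if (nrow(b) == 0) return(list())
  n <- nrow(mol$atoms)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(b$i, b$j))
  rings <- list()
  seen <- character()
  for (e in seq_len(nrow(b))) {
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = b$i[e], to = b$j[e]))
    vp <- sp$vpath[[1]]
    if (length(vp) == 0 || length(vp) > max_size) next
    ring <- as.integer(vp)
    key <- paste(sort(ring), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    rings[[length(rings) + 1]] <- ring
  }
  rings
}

bond_lookup <- function(mol) {
  b <- mol$bonds
  key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
  stats::setNames(seq_len(nrow(b)), key)
}

ring_bond_ids <- function(ring, lut) {
  nxt <- c(ring[-1], ring[1])
  unname(lut[paste(pmin(ring, nxt), pmax(ring, nxt))])
}

# Aromatic if every ring bond carries the aromatic flag, or the ring is
# even-sized with strictly alternating single/double orders.
is_aromatic_ring <- function(mol, ring, lut) {
  ids <- ring_bond_ids(ring, lut)
  if (anyNA(ids)) return(FALSE)
  if (all(mol$bonds$aromatic[ids])) return(TRUE)
  if (length(ring) %% 2 != 0) return(FALSE)
  ord <- round(mol$bonds$order[ids])
  all(ord %in% c(1, 2)) && all(abs(diff(c(ord, ord[1]))) == 1)
}

# --- pharmacophore perception ----------------------------------------------

neighbors_of <- function(mol) {
  n <- nrow(mol$atoms)
  nb <- vector("list", n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    nb[[b$i[k]]] <- c(nb[[b$i[k]]], b$j[k])
    nb[[b$j[k]]] <- c(nb[[b$j[k]]], b$i[k])
  }
  nb
}

# Sum of bond orders at each atom (aromatic counted 1.5).
valence_sum <- function(mol) {
  n <- nrow(mol$atoms)
  v <- numeric(n)
  b <- mol$bonds
  ord <- ifelse(b$aromatic, 1.5, b$order)
  for (k in seq_len(nrow(b))) {
    v[b$i[k]] <- v[b$i[k]] + ord[k]
    v[b$j[k]] <- v[b$j[k]] + ord[k]
  }
  v
}

pharm_point <- function(type, center, direction = NULL, source_atoms = integer()) {
  list(type = type, center = as.numeric(center),
       direction = if (is.null(direction)) NULL else as.numeric(direction),
       source_atoms = as.integer(source_atoms))
}

#' Perceive pharmacophore points of a ligand
#'
#' Six feature types are assigned: hydrogen-bond donors (HDON) and acceptors
#' (HACC) on polar heavy atoms, positive/negative charge centers (POSC/NEGC)
#' on formally charged heavy atoms, one aromatic point (AROM) per aromatic
#' ring at the ring centroid with its direction perpendicular to the ring
#' plane, and lipophilic points (LIPO) at the contribution-weighted centroid
#' of each connected lipophilic region.  A single atom may seed several
#' points (e.g. a hydroxyl oxygen is both donor and acceptor).  HDON/HACC
#' directions follow the attached polar hydrogens (donor) or point away from
#' the mean bonded-neighbour direction (acceptor, lone-pair proxy); when
#' hydrogens are absent donors are inferred from free valence.
#'
#' @param mol a \code{ligand}.
#' @param lipo_core contribution of an apolar carbon/halogen (default 1.0).
#' @param lipo_polar_adjacent contribution of a carbon bonded to exactly one
#'   N/O (default 0.3).
#' @return list of pharmacophore points (class \code{"pharm_set"}); each has
#'   \code{type}, \code{center}, optional unit \code{direction},
#'   \code{source_atoms}.
#' @export
perceive_pharmacophores <- function(mol, lipo_core = 1.0, lipo_polar_adjacent = 0.3) {
  a <- mol$atoms
  n <- nrow(a)
  xyz <- ligand_coords(mol)
  nb <- neighbors_of(mol)
  val <- valence_sum(mol)
  is_h <- a$elem == "H"
  has_explicit_h <- any(is_h)
  lut <- bond_lookup(mol)
  pts <- list()

  rings <- find_rings(mol)
  arom_rings <- Filter(function(r) is_aromatic_ring(mol, r, lut), rings)
  arom_atoms <- unique(unlist(arom_rings))
  for (ring in arom_rings) {
    center <- colMeans(xyz[ring, , drop = FALSE])
    nrm <- cross3(xyz[ring[2], ] - xyz[ring[1], ], xyz[ring[3], ] - xyz[ring[1], ])
    u <- unitv(nrm)
    pts[[length(pts) + 1]] <- pharm_point("AROM", center, u, ring)
  }

  for (i in which(!is_h)) {
    el <- a$elem[i]
    chg <- a$charge[i]
    h_nb <- nb[[i]][is_h[nb[[i]]]]
    heavy_nb <- nb[[i]][!is_h[nb[[i]]]]
    if (chg > 0) pts[[length(pts) + 1]] <- pharm_point("POSC", xyz[i, ], NULL, i)
    if (chg < 0) pts[[length(pts) + 1]] <- pharm_point("NEGC", xyz[i, ], NULL, i)
    if (el %in% c("N", "O", "S")) {
      # donor: bears polar H (or, with no explicit H in the file, free valence)
      donor <- if (has_explicit_h) length(h_nb) > 0
               else chg >= 0 && val[i] < c(N = 3, O = 2, S = 2)[el]
      if (isTRUE(donor)) {
        dir <- NULL
        if (length(h_nb) > 0) {
          vs <- lapply(h_nb, function(h) unitv(xyz[h, ] - xyz[i, ]))
          dir <- unitv(Reduce(`+`, vs))
        } else if (length(heavy_nb) > 0) {
          vs <- lapply(heavy_nb, function(j) unitv(xyz[j, ] - xyz[i, ]))
          dir <- unitv(-Reduce(`+`, vs))
        }
        pts[[length(pts) + 1]] <- pharm_point("HDON", xyz[i, ], dir, i)
      }
      # acceptor: lone-pair-bearing N/O (not positively charged; aromatic
      # N-H such as pyrrole is donor-only)
      acceptor <- el %in% c("N", "O") && chg <= 0 &&
        !(i %in% arom_atoms && length(h_nb) > 0) &&
        val[i] <= c(N = 3, O = 2)[el] + 1e-9
      if (isTRUE(acceptor)) {
        all_nb <- nb[[i]]
        dir <- if (length(all_nb) > 0) {
          vs <- lapply(all_nb, function(j) unitv(xyz[j, ] - xyz[i, ]))
          unitv(-Reduce(`+`, vs))
        } else NULL
        if (is.null(dir))
          warning(sprintf("degenerate acceptor direction at atom %d; point emitted without direction", i))
        pts[[length(pts) + 1]] <- pharm_point("HACC", xyz[i, ], dir, i)
      }
    }
  }

  contrib <- lipo_contributions(mol, lipo_core, lipo_polar_adjacent)
  pts <- c(pts, merge_lipophilic(mol, contrib))
  structure(pts, class = "pharm_set")
}

#' @export
print.pharm_set <- function(x, ...) {
  tab <- table(factor(vapply(x, `[[`, "", "type"), levels = PHARM_TYPES))
  cat("<pharm_set>", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  invisible(x)
}

# Atom-level lipophilic contributions: apolar carbons/halogens 1.0, carbons
# bonded to exactly one N/O 0.3, everything else 0.
lipo_contributions <- function(mol, core = 1.0, polar_adjacent = 0.3) {
  a <- mol$atoms
  nb <- neighbors_of(mol)
  contrib <- numeric(nrow(a))
  charged <- a$charge != 0
  for (i in seq_len(nrow(a))) {
    el <- a$elem[i]
    if (!(el == "C" || el %in% c("F", "Cl", "Br", "I"))) next
    if (charged[i]) next
    nbe <- a$elem[nb[[i]]]
    n_po <- sum(nbe %in% c("N", "O"))
    nb_charged <- any(charged[nb[[i]]])
    if (n_po == 0 && !nb_charged) contrib[i] <- core
    else if (el == "C" && n_po == 1 && !nb_charged) contrib[i] <- polar_adjacent
  }
  contrib
}

#' Merge adjacent lipophilic atoms into single LIPO points
#'
#' Lipophilic atoms connected by bonds form regions; each region yields one
#' LIPO pharmacophore at the contribution-weighted centroid of its atoms.
#'
#' @param mol a \code{ligand}.
#' @param contributions per-atom lipophilic scores (zero excludes an atom).
#' @return list of LIPO pharmacophore points.
#' @export
merge_lipophilic <- function(mol, contributions) {
  act <- which(contributions > 0)
  if (length(act) == 0) return(list())
  xyz <- ligand_coords(mol)
  b <- mol$bonds
  sel <- b$i %in% act & b$j %in% act
  g <- igraph::make_empty_graph(n = length(act), directed = FALSE)
  if (any(sel))
    g <- igraph::add_edges(g, rbind(match(b$i[sel], act), match(b$j[sel], act)))
  comp <- igraph::components(g)$membership
  lapply(unique(comp), function(cc) {
    idx <- act[comp == cc]
    w <- contributions[idx]
    center <- colSums(xyz[idx, , drop = FALSE] * w) / sum(w)
    pharm_point("LIPO", center, NULL, idx)
  })
}

#' Write pharmacophore points as PDB-like debug text
#'
#' One HETATM per point with the type in the residue-name field; intended for
#' visual inspection only.
#'
#' @param pts a \code{pharm_set}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_pharm_debug <- function(pts, path) {
  lines <- vapply(seq_along(pts), function(k) {
    p <- pts[[k]]
    sprintf("HETATM%5d  X   %-4s%s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            k, substr(p$type, 1, 4), "P", k, p$center[1], p$center[2], p$center[3])
  }, "")
  writeLines(c(lines, "END"), path)
  invisible(path)
}
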