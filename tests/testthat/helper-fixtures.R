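# Fixture builders shared by the suite: everything generated in code.

# A full guanosine residue (23 heavy atoms) as PDB lines, offset along x so
# several residues can be concatenated.  Optionally duplicates C4' with
# altlocs A/B at different coordinates.
full_g_residue_pdb <- function(resno, x0 = 0, serial0 = 0, altloc_c4 = FALSE) {
  atoms <- list(
    c("P", 0.0, 0.0, 0.0),    c("OP1", -1.2, 0.8, 0.0), c("OP2", 0.9, 1.1, 0.5),
    c("O5'", 0.5, -1.3, 0.8), c("C5'", 1.8, -1.8, 0.6), c("C4'", 2.8, -1.0, 1.4),
    c("O4'", 3.0, 0.3, 0.9),  c("C3'", 4.1, -1.6, 1.5), c("O3'", 4.3, -2.3, 2.7),
    c("C2'", 5.1, -0.5, 1.3), c("O2'", 6.0, -0.6, 0.3), c("C1'", 4.3, 0.7, 1.1),
    c("N9", 4.6, 1.6, 2.2),   c("C8", 4.2, 1.5, 3.5),   c("N7", 4.6, 2.5, 4.2),
    c("C5", 5.3, 3.3, 3.4),   c("C6", 6.0, 4.5, 3.6),   c("O6", 6.2, 5.1, 4.7),
    c("N1", 6.5, 5.0, 2.4),   c("C2", 6.4, 4.4, 1.2),   c("N2", 7.0, 5.0, 0.2),
    c("N3", 5.7, 3.3, 1.0),   c("C4", 5.2, 2.8, 2.2))
  lines <- character()
  serial <- serial0
  for (a in atoms) {
    serial <- serial + 1
    alts <- if (altloc_c4 && a[1] == "C4'") c("A", "B") else ""
    for (al in alts) {
      dx <- if (al == "B") 0.6 else 0
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s%1s%3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %1s",
        serial, a[1], al, "G", resno,
        as.numeric(a[2]) + x0 + dx, as.numeric(a[3]), as.numeric(a[4]),
        substr(a[1], 1, 1)))
    }
  }
  lines
}

write_two_g_pdb <- function(path, altloc_c4 = FALSE) {
  writeLines(c(full_g_residue_pdb(1, 0, 0, altloc_c4),
               full_g_residue_pdb(2, 8, 30), "TER", "END"), path)
  path
}

# Plain all-carbon 6-ring (benzene skeleton, no H) as a ligand.
make_c6_ring <- function() {
  k <- 0:5
  atoms <- data.frame(elem = "C", x = 1.396 * cos(pi * k / 3),
                      y = 1.396 * sin(pi * k / 3), z = 0, charge = 0L)
  bonds <- data.frame(i = 1:6, j = c(2:6, 1), order = 1, aromatic = TRUE)
  ligand(atoms, bonds, name = "c6ring")
}

rotate_ligand <- function(mol, axis, angle_deg, about = c(0, 0, 0)) {
  R <- rligscore:::rotation_matrix(axis, angle_deg)
  xyz <- sweep(as.matrix(mol$atoms[, c("x", "y", "z")]), 2, about)
  mol$atoms[, c("x", "y", "z")] <- sweep(xyz %*% t(R), 2, -about)
  mol
}

translate_ligand <- function(mol, v) {
  mol$atoms[, c("x", "y", "z")] <- sweep(as.matrix(mol$atoms[, c("x", "y", "z")]),
                                         2, -v)
  mol
}

# A single coarse-grained residue built by hand (no PDB involved).
toy_cg_residue <- function(beads, base = "G", normal = NULL, usable = TRUE) {
  structure(list(list(base = base, chain = "A", resno = 1L, ins = "",
                      beads = beads, plane_normal = normal, usable = usable)),
            class = "rna_cg")
}

toy_pharm_point <- function(type, center, direction = NULL) {
  structure(list(rligscore:::pharm_point(type, center, direction, 1L)),
            class = "pharm_set")
}

# Scoring-model stub whose every group returns a constant probability
# (kNN with two coincident reference records; p in {0, 0.5, 1}).
stub_model <- function(p = 0.5) {
  stopifnot(p %in% c(0, 0.5, 1))
  mk <- function(key) {
    ptype <- strsplit(key, ":")[[1]][3]
    feats <- rligscore:::features_for_ptype(ptype)
    nf <- length(feats)
    y <- switch(as.character(p), "0" = c(FALSE, FALSE), "0.5" = c(TRUE, FALSE),
                "1" = c(TRUE, TRUE))
    list(key = key, features = feats,
         scaler = list(min = stats::setNames(rep(0, nf), feats),
                       max = stats::setNames(rep(1, nf), feats)),
         algorithm = "knn", config = list(k = 2),
         fit = rligscore:::knn_fit(matrix(0.5, 2, nf), y, 2),
         n_pos = sum(y), n_neg = sum(!y))
  }
  keys <- group_keys()
  structure(list(algorithm = "knn",
                 groups = stats::setNames(lapply(keys, mk), keys),
                 manifest = data.frame(key = keys, status = "retained",
                                       n_pos = 2, n_neg = 2, n_retained = 2,
                                       config = "k=2", cv_accuracy = NA_real_),
                 seed = 1, min_pos = 10, enn_k = 3, n_records = 0L),
            class = "rlsf")
}

# Brute-force minimum RMSD over all element- and bond-preserving atom
# permutations (heavy atoms only); exponential, for <= 8 heavy atoms.
brute_symmetry_rmsd <- function(ref, pose) {
  heavy <- which(ref$atoms$elem != "H")
  n <- length(heavy)
  el <- ref$atoms$elem[heavy]
  bkey <- function(mol, idx) {
    b <- mol$bonds
    sel <- b$i %in% idx & b$j %in% idx
    m <- match(seq_len(nrow(mol$atoms)), idx)
    paste(pmin(m[b$i[sel]], m[b$j[sel]]), pmax(m[b$i[sel]], m[b$j[sel]]),
          b$order[sel], b$aromatic[sel])
  }
  ref_bonds <- sort(bkey(ref, heavy))
  pose_bonds_set <- bkey(pose, which(pose$atoms$elem != "H"))
  X1 <- as.matrix(ref$atoms[heavy, c("x", "y", "z")])
  X2 <- as.matrix(pose$atoms[pose$atoms$elem != "H", c("x", "y", "z")])
  pose_el <- pose$atoms$elem[pose$atoms$elem != "H"]
  b <- pose$bonds
  hsel <- b$i %in% which(pose$atoms$elem != "H") & b$j %in% which(pose$atoms$elem != "H")
  m2 <- match(seq_len(nrow(pose$atoms)), which(pose$atoms$elem != "H"))
  pb <- paste(pmin(m2[b$i[hsel]], m2[b$j[hsel]]), pmax(m2[b$i[hsel]], m2[b$j[hsel]]),
              b$order[hsel], b$aromatic[hsel])
  best <- Inf
  perm_rec <- function(assigned) {
    k <- length(assigned) + 1
    if (k > n) {
      # check bonds preserved under the mapping ref i -> pose assigned[i]
      bmapped <- sort(vapply(strsplit(ref_bonds, " "), function(f) {
        i <- assigned[as.integer(f[1])]; j <- assigned[as.integer(f[2])]
        paste(min(i, j), max(i, j), f[3], f[4])
      }, ""))
      if (!identical(bmapped, sort(pb))) return()
      r <- sqrt(mean(rowSums((X1 - X2[assigned, , drop = FALSE])^2)))
      best <<- min(best, r)
      return()
    }
    for (cand in seq_len(n)) {
      if (cand %in% assigned) next
      if (pose_el[cand] != el[k]) next
      perm_rec(c(assigned, cand))
    }
  }
  perm_rec(integer())
  best
}
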