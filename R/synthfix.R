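# Synthetic fixtures: an idealised single-strand toy RNA, hard-coded ligand
# templates, pose sets with planted RMSDs, and class-conditional contact
# tables.  These emulate the representational structure the trainer and
# scorer assume (near-native band, >= 4 A decoys, short-distance positive
# contacts) -- not the geometry of real complexes.

# Cylindrical placement (radius, angular offset in degrees, z offset) of the
# bead-defining atoms of one idealised residue; helix rise 2.81 A, twist 32
# degrees per residue.  Values are fixed arbitrary internal coordinates
# chosen once for representational completeness (non-collinear base triplets).
TOY_ATOM_TEMPLATE <- list(
  purine = list(
    "P"   = c(9.40,  0.0, 0.00),
    "C4'" = c(9.00, 14.0, 0.50),
    "N9"  = c(5.90,  8.0, 0.30),
    "C2"  = c(3.95, 20.0, 0.90),
    "C6"  = c(5.10, 27.0, 0.10)),
  pyrimidine = list(
    "P"   = c(9.40,  0.0, 0.00),
    "C4'" = c(9.00, 14.0, 0.50),
    "N1"  = c(5.90,  8.0, 0.30),
    "C2"  = c(4.30, 18.0, 0.85),
    "C4"  = c(4.90, 28.0, 0.15))
)

toy_xyz <- function(rphi_z, twist_deg, rise) {
  r <- rphi_z[1]; phi <- (rphi_z[2] + twist_deg) * pi / 180; dz <- rphi_z[3]
  c(r * cos(phi), r * sin(phi), rise + dz)
}

#' Generate an idealised toy RNA strand as PDB text
#'
#' A single chain with every bead-defining atom present per residue (so each
#' residue coarse-grains to exactly 5 beads with a well-defined base-plane
#' normal).  Geometry is an idealised helix; biological realism is not a
#' goal.
#'
#' @param sequence string over A/C/G/U (e.g. \code{"GGCAU"}).
#' @return character vector of PDB lines (use \code{writeLines} to save).
#' @export
make_toy_rna <- function(sequence) {
  bases <- strsplit(toupper(sequence), NULL)[[1]]
  if (length(bases) == 0 || any(!bases %in% c("A", "C", "G", "U")))
    stop_usage("sequence must be non-empty over A/C/G/U")
  lines <- character()
  serial <- 0L
  for (i in seq_along(bases)) {
    base <- bases[i]
    tmpl <- TOY_ATOM_TEMPLATE[[if (base %in% PURINES) "purine" else "pyrimidine"]]
    for (nm in names(tmpl)) {
      serial <- serial + 1L
      p <- toy_xyz(tmpl[[nm]], twist_deg = 32 * (i - 1), rise = 2.81 * (i - 1))
      el <- substr(nm, 1, 1)
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, nm, base, i, p[1], p[2], p[3], el))
    }
  }
  c(lines, "TER", "END")
}

# --- ligand templates -------------------------------------------------------

#' Built-in ligand templates
#'
#' Hard-coded connection tables (no perception ambiguity):
#' \code{"ring_hydroxyl"} (phenol: aromatic ring + OH),
#' \code{"chain_amine"} (n-propylamine) and \code{"charged_acid"}
#' (acetate, one O carrying formal charge -1).
#'
#' @param id template identifier.
#' @return a \code{ligand} centred near the origin, explicit hydrogens
#'   present.
#' @export
ligand_template <- function(id = c("ring_hydroxyl", "chain_amine", "charged_acid")) {
  id <- match.arg(id)
  hex <- function(k, r = 1.396) c(r * cos(pi * k / 3), r * sin(pi * k / 3), 0)
  if (id == "ring_hydroxyl") {
    atoms <- rbind(
      t(vapply(0:5, hex, numeric(3))),                 # C1..C6
      t(vapply(0:5, hex, numeric(3), r = 2.47))[2:6, ],# H on C2..C6
      c(2.76, 0, 0),                                   # O on C1
      c(3.33, 0.82, 0))                                # H on O
    elem <- c(rep("C", 6), rep("H", 5), "O", "H")
    bonds <- data.frame(
      i = c(1, 2, 3, 4, 5, 6, 2, 3, 4, 5, 6, 1, 12),
      j = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10, 11, 12, 13),
      order = c(rep(1, 6), rep(1, 7)),
      aromatic = c(rep(TRUE, 6), rep(FALSE, 7)))
  } else if (id == "chain_amine") {
    atoms <- rbind(
      c(0.00, 0.00, 0.0), c(1.52, 0.00, 0.0), c(2.10, 1.40, 0.0),  # C C C
      c(3.57, 1.40, 0.0),                                          # N
      c(-0.40, -0.50, 0.85), c(-0.40, -0.50, -0.85), c(-0.38, 1.01, 0.0),
      c(1.90, -0.53, 0.86), c(1.90, -0.53, -0.86),
      c(1.75, 1.95, 0.86), c(1.75, 1.95, -0.86),
      c(3.95, 1.90, 0.80), c(3.95, 1.90, -0.80))
    elem <- c("C", "C", "C", "N", rep("H", 9))
    bonds <- data.frame(
      i = c(1, 2, 3, 1, 1, 1, 2, 2, 3, 3, 4, 4),
      j = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13),
      order = 1, aromatic = FALSE)
  } else {
    atoms <- rbind(
      c(0.00, 0.00, 0.0),   # CH3
      c(1.51, 0.00, 0.0),   # C(=O)O-
      c(2.15, 1.06, 0.0),   # =O
      c(2.10, -1.15, 0.0),  # O-
      c(-0.38, -0.52, 0.88), c(-0.38, -0.52, -0.88), c(-0.38, 1.02, 0.0))
    elem <- c("C", "C", "O", "O", "H", "H", "H")
    bonds <- data.frame(
      i = c(1, 2, 2, 1, 1, 1),
      j = c(2, 3, 4, 5, 6, 7),
      order = c(1, 2, 1, 1, 1, 1), aromatic = FALSE)
  }
  a <- data.frame(elem = elem, x = atoms[, 1], y = atoms[, 2], z = atoms[, 3],
                  charge = 0L)
  if (id == "charged_acid") a$charge[4] <- -1L
  ligand(a, bonds, name = id)
}

#' Generate a pose set with planted RMSDs
#'
#' The native pose places the template next to the toy RNA strand; each
#' requested pose is a rigid translation of the native along a seeded random
#' direction whose magnitude equals the target RMSD (a pure translation of a
#' rigid body changes the symmetry-corrected RMSD by exactly its length).
#' Achieved RMSDs are verified to within 0.05 Angstrom.
#'
#' @param targets numeric vector of target RMSDs in Angstrom (0 = native copy).
#' @param template template id (see \code{\link{ligand_template}}).
#' @param rna_sequence toy RNA sequence used to anchor the placement.
#' @param seed integer seed (directions).
#' @param e_gaff optional numeric vector of per-pose internal energies
#'   written to the \code{E_GAFF} property.
#' @return list with \code{rna} (PDB lines), \code{native} (ligand),
#'   \code{poses} (list of ligands) and \code{rmsd}
#'   (data.frame pose_id, target, achieved).
#' @export
make_pose_set <- function(targets, template = "ring_hydroxyl",
                          rna_sequence = "GGCAU", seed = 1, e_gaff = NULL) {
  if (length(targets) == 0) stop_usage("pose plan is empty")
  rna_lines <- make_toy_rna(rna_sequence)
  tmp <- tempfile(fileext = ".pdb")
  writeLines(rna_lines, tmp)
  rna <- read_rna_pdb(tmp)
  unlink(tmp)
  cg <- coarse_grain_rna(rna)
  mid <- cg[[ceiling(length(cg) / 2)]]
  anchor <- mid$beads["C2", ]
  # native ligand centroid sits 3.5 A radially outward from the mid-strand base
  radial <- unitv(c(anchor[1], anchor[2], 0))
  mol <- ligand_template(template)
  xyz <- ligand_coords(mol)
  native <- ligand_set_coords(mol, sweep(xyz, 2, colMeans(xyz) - (anchor + 3.5 * radial)))
  poses <- vector("list", length(targets))
  achieved <- numeric(length(targets))
  dirs <- with_seed(seed, {
    m <- matrix(stats::rnorm(3 * length(targets)), ncol = 3)
    m / sqrt(rowSums(m^2))
  })
  for (k in seq_along(targets)) {
    t_k <- targets[k]
    pose <- if (t_k == 0) native
            else ligand_set_coords(native, sweep(ligand_coords(native), 2, -t_k * dirs[k, ]))
    if (!is.null(e_gaff)) pose$properties <- c(pose$properties, E_GAFF = format(e_gaff[k]))
    achieved[k] <- symmetry_rmsd(native, pose)
    if (abs(achieved[k] - t_k) > 0.05)
      warning(sprintf("pose %d: achieved RMSD %.3f deviates from target %.3f",
                      k, achieved[k], t_k))
    poses[[k]] <- pose
  }
  list(rna = rna_lines, native = native, poses = poses,
       rmsd = data.frame(pose_id = seq_along(targets), target = targets,
                         achieved = achieved))
}

#' Generate a class-conditional labelled contact table
#'
#' Positives are drawn short-range (d ~ N(3.0, 0.5^2) truncated to (0, 10],
#' angles normal around characteristic values with 15-degree spread);
#' negatives are diffuse (d ~ U(2, 10), angles ~ U(0, 180)).  Group keys are
#' sampled uniformly over \code{groups}.  Angle columns that the group's
#' pharmacophore type lacks (beta/delta for undirected types) are NA, as in
#' real contact tables.
#'
#' @param n_per_class records per class.
#' @param groups character vector of group keys (default: a small mixed set).
#' @param seed integer seed.
#' @param pos_d_mean,pos_d_sd positive-class distance parameters (Angstrom).
#' @param pos_angle_means named numeric: mean alpha, beta, gamma, delta for
#'   positives (degrees).
#' @param cutoff truncation bound for d (default 10).
#' @return labelled contact data.frame (complex_id, pose_id, base, bead,
#'   ptype, key, descriptors, label).
#' @export
make_contact_dataset <- function(n_per_class = 1000,
                                 groups = c("G:N9:HDON", "G:C2:HACC",
                                            "A:C4':LIPO", "U:N1:AROM"),
                                 seed = 1,
                                 pos_d_mean = 3.0, pos_d_sd = 0.5,
                                 pos_angle_means = c(alpha = 90, beta = 45,
                                                     gamma = 60, delta = 30),
                                 cutoff = 10) {
  if (n_per_class < 1) stop_usage("n_per_class must be >= 1")
  if (pos_d_sd <= 0 || pos_d_mean <= 0) stop_usage("invalid distance distribution")
  bad <- !groups %in% group_keys()
  if (any(bad)) stop_usage("unknown group key(s): %s", paste(groups[bad], collapse = ", "))
  rtrunc_norm <- function(n, mean, sd, lo, hi) {
    out <- numeric(0)
    while (length(out) < n) {
      x <- stats::rnorm(n, mean, sd)
      out <- c(out, x[x > lo & x <= hi])
    }
    out[seq_len(n)]
  }
  with_seed(seed, {
    mk <- function(label) {
      n <- n_per_class
      key <- sample(groups, n, replace = TRUE)
      parts <- strsplit(key, ":")
      ptype <- vapply(parts, `[`, "", 3)
      directed <- ptype %in% DIRECTED_PTYPES
      if (label == "positive") {
        d <- rtrunc_norm(n, pos_d_mean, pos_d_sd, 0, cutoff)
        ang <- vapply(c("alpha", "beta", "gamma", "delta"), function(a)
          rtrunc_norm(n, pos_angle_means[[a]], 15, 0, 180), numeric(n))
      } else {
        d <- stats::runif(n, 2, cutoff)
        ang <- matrix(stats::runif(4 * n, 0, 180), ncol = 4,
                      dimnames = list(NULL, c("alpha", "beta", "gamma", "delta")))
      }
      data.frame(complex_id = "synthetic", pose_id = ifelse(label == "positive", 1L, 2L),
                 base = vapply(parts, `[`, "", 1), bead = vapply(parts, `[`, "", 2),
                 ptype = ptype, key = key, d = d,
                 alpha = ang[, "alpha"],
                 beta = ifelse(directed, ang[, "beta"], NA_real_),
                 gamma = ang[, "gamma"],
                 delta = ifelse(directed, ang[, "delta"], NA_real_),
                 label = label, stringsAsFactors = FALSE)
    }
    rbind(mk("positive"), mk("negative"))
  })
}

#' Write a complete fixture bundle to a directory
#'
#' Emits \code{rna.pdb}, \code{native.sdf}, \code{poses.sdf},
#' \code{rmsd.csv} and \code{contacts.csv}, all derived deterministically
#' from the seed.
#'
#' @param out_dir target directory.
#' @param seed integer seed.
#' @param targets pose plan (default: ten poses in the near-native band and
#'   eight decoys at >= 4.5 Angstrom).
#' @param template,rna_sequence forwarded to \code{\link{make_pose_set}}.
#' @return \code{out_dir}, invisibly.
#' @export
write_fixture_bundle <- function(out_dir, seed = 1,
                                 targets = c(seq(0.3, 1.4, length.out = 10),
                                             seq(4.5, 8, length.out = 8)),
                                 template = "ring_hydroxyl",
                                 rna_sequence = "GGCAU") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fx <- make_pose_set(targets, template = template, rna_sequence = rna_sequence,
                      seed = seed)
  writeLines(fx$rna, file.path(out_dir, "rna.pdb"))
  write_ligand_sdf(fx$native, file.path(out_dir, "native.sdf"))
  write_ligand_sdf(fx$poses, file.path(out_dir, "poses.sdf"))
  utils::write.csv(fx$rmsd, file.path(out_dir, "rmsd.csv"), row.names = FALSE)
  contacts <- fixture_contact_table(fx)
  utils::write.csv(contacts, file.path(out_dir, "contacts.csv"), row.names = FALSE,
                   na = "")
  invisible(out_dir)
}

# Labelled contact table of a pose-set fixture: enumerate contacts of every
# pose and attach the pose's RMSD-derived class label.
fixture_contact_table <- function(fx, policy = label_policy(), cutoff = 10) {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(fx$rna, tmp)
  cg <- coarse_grain_rna(read_rna_pdb(tmp))
  unlink(tmp)
  labels <- label_pose(fx$rmsd$achieved, policy)
  out <- list()
  for (k in seq_along(fx$poses)) {
    pts <- perceive_pharmacophores(fx$poses[[k]])
    con <- enumerate_contacts(cg, pts, cutoff)
    if (nrow(con) == 0) next
    con$complex_id <- "fixture"
    con$pose_id <- k
    con$label <- labels[k]
    out[[length(out) + 1]] <- con
  }
  do.call(rbind, out)
}

#' Run the full synthetic train-score loop once
#'
#' Generates a fixture, trains a kNN model on its labelled contacts and
#' rescores the pose set; used to check that the planted near-native pose is
#' recovered at rank 1.
#'
#' @param seed integer seed.
#' @param grid kNN grid (default k in \{5, 15\} for speed at fixture size).
#' @return list with \code{scores} (score table), \code{rmsd} (per pose) and
#'   \code{top_is_near_native} (logical: rank-1 pose lies in the positive
#'   RMSD band).
#' @export
fixture_loop <- function(seed = 1, grid = lapply(c(5, 15), function(k) list(k = k))) {
  fx <- make_pose_set(c(seq(0.3, 1.4, length.out = 10), seq(4.5, 8, length.out = 8)),
                      seed = seed)
  contacts <- fixture_contact_table(fx)
  model <- suppressWarnings(rlsf_train(contacts, algorithm = "knn", grid = grid,
                                       seed = seed, min_pos = 10))
  tmp <- tempfile(fileext = ".pdb")
  writeLines(fx$rna, tmp)
  rna <- read_rna_pdb(tmp)
  unlink(tmp)
  scores <- score_poses(rna, fx$poses, model)
  top_pose <- scores$pose_id[scores$rank == 1]
  list(scores = scores, rmsd = fx$rmsd,
       top_is_near_native = fx$rmsd$achieved[top_pose] <= 1.5)
}
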