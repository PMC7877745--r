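# Total pose score: E = E_RNA-Ligand + E_Ligand, with
# E_RNA-Ligand = -sum of per-contact interaction probabilities and
# E_Ligand = (E_GAFF - b) * w.  Optional post-processing: greedy RMSD
# clustering, centroid averaging, rigid-body local optimisation.

#' Scoring parameters
#'
#' @param cutoff interaction cutoff in Angstrom (default 10).
#' @param b shift of the ligand internal-energy term (default 473.58, the
#'   third quartile of GAFF energies over deposited ligand structures).
#' @param w weight of the ligand term (default 0.1; user-overridable).
#' @return list of class \code{"scoring_params"}.
#' @export
scoring_params <- function(cutoff = 10, b = 473.58, w = 0.1) {
  if (cutoff <= 0) stop_usage("cutoff must be positive")
  if (w < 0) stop_usage("ligand-term weight w must be non-negative")
  structure(list(cutoff = cutoff, b = b, w = w), class = "scoring_params")
}

#' Ligand internal-energy term
#'
#' \code{E_ligand = (E_GAFF - b) * w}: the shift \code{b} moves typical
#' positive force-field energies to negative score contributions, and
#' \code{w} weights the term against the interaction sum.
#'
#' @param E_GAFF ligand internal energy (force-field units).
#' @param params \code{\link{scoring_params}}.
#' @return numeric score contribution.
#' @export
ligand_energy_term <- function(E_GAFF, params = scoring_params()) {
  if (length(E_GAFF) != 1 || !is.finite(E_GAFF))
    stop_data("E_GAFF must be a single finite number")
  (E_GAFF - params$b) * params$w
}

#' Score one ligand pose against a coarse-grained RNA
#'
#' Enumerates contacts at the cutoff, sums the model probabilities of every
#' contact whose group has a trained classifier, and adds the weighted
#' ligand internal-energy term.  Contacts in unmodelled groups (or with
#' incomplete descriptors) are skipped and counted.
#'
#' @param cg_rna an \code{rna_cg}.
#' @param pharm_points a \code{pharm_set} for the pose.
#' @param model an \code{rlsf}.
#' @param params \code{\link{scoring_params}}.
#' @param E_GAFF optional ligand internal energy; when absent the ligand term
#'   contributes 0 (with a warning).
#' @return list of class \code{"pose_score"}: E_total, E_rna_ligand,
#'   E_ligand, n_contacts, n_skipped.
#' @export
score_pose <- function(cg_rna, pharm_points, model, params = scoring_params(),
                       E_GAFF = NULL) {
  usable <- vapply(cg_rna, `[[`, TRUE, "usable")
  if (!any(usable)) warning("no usable residues; score has no contacts")
  contacts <- enumerate_contacts(cg_rna, pharm_points, params$cutoff)
  p <- stats::predict(model, contacts)
  scored <- !is.na(p)
  e_rl <- -sum(p[scored])
  if (is.null(E_GAFF) || (length(E_GAFF) == 1 && is.na(E_GAFF))) {
    warning("no ligand internal energy supplied; E_ligand = 0")
    e_lig <- 0
  } else {
    e_lig <- ligand_energy_term(E_GAFF, params)
  }
  structure(list(E_total = e_rl + e_lig, E_rna_ligand = e_rl, E_ligand = e_lig,
                 n_contacts = sum(scored), n_skipped = sum(!scored)),
            class = "pose_score")
}

#' @export
print.pose_score <- function(x, ...) {
  cat(sprintf("E_total = %.4f  (E_RNA-Ligand = %.4f over %d contacts, E_Ligand = %.4f, %d skipped)\n",
              x$E_total, x$E_rna_ligand, x$n_contacts, x$E_ligand, x$n_skipped))
  invisible(x)
}

#' Score a set of poses and rank them
#'
#' @param rna an \code{rna_structure} (or path to a PDB file).
#' @param poses list of \code{ligand} poses (or path to an SDF/MOL2 file);
#'   a per-pose \code{E_GAFF} property, when present, feeds the ligand term.
#' @param model an \code{rlsf} model (or path to a model archive).
#' @param params \code{\link{scoring_params}}.
#' @param complex_id identifier written to the output rows.
#' @return data.frame (complex_id, pose_id, E_total, E_rna_ligand, E_ligand,
#'   n_contacts, n_skipped, rank), sorted ascending by E_total with ties
#'   broken by pose order.
#' @export
score_poses <- function(rna, poses, model, params = scoring_params(),
                        complex_id = "complex") {
  if (is.character(rna)) rna <- read_rna_pdb(rna)
  if (is.character(poses)) poses <- read_ligand_poses(poses)
  if (is.character(model)) model <- read_rlsf(model)
  cg <- suppressWarnings(coarse_grain_rna(rna))
  rows <- lapply(seq_along(poses), function(i) {
    mol <- poses[[i]]
    eg <- suppressWarnings(as.numeric(unname(mol$properties["E_GAFF"])))
    if (length(eg) == 0 || is.na(eg)) eg <- NULL
    pts <- perceive_pharmacophores(mol)
    ps <- suppressWarnings(score_pose(cg, pts, model, params, E_GAFF = eg))
    data.frame(complex_id = complex_id, pose_id = i, E_total = ps$E_total,
               E_rna_ligand = ps$E_rna_ligand, E_ligand = ps$E_ligand,
               n_contacts = ps$n_contacts, n_skipped = ps$n_skipped)
  })
  df <- do.call(rbind, rows)
  ord <- order(df$E_total, df$pose_id)
  df$rank <- NA_integer_
  df$rank[ord] <- seq_len(nrow(df))
  df[ord, , drop = FALSE]
}

#' Score a pose file and write the ranked CSV
#'
#' @param rna_path receptor PDB.
#' @param poses_path ligand pose file (SDF/MOL2/PDB).
#' @param model model archive directory or \code{rlsf} object.
#' @param params \code{\link{scoring_params}}.
#' @param out_csv output path (optional).
#' @param complex_id identifier for the output rows.
#' @return the score table, invisibly when written to file.
#' @export
score_pose_file <- function(rna_path, poses_path, model,
                            params = scoring_params(), out_csv = NULL,
                            complex_id = NULL) {
  if (is.null(complex_id))
    complex_id <- tools::file_path_sans_ext(basename(poses_path))
  df <- score_poses(rna_path, poses_path, model, params, complex_id)
  if (!is.null(out_csv)) {
    utils::write.csv(df, out_csv, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Greedy RMSD clustering of scored poses
#'
#' AutoDock-style: the best-scored unassigned pose seeds a cluster and every
#' unassigned pose within the RMSD threshold of the seed joins it; repeat
#' until all poses are assigned.  Clusters are numbered in seed-score order.
#'
#' @param poses list of \code{ligand} poses (identical graphs).
#' @param scores numeric vector, one per pose (lower is better).
#' @param rmsd_threshold joining threshold in Angstrom (default 2.0).
#' @return list with \code{cluster} (integer per pose) and \code{seeds}
#'   (pose index seeding each cluster).
#' @export
cluster_poses <- function(poses, scores, rmsd_threshold = 2.0) {
  n <- length(poses)
  cluster <- rep(NA_integer_, n)
  seeds <- integer()
  cl <- 0L
  while (anyNA(cluster)) {
    un <- which(is.na(cluster))
    seed <- un[order(scores[un], un)[1]]
    cl <- cl + 1L
    seeds <- c(seeds, seed)
    cluster[seed] <- cl
    for (i in un[un != seed]) {
      if (symmetry_rmsd(poses[[seed]], poses[[i]]) <= rmsd_threshold)
        cluster[i] <- cl
    }
  }
  list(cluster = cluster, seeds = seeds)
}

#' Centroid (average) pose of a cluster
#'
#' Atom correspondence between each member and the cluster seed is resolved
#' through the ligand-symmetry mapping minimising that member's RMSD to the
#' seed, then coordinates are averaged atom-wise.
#'
#' @param cluster_members list of \code{ligand} poses; the first is the seed.
#' @return a \code{ligand} with averaged coordinates (in the seed's atom
#'   order).
#' @export
centroid_pose <- function(cluster_members) {
  if (length(cluster_members) == 0) stop_data("empty cluster")
  seed <- cluster_members[[1]]
  if (length(cluster_members) == 1) return(seed)
  acc <- matrix(0, nrow(seed$atoms), 3)
  for (m in cluster_members) {
    sm <- symmetry_rmsd(seed, m, return_mapping = TRUE)
    xyz <- ligand_coords(m)
    full_map <- sm$full_mapping
    acc <- acc + xyz[full_map, , drop = FALSE]
  }
  ligand_set_coords(seed, acc / length(cluster_members))
}

#' Rigid-body local optimisation of a pose
#'
#' Deterministic coordinate descent over the six rigid degrees of freedom:
#' translations along x/y/z (initial step 0.5 Angstrom) and rotations about
#' the centroid (initial step 10 degrees), with step halving when no move
#' improves, a bounded evaluation budget, and monotone score decrease.
#'
#' @param pose a \code{ligand}.
#' @param score_fn function(ligand) -> numeric score (lower is better).
#' @param trans_step initial translation step (Angstrom).
#' @param rot_step initial rotation step (degrees).
#' @param max_eval maximum score evaluations (default 200).
#' @return list with \code{pose}, \code{score} (<= the input score) and
#'   \code{n_eval}.
#' @export
local_optimize <- function(pose, score_fn, trans_step = 0.5, rot_step = 10,
                           max_eval = 200) {
  best <- pose
  best_score <- score_fn(pose)
  n_eval <- 1L
  ts <- trans_step; rs <- rot_step
  axes <- diag(3)
  while (n_eval < max_eval && (ts > 0.01 || rs > 0.2)) {
    improved <- FALSE
    for (ax in 1:3) {
      for (sgn in c(1, -1)) {
        if (n_eval >= max_eval) break
        cand <- ligand_set_coords(best, sweep(ligand_coords(best), 2,
                                              -sgn * ts * axes[ax, ]))
        sc <- score_fn(cand); n_eval <- n_eval + 1L
        if (sc < best_score) { best <- cand; best_score <- sc; improved <- TRUE }
      }
    }
    for (ax in 1:3) {
      for (sgn in c(1, -1)) {
        if (n_eval >= max_eval) break
        xyz <- ligand_coords(best)
        ctr <- colMeans(xyz)
        R <- rotation_matrix(axes[ax, ], sgn * rs)
        cand <- ligand_set_coords(best, sweep(sweep(xyz, 2, ctr) %*% t(R), 2, -ctr))
        sc <- score_fn(cand); n_eval <- n_eval + 1L
        if (sc < best_score) { best <- cand; best_score <- sc; improved <- TRUE }
      }
    }
    if (!improved) { ts <- ts / 2; rs <- rs / 2 }
  }
  list(pose = best, score = best_score, n_eval = n_eval)
}
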