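# Docking-evaluation metrics: symmetry-corrected ligand RMSD, S(X),
# SR(X,C) success rates, Monte-Carlo random baselines, score-RMSD
# correlations.

colored_ligand_graph <- function(mol, heavy_only = TRUE) {
  keep <- if (heavy_only) which(mol$atoms$elem != "H") else seq_len(nrow(mol$atoms))
  b <- mol$bonds
  sel <- b$i %in% keep & b$j %in% keep
  map <- match(seq_len(nrow(mol$atoms)), keep)
  g <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
  if (any(sel)) g <- igraph::add_edges(g, rbind(map[b$i[sel]], map[b$j[sel]]))
  vcol <- as.integer(factor(mol$atoms$elem[keep],
                            levels = sort(unique(mol$atoms$elem))))
  ecol <- as.integer(ifelse(b$aromatic[sel], 3L, round(2 * b$order[sel])))
  list(graph = g, vcol = vcol, ecol = ecol, keep = keep)
}

#' Symmetry-corrected RMSD between two poses of the same molecule
#'
#' Minimum heavy-atom RMSD over all graph isomorphisms of the two
#' (element- and bond-order-labelled) molecular graphs; for a self-symmetric
#' ligand this removes the spurious RMSD a fixed atom order would report.
#' Coordinates are compared in place (receptor frame) -- no re-superposition.
#'
#' @param ref_mol,pose_mol \code{ligand} objects with identical graphs.
#' @param heavy_only drop hydrogens first (default TRUE).
#' @param max_maps cap on enumerated symmetry mappings; beyond it the minimum
#'   over the enumerated subset is returned with a warning.
#' @param return_mapping also return the best atom mapping (used for
#'   centroid averaging).
#' @return RMSD in Angstrom, or (with \code{return_mapping}) a list with
#'   \code{rmsd}, \code{mapping} (heavy-atom), \code{full_mapping}
#'   (all atoms; hydrogens mapped identically).
#' @export
symmetry_rmsd <- function(ref_mol, pose_mol, heavy_only = TRUE,
                          max_maps = 10000, return_mapping = FALSE) {
  g1 <- colored_ligand_graph(ref_mol, heavy_only)
  g2 <- colored_ligand_graph(pose_mol, heavy_only)
  if (length(g1$keep) != length(g2$keep) ||
      !identical(sort(ref_mol$atoms$elem), sort(pose_mol$atoms$elem)))
    stop_data("molecular graphs differ between reference and pose")
  maps <- igraph::isomorphisms(g1$graph, g2$graph, method = "vf2",
                               vertex.color1 = g1$vcol, vertex.color2 = g2$vcol,
                               edge.color1 = g1$ecol, edge.color2 = g2$ecol)
  if (length(maps) == 0)
    stop_data("molecular graphs of reference and pose are not isomorphic")
  if (length(maps) > max_maps) {
    warning(sprintf("%d symmetry mappings; evaluating the first %d",
                    length(maps), max_maps))
    maps <- maps[seq_len(max_maps)]
  }
  X1 <- as.matrix(ref_mol$atoms[g1$keep, c("x", "y", "z")])
  X2 <- as.matrix(pose_mol$atoms[g2$keep, c("x", "y", "z")])
  best <- Inf; best_map <- NULL
  for (m in maps) {
    perm <- as.integer(m)
    r <- sqrt(mean(rowSums((X1 - X2[perm, , drop = FALSE])^2)))
    if (r < best) { best <- r; best_map <- perm }
  }
  if (!return_mapping) return(best)
  full <- seq_len(nrow(ref_mol$atoms))
  full[g1$keep] <- g2$keep[best_map]
  list(rmsd = best, mapping = best_map, full_mapping = full)
}

#' S(X): best RMSD among the top-X scored poses
#'
#' @param rmsds_by_rank RMSDs ordered by score rank (rank 1 first).
#' @param X how many top poses to consider.
#' @return minimum RMSD among ranks 1..min(X, n), in Angstrom.
#' @export
s_of_x <- function(rmsds_by_rank, X) {
  if (X < 1) stop_usage("X must be >= 1")
  if (length(rmsds_by_rank) == 0) stop_data("empty pose set")
  min(rmsds_by_rank[seq_len(min(X, length(rmsds_by_rank)))])
}

#' SR(X,C): top-X success indicator at RMSD threshold C
#'
#' 1 when any of the top-X scored poses is within C Angstrom of the
#' reference (boundary counts as success), else 0.
#'
#' @param rmsds_by_rank RMSDs ordered by score rank.
#' @param X top pose count.
#' @param C RMSD threshold in Angstrom.
#' @return 0 or 1.
#' @export
success_rate <- function(rmsds_by_rank, X, C) {
  if (C <= 0) stop_usage("C must be positive")
  as.integer(s_of_x(rmsds_by_rank, X) <= C)
}

#' Aggregate SR(X,C) over complexes
#' @param rmsd_lists list of per-complex rank-ordered RMSD vectors.
#' @param X,C as in \code{\link{success_rate}}.
#' @return mean success indicator.
#' @export
aggregate_success_rate <- function(rmsd_lists, X, C) {
  mean(vapply(rmsd_lists, function(r) success_rate(r, X, C), integer(1)))
}

#' Random-selection baseline for SR(X,C)
#'
#' Monte-Carlo estimate of the probability that X poses drawn uniformly
#' without replacement contain at least one with RMSD <= C; the draw is
#' repeated \code{n_draws} times (default 100000) and averaged, and is
#' deterministic under the seed.
#'
#' @param rmsds pose RMSDs (any order).
#' @param X draw size.
#' @param C threshold in Angstrom.
#' @param n_draws Monte-Carlo sample count.
#' @param seed integer seed.
#' @param replace draw with replacement instead (default FALSE, matching the
#'   without-replacement selection of distinct poses).
#' @return estimated success probability in [0, 1].
#' @export
random_baseline <- function(rmsds, X, C, n_draws = 100000, seed = 1,
                            replace = FALSE) {
  n <- length(rmsds)
  if (X > n) stop_usage("X = %d exceeds the number of poses (%d)", X, n)
  good <- which(rmsds <= C)
  if (length(good) == 0) return(0)
  if (replace) {
    return(with_seed(seed, {
      draws <- matrix(sample.int(n, n_draws * X, replace = TRUE), ncol = X)
      mean(apply(draws, 1, function(ix) any(ix %in% good)))
    }))
  }
  # vectorised without-replacement sampling: per draw, assign each pose a
  # uniform key; the X smallest keys are the sample.  The sample contains a
  # good pose iff the smallest good key ranks within the first X keys.
  with_seed(seed, {
    keys <- matrix(stats::runif(n_draws * n), nrow = n_draws, ncol = n)
    min_good <- do.call(pmin, lapply(good, function(j) keys[, j]))
    rank_of_min_good <- 1 + rowSums(keys < min_good)
    mean(rank_of_min_good <= X)
  })
}

#' Score-RMSD correlation coefficients
#'
#' Spearman, Pearson and Kendall correlations between pose scores and their
#' RMSDs to the reference (ties mid-ranked).  Constant input yields NA
#' values flagged as undefined rather than propagating NaN.
#'
#' @param scores,rmsds numeric vectors of equal length (n >= 3).
#' @return list with \code{spearman}, \code{pearson}, \code{kendall} and
#'   logical \code{defined}.
#' @export
score_rmsd_correlations <- function(scores, rmsds) {
  if (length(scores) != length(rmsds)) stop_usage("length mismatch")
  if (length(scores) < 3) stop_usage("need at least 3 poses")
  if (stats::sd(scores) == 0 || stats::sd(rmsds) == 0) {
    warning("constant input; correlations undefined")
    return(list(spearman = NA_real_, pearson = NA_real_, kendall = NA_real_,
                defined = FALSE))
  }
  list(spearman = stats::cor(scores, rmsds, method = "spearman"),
       pearson = stats::cor(scores, rmsds, method = "pearson"),
       kendall = stats::cor(scores, rmsds, method = "kendall"),
       defined = TRUE)
}

#' Per-complex and aggregate docking-evaluation report
#'
#' Computes S(1), S(3), S(5), the SR(X,C) indicators for X in \{3, 5\} and
#' C in \{2, 5\} Angstrom, Monte-Carlo random baselines for the same SR
#' settings, and score-RMSD correlations, then aggregates across complexes.
#'
#' @param complexes named list; each element a data.frame (or list) with
#'   \code{score} and \code{rmsd} per pose.
#' @param n_draws Monte-Carlo draws for the baselines (default 100000).
#' @param seed integer seed for the baselines.
#' @return list of class \code{"eval_report"} with \code{per_complex}
#'   (data.frame) and \code{aggregate} (named numeric).
#' @export
eval_report <- function(complexes, n_draws = 100000, seed = 1) {
  rows <- lapply(names(complexes), function(id) {
    cx <- complexes[[id]]
    ord <- order(cx$score, seq_along(cx$score))
    r <- cx$rmsd[ord]
    cors <- if (length(r) >= 3)
      suppressWarnings(score_rmsd_correlations(cx$score, cx$rmsd))
    else list(spearman = NA_real_, pearson = NA_real_, kendall = NA_real_)
    base <- function(X, C) if (X <= length(r))
      random_baseline(cx$rmsd, X, C, n_draws = n_draws, seed = seed) else NA_real_
    sr <- function(X, C) success_rate(r, X, C)
    data.frame(
      complex_id = id, n_poses = length(r),
      S1 = s_of_x(r, 1), S3 = s_of_x(r, 3), S5 = s_of_x(r, 5),
      SR_3_2 = sr(3, 2), SR_3_5 = sr(3, 5), SR_5_2 = sr(5, 2), SR_5_5 = sr(5, 5),
      base_3_2 = base(3, 2), base_3_5 = base(3, 5),
      base_5_2 = base(5, 2), base_5_5 = base(5, 5),
      spearman = cors$spearman, pearson = cors$pearson, kendall = cors$kendall,
      stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  agg_cols <- c("S1", "S3", "S5", "SR_3_2", "SR_3_5", "SR_5_2", "SR_5_5",
                "base_3_2", "base_3_5", "base_5_2", "base_5_5",
                "spearman", "pearson", "kendall")
  agg <- colMeans(per[, agg_cols], na.rm = TRUE)
  structure(list(per_complex = per, aggregate = agg), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d complexes\n", nrow(x$per_complex)))
  cat(sprintf("  mean S(1)=%.2f  S(3)=%.2f  S(5)=%.2f A\n",
              x$aggregate["S1"], x$aggregate["S3"], x$aggregate["S5"]))
  cat(sprintf("  SR(3,2)=%.2f (random %.2f)  SR(5,2)=%.2f (random %.2f)\n",
              x$aggregate["SR_3_2"], x$aggregate["base_3_2"],
              x$aggregate["SR_5_2"], x$aggregate["base_5_2"]))
  invisible(x)
}
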