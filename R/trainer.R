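# Training-side primitives: pose labeling, [0,1] rescaling, ENN denoising,
# class balancing, path fingerprints and k-Medoids ligand clustering.

#' Pose labelling policy
#'
#' Poses with symmetry-corrected RMSD to the native pose in
#' [\code{pos_low}, \code{pos_high}] are positives, poses at or beyond
#' \code{neg_min} are negatives; everything else (near-duplicates below
#' \code{pos_low} and the gap up to \code{neg_min}) is excluded.
#'
#' @param pos_low,pos_high,neg_min band edges in Angstrom
#'   (defaults 0.1, 1.5, 4.0).
#' @return list of class \code{"label_policy"}.
#' @export
label_policy <- function(pos_low = 0.1, pos_high = 1.5, neg_min = 4.0) {
  if (!(0 <= pos_low && pos_low < pos_high && pos_high < neg_min))
    stop_usage("label policy must satisfy 0 <= pos_low < pos_high < neg_min")
  structure(list(pos_low = pos_low, pos_high = pos_high, neg_min = neg_min),
            class = "label_policy")
}

#' Label poses by RMSD to the native pose
#'
#' @param rmsd_to_native numeric vector of RMSDs (Angstrom, non-negative).
#' @param policy a \code{\link{label_policy}}.
#' @return character vector in \{"positive", "negative", "excluded"\}.
#' @export
label_pose <- function(rmsd_to_native, policy = label_policy()) {
  if (any(rmsd_to_native < 0)) stop_data("negative RMSD")
  ifelse(rmsd_to_native >= policy$pos_low & rmsd_to_native <= policy$pos_high,
         "positive",
         ifelse(rmsd_to_native >= policy$neg_min, "negative", "excluded"))
}

# --- feature scaling --------------------------------------------------------

fit_scaler <- function(X) {
  list(min = apply(X, 2, min), max = apply(X, 2, max))
}

apply_scaler <- function(scaler, X) {
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- 1   # degenerate feature maps to 0
  sweep(sweep(X, 2, scaler$min), 2, rng, "/")
}

# --- ENN --------------------------------------------------------------------

#' Edited Nearest Neighbours label-noise filter
#'
#' Single pass: a record is removed when the majority label among its k
#' nearest neighbours (Euclidean, excluding itself) disagrees with its own
#' label.  Ties keep the record.
#'
#' @param X numeric matrix of (scaled) features.
#' @param labels character/factor vector, one per row.
#' @param k neighbourhood size (default 3).
#' @return integer indices of surviving rows.
#' @export
enn_filter <- function(X, labels, k = 3) {
  n <- nrow(X)
  if (n < k + 1) {
    warning("fewer than k+1 records; ENN left the data unchanged")
    return(seq_len(n))
  }
  labels <- as.character(labels)
  D <- as.matrix(stats::dist(X))
  keep <- logical(n)
  for (i in seq_len(n)) {
    ord <- order(D[i, -i], seq_len(n)[-i])
    nn <- (seq_len(n)[-i])[ord[seq_len(k)]]
    votes <- table(labels[nn])
    top <- max(votes)
    winners <- names(votes)[votes == top]
    keep[i] <- labels[i] %in% winners
  }
  which(keep)
}

#' Balance classes by random undersampling
#'
#' The majority class is undersampled (without replacement) to the minority
#' count; deterministic under a fixed seed.
#'
#' @param labels character vector with exactly two classes present.
#' @param seed integer seed.
#' @return integer indices of the retained rows, in original order.
#' @export
balance_classes <- function(labels, seed = 1) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2)
    stop_data("class balancing needs both classes present (got only '%s')",
              classes[1])
  counts <- table(labels)
  n_min <- min(counts)
  keep <- with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      idx <- which(labels == cl)
      if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
    }))
  })
  sort(keep)
}

# --- fingerprints & ligand clustering --------------------------------------

# Deterministic polynomial hash of a string, mod nbits.
hash_string <- function(s, nbits) {
  h <- 0
  for (b in as.integer(charToRaw(s)))
    h <- (h * 31 + b) %% nbits
  as.integer(h) + 1L
}

#' Hashed linear-path fingerprint of a ligand bond graph
#'
#' Enumerates all simple paths of up to \code{maxdepth} heavy atoms, encodes
#' each as an element/bond-order string (canonical direction), and hashes it
#' into a fixed-width bit vector.  Only the relative Tanimoto structure of
#' the fingerprints matters for ligand clustering; the exact scheme is
#' configurable via its parameters.
#'
#' @param mol a \code{ligand}.
#' @param nbits fingerprint width (default 2048).
#' @param maxdepth maximum path length in atoms (default 5).
#' @return logical vector of length \code{nbits}.
#' @export
ligand_fingerprint <- function(mol, nbits = 2048, maxdepth = 5) {
  heavy <- which(mol$atoms$elem != "H")
  fp <- logical(nbits)
  if (length(heavy) == 0) return(fp)
  nb <- neighbors_of(mol)
  lut <- bond_lookup(mol)
  elem <- mol$atoms$elem
  ordc <- function(i, j) {
    id <- lut[paste(min(i, j), max(i, j))]
    if (mol$bonds$aromatic[id]) "a" else as.character(round(mol$bonds$order[id]))
  }
  emit <- function(path) {
    s <- elem[path[1]]
    if (length(path) > 1)
      for (k in 2:length(path))
        s <- paste0(s, ordc(path[k - 1], path[k]), elem[path[k]])
    r <- paste(rev(strsplit(s, NULL)[[1]]), collapse = "")
    fp[hash_string(min(s, r), nbits)] <<- TRUE
  }
  walk <- function(path) {
    emit(path)
    if (length(path) >= maxdepth) return()
    tip <- path[length(path)]
    for (j in nb[[tip]]) {
      if (j %in% path || elem[j] == "H") next
      walk(c(path, j))
    }
  }
  for (i in heavy) walk(i)
  fp
}

#' Tanimoto similarity of two bit fingerprints
#' @param a,b logical vectors of equal length.
#' @return similarity in [0, 1] (1 when both are empty).
#' @export
tanimoto <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Cluster ligands by fingerprint Tanimoto distance (k-Medoids)
#'
#' Partitioning around medoids on the distance 1 - Tanimoto; the PAM
#' build/swap algorithm is deterministic, so identical inputs give identical
#' splits regardless of seed.
#'
#' @param fingerprints list of logical fingerprint vectors (or a logical
#'   matrix, one row per ligand).
#' @param k number of clusters (default 5).
#' @param seed kept for interface symmetry; PAM itself is deterministic.
#' @return integer cluster assignment, one per ligand.
#' @export
cluster_ligands <- function(fingerprints, k = 5, seed = 1) {
  if (is.matrix(fingerprints))
    fingerprints <- lapply(seq_len(nrow(fingerprints)), function(i) fingerprints[i, ])
  n <- length(fingerprints)
  if (k > n) stop_usage("k = %d exceeds the number of ligands (%d)", k, n)
  if (k == 1) return(rep(1L, n))
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- 1 - tanimoto(fingerprints[[i]], fingerprints[[j]])
  as.integer(cluster::pam(stats::as.dist(D), k = k, diss = TRUE,
                          cluster.only = TRUE))
}
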