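# Contact enumeration and the five geometric descriptors (d, alpha, beta,
# gamma, delta) of an RNA-bead / pharmacophore pair.

# Partner bead used to build the alpha/beta angle axis: base beads pair with
# C4', C4' pairs with P, P pairs with C4'.  Configurable convention.
PARTNER_BEAD <- function(bead) if (bead == "C4'") "P" else "C4'"

#' All possible contact-group keys
#'
#' The cross product of 4 bases, their 5 pseudoatom beads, and 6 pharmacophore
#' types, giving 120 keys of the canonical form \code{"base:bead:ptype"}.
#'
#' @return character vector of length 120.
#' @export
group_keys <- function() {
  out <- character()
  for (base in c("A", "C", "G", "U"))
    for (bead in BEAD_NAMES[[base]])
      for (pt in PHARM_TYPES)
        out <- c(out, paste(base, bead, pt, sep = ":"))
  out
}

#' Geometric descriptors of one bead/pharmacophore contact
#'
#' Computes the distance \code{d} and the four angles (degrees, in [0, 180]):
#' \code{alpha} at the bead between bead->partner-bead and bead->point,
#' \code{beta} between the partner->bead axis and the pharmacophore direction,
#' \code{gamma} between the base-plane normal and bead->point, and
#' \code{delta} between the base-plane normal and the pharmacophore direction.
#' Components whose defining geometry is absent (missing partner bead, no
#' plane normal, undirected pharmacophore) are returned as NA, never
#' fabricated.
#'
#' @param residue_cg one residue of an \code{rna_cg}.
#' @param bead_name bead to measure from (must be present).
#' @param point one pharmacophore point.
#' @return named numeric: d, alpha, beta, gamma, delta.
#' @export
contact_geometry <- function(residue_cg, bead_name, point) {
  beads <- residue_cg$beads
  if (!bead_name %in% rownames(beads))
    stop_data("bead '%s' absent from residue", bead_name)
  bead <- beads[bead_name, ]
  center <- point$center
  v_bp <- center - bead
  d <- vnorm(v_bp)
  alpha <- beta <- gamma <- delta <- NA_real_
  partner_name <- PARTNER_BEAD(bead_name)
  if (partner_name %in% rownames(beads)) {
    partner <- beads[partner_name, ]
    axis <- bead - partner               # partner -> bead
    alpha <- angle_deg(partner - bead, v_bp) # at the bead: bead->partner vs bead->point
    if (!is.null(point$direction))
      beta <- angle_deg(axis, point$direction)
  }
  nrm <- residue_cg$plane_normal
  if (!is.null(nrm)) {
    gamma <- angle_deg(nrm, v_bp)
    if (!is.null(point$direction))
      delta <- angle_deg(nrm, point$direction)
  }
  c(d = d, alpha = alpha, beta = beta, gamma = gamma, delta = delta)
}

#' Enumerate RNA-ligand contacts within the interaction cutoff
#'
#' One record per (usable residue bead, pharmacophore point) pair whose
#' Euclidean distance is at most \code{cutoff} (default 10 Angstrom), in
#' deterministic order (residue, bead-table order, point index).
#'
#' @param cg_rna an \code{rna_cg}.
#' @param pharm_points a \code{pharm_set}.
#' @param cutoff interaction threshold in Angstrom.
#' @return data.frame with columns base, bead, ptype, key, d, alpha, beta,
#'   gamma, delta, res_index, point_index.
#' @export
enumerate_contacts <- function(cg_rna, pharm_points, cutoff = 10) {
  if (cutoff <= 0) stop_usage("cutoff must be positive")
  if (length(pharm_points) == 0 || length(cg_rna) == 0)
    return(empty_contacts())
  centers <- t(vapply(pharm_points, `[[`, numeric(3), "center"))
  ptypes <- vapply(pharm_points, `[[`, "", "type")
  rows <- vector("list", 0)
  for (ri in seq_along(cg_rna)) {
    res <- cg_rna[[ri]]
    if (!isTRUE(res$usable) || nrow(res$beads) == 0) next
    for (bead_name in rownames(res$beads)) {
      bead <- res$beads[bead_name, ]
      dd <- sqrt(colSums((t(centers) - bead)^2))
      hits <- which(dd <= cutoff)
      for (pi in hits) {
        geo <- contact_geometry(res, bead_name, pharm_points[[pi]])
        rows[[length(rows) + 1]] <- data.frame(
          base = res$base, bead = bead_name, ptype = ptypes[pi],
          key = paste(res$base, bead_name, ptypes[pi], sep = ":"),
          d = geo["d"], alpha = geo["alpha"], beta = geo["beta"],
          gamma = geo["gamma"], delta = geo["delta"],
          res_index = ri, point_index = pi,
          stringsAsFactors = FALSE, row.names = NULL)
      }
    }
  }
  if (length(rows) == 0) return(empty_contacts())
  do.call(rbind, rows)
}

empty_contacts <- function() {
  data.frame(base = character(), bead = character(), ptype = character(),
             key = character(), d = numeric(), alpha = numeric(),
             beta = numeric(), gamma = numeric(), delta = numeric(),
             res_index = integer(), point_index = integer(),
             stringsAsFactors = FALSE)
}

#' Write a contact table to CSV
#'
#' Schema: complex_id, pose_id, base, bead, ptype, d, alpha, beta, gamma,
#' delta, label; missing values are empty fields.
#'
#' @param contacts contact data.frame (label optional).
#' @param path output CSV.
#' @param complex_id,pose_id identifiers filled in when the table lacks them.
#' @return \code{path}, invisibly.
#' @export
write_contacts <- function(contacts, path, complex_id = "complex", pose_id = 1L) {
  df <- contacts
  if (is.null(df$complex_id)) df$complex_id <- complex_id
  if (is.null(df$pose_id)) df$pose_id <- pose_id
  if (is.null(df$label)) df$label <- NA_character_
  cols <- c("complex_id", "pose_id", "base", "bead", "ptype",
            "d", "alpha", "beta", "gamma", "delta", "label")
  utils::write.csv(df[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a contact table written by \code{\link{write_contacts}}
#' @param path CSV file.
#' @return contact data.frame with a \code{key} column rebuilt.
#' @export
read_contacts <- function(path) {
  if (!file.exists(path)) stop_data("cannot read contact table '%s'", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("base", "bead", "ptype", "d")
  if (!all(need %in% names(df)))
    stop_data("'%s' is not a contact table (missing columns: %s)", path,
              paste(setdiff(need, names(df)), collapse = ", "))
  df$key <- paste(df$base, df$bead, df$ptype, sep = ":")
  df
}
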