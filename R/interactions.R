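#' Hydrogen-bond strength class from donor-acceptor distance
#'
#' Heavy-atom donor-acceptor distance bins: strong below 2.5 A, moderate
#' in `[2.5, 3.2)`, weak in `[3.2, 4.0)`, none at 4.0 A or beyond.
#'
#' @param distance Positive donor-acceptor distance(s) in Angstrom.
#' @return Character vector: `"strong"`, `"moderate"`, `"weak"`, `"none"`.
#' @examples
#' classify_hbond(2.73)  # moderate
#' classify_hbond(3.99)  # weak
#' @export
classify_hbond <- function(distance) {
  if (any(!is.finite(distance)) || any(distance <= 0))
    stop("classify_hbond: distance must be positive")
  ifelse(distance < 2.5, "strong",
         ifelse(distance < 3.2, "moderate",
                ifelse(distance < 4.0, "weak", "none")))
}

# aromatic ring atom names per residue type (6-membered ring used for Trp)
.ring_atoms <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

.receptor_table <- function(receptor) {
  if (inherits(receptor, "pdb")) receptor <- receptor$atom
  receptor <- as.data.frame(receptor)
  need <- c("resid", "resno", "x", "y", "z")
  if (!all(need %in% names(receptor)))
    stop("profile_interactions: receptor lacks residue annotations (",
         paste(setdiff(need, names(receptor)), collapse = ", "), ")")
  if (!"chain" %in% names(receptor)) receptor$chain <- "A"
  if (!"elety" %in% names(receptor)) receptor$elety <- ""
  if (!"elesy" %in% names(receptor) || all(is.na(receptor$elesy)))
    receptor$elesy <- substr(trimws(receptor$elety), 1, 1)
  receptor
}

#' Profile receptor-ligand interactions for a docked pose
#'
#' Detects, per residue, (i) hydrophobic contacts: any ligand carbon
#' within `hydrophobic_cut` of a residue carbon; (ii) hydrogen bonds: any
#' ligand N/O within 4.0 A of a residue N/O, classified by
#' [classify_hbond()]; (iii) pi-cation contacts: a cationic ligand
#' nitrogen within `pication_cut` of an aromatic side-chain ring centroid
#' (Phe/Tyr/Trp/His). One record per (residue, type) with the minimal
#' distance.
#'
#' @param receptor A `bio3d` pdb object or a data frame with columns
#'   `resid`, `resno`, `chain`, `elety`, `elesy`, `x`, `y`, `z`.
#' @param p A `gt_pose` in the receptor frame.
#' @param cation_atoms Indices of ligand atoms treated as cationic
#'   nitrogens; defaults to nitrogen atoms flagged in
#'   `attr(p, "cation")` or, failing that, none.
#' @param hydrophobic_cut Carbon-carbon cutoff in A (default 4.5).
#' @param hbond_cut Donor-acceptor cutoff in A (default 4.0).
#' @param pication_cut Cation-to-centroid cutoff in A (default 6.0).
#' @return Data frame `residue, type, distance_A, class` (zero rows when
#'   no contact is found).
#' @export
profile_interactions <- function(receptor, p, cation_atoms = NULL,
                                 hydrophobic_cut = 4.5, hbond_cut = 4.0,
                                 pication_cut = 6.0) {
  stopifnot(inherits(p, "gt_pose"))
  rec <- .receptor_table(receptor)
  rec$elesy <- toupper(trimws(rec$elesy))
  rec$key <- sprintf("%s%d%s", rec$resid, rec$resno,
                     ifelse(is.na(rec$chain) | rec$chain == "", "",
                            paste0(":", rec$chain)))
  lig_xyz <- p$coords
  lig_el <- toupper(p$elements)
  if (is.null(cation_atoms)) cation_atoms <- attr(p, "cation")

  recs <- list()
  add <- function(residue, type, dist) {
    recs[[length(recs) + 1L]] <<- data.frame(
      residue = residue, type = type, distance_A = dist,
      class = if (type == "hbond") classify_hbond(dist) else
        if (dist <= hydrophobic_cut || type == "pi-cation") "contact" else "none",
      stringsAsFactors = FALSE)
  }

  for (key in unique(rec$key)) {
    rr <- rec[rec$key == key, , drop = FALSE]
    rxyz <- as.matrix(rr[, c("x", "y", "z")])
    # hydrophobic: ligand C vs residue C
    ci <- which(lig_el == "C"); cj <- which(rr$elesy == "C")
    if (length(ci) && length(cj)) {
      d <- .min_cross_dist(lig_xyz[ci, , drop = FALSE], rxyz[cj, , drop = FALSE])
      if (d <= hydrophobic_cut) add(key, "hydrophobic", d)
    }
    # H-bond: ligand N/O vs residue N/O (heavy-atom distance only)
    hi <- which(lig_el %in% c("N", "O")); hj <- which(rr$elesy %in% c("N", "O"))
    if (length(hi) && length(hj)) {
      d <- .min_cross_dist(lig_xyz[hi, , drop = FALSE], rxyz[hj, , drop = FALSE])
      if (d < hbond_cut) add(key, "hbond", d)
    }
    # pi-cation: cationic ligand N vs aromatic ring centroid
    ring <- .ring_atoms[[rr$resid[1]]]
    if (!is.null(ring) && length(cation_atoms)) {
      ra <- rr[trimws(rr$elety) %in% ring, , drop = FALSE]
      if (nrow(ra) >= 3L) {
        centroid <- colMeans(as.matrix(ra[, c("x", "y", "z")]))
        d <- min(sqrt(rowSums(sweep(lig_xyz[cation_atoms, , drop = FALSE],
                                    2, centroid)^2)))
        if (d <= pication_cut) add(key, "pi-cation", d)
      }
    }
  }
  if (length(recs) == 0L)
    return(data.frame(residue = character(0), type = character(0),
                      distance_A = numeric(0), class = character(0)))
  out <- do.call(rbind, recs)
  out[order(out$residue, out$type), , drop = FALSE]
}

#' Read a receptor structure from a PDB file
#'
#' Thin wrapper over `bio3d::read.pdb` returning the annotated atom table
#' expected by [profile_interactions()].
#'
#' @param path PDB file path.
#' @return Data frame `resid, resno, chain, elety, elesy, x, y, z`.
#' @export
read_receptor_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  .receptor_table(pdb)
}

.min_cross_dist <- function(a, b) {
  dd <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(dd)))
}
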