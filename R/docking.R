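#' Axis-aligned docking grid box
#'
#' @param center Numeric length-3 center (x, y, z) in Angstrom.
#' @param dims Numeric length-3 box edge lengths in Angstrom (positive).
#' @param target Target identifier (e.g. a PDB id).
#' @return A `gt_grid_box`.
#' @export
grid_box <- function(center, dims, target = "") {
  center <- as.numeric(center); dims <- as.numeric(dims)
  stopifnot(length(center) == 3L, length(dims) == 3L)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("grid_box: dimensions must be positive")
  structure(list(center = center, dims = dims, target = target),
            class = "gt_grid_box")
}

#' Published grid boxes for the two docking targets
#'
#' The aldose-reductase (PDB 2IKH) box is centered at
#' (14.17, -0.095, 23.464) with dimensions 60 x 40 x 56 A; the glucokinase
#' (PDB 4IXC) box at (63.267, 25.856, 0.231) with dimensions 66 x 72 x 66 A.
#'
#' @return Named list of two `gt_grid_box` objects (`"2IKH"`, `"4IXC"`).
#' @export
default_grid_boxes <- function() {
  list(`2IKH` = grid_box(c(14.17, -0.095, 23.464), c(60, 40, 56), "2IKH"),
       `4IXC` = grid_box(c(63.267, 25.856, 0.231), c(66, 72, 66), "4IXC"))
}

#' Construct a docked ligand pose
#'
#' @param coords Numeric matrix (n x 3) of ligand atom coordinates (A),
#'   receptor frame.
#' @param elements Character vector of element symbols, length n.
#' @param ea Affinity energy E_A in kcal/mol (finite).
#' @param run,index Run and pose indices within the docking campaign.
#' @param bonds Optional data.frame `a1, a2` of ligand bonds (used for
#'   symmetry-aware RMSD).
#' @return A `gt_pose`.
#' @export
pose <- function(coords, elements, ea = NA_real_, run = 1L, index = 1L,
                 bonds = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, nrow(coords) == length(elements))
  if (any(!is.finite(coords))) stop("pose: coordinates must be complete")
  if (!is.na(ea) && !is.finite(ea)) stop("pose: affinity energy must be finite")
  structure(list(coords = coords, elements = as.character(elements),
                 ea = ea, run = as.integer(run), index = as.integer(index),
                 bonds = bonds),
            class = "gt_pose")
}

#' @export
print.gt_pose <- function(x, ...) {
  cat(sprintf("<gt_pose> %d atoms, E_A = %s kcal/mol (run %d, pose %d)\n",
              nrow(x$coords), format(x$ea), x$run, x$index))
  invisible(x)
}

# bonds from covalent-radius distance when none are recorded
.infer_bonds <- function(coords, elements, slack = 0.45) {
  rad <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, Cl = 1.02,
           Br = 1.20, I = 1.39, S = 1.05, P = 1.07)
  r <- rad[elements]; r[is.na(r)] <- 0.77
  n <- nrow(coords)
  out <- list(); k <- 0L
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (d <= r[i] + r[j] + slack) { k <- k + 1L; out[[k]] <- c(i, j) }
  }
  if (k == 0L) return(data.frame(a1 = integer(0), a2 = integer(0)))
  m <- do.call(rbind, out)
  data.frame(a1 = m[, 1], a2 = m[, 2])
}

# all element-preserving graph automorphisms of the ligand, capped;
# falls back to the identity with a warning beyond the cap
.ligand_automorphisms <- function(p, max_perms = 1e4) {
  bonds <- p$bonds
  if (is.null(bonds)) bonds <- .infer_bonds(p$coords, p$elements)
  n <- nrow(p$coords)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds) > 0L)
    g <- igraph::add_edges(g, rbind(bonds$a1, bonds$a2))
  col <- as.integer(factor(p$elements))
  isos <- tryCatch(
    igraph::subgraph_isomorphisms(pattern = g, target = g, method = "vf2",
                                  vertex.color1 = col, vertex.color2 = col),
    error = function(e) NULL)
  if (is.null(isos) || length(isos) == 0L) return(list(seq_len(n)))
  if (length(isos) > max_perms) {
    warning(sprintf(
      "pose_rmsd: %d automorphisms exceed the cap of %d; using identity mapping",
      length(isos), max_perms))
    return(list(seq_len(n)))
  }
  lapply(isos, as.integer)
}

#' Root-mean-square deviation between two poses
#'
#' RMSD in the shared receptor frame (docking convention: no
#' re-superposition). When `symmetry_aware = TRUE` the RMSD is minimized
#' over the element-preserving graph automorphisms of the ligand
#' connectivity (capped at `max_perms` permutations, falling back to the
#' identity mapping with a warning).
#'
#' @param a,b `gt_pose` objects with identical element multisets.
#' @param symmetry_aware Minimize over automorphism relabelings
#'   (default `FALSE`).
#' @param max_perms Automorphism cap (default 1e4).
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(a, b, symmetry_aware = FALSE, max_perms = 1e4) {
  stopifnot(inherits(a, "gt_pose"), inherits(b, "gt_pose"))
  if (nrow(a$coords) != nrow(b$coords))
    stop("pose_rmsd: atom-count mismatch")
  if (!identical(sort(a$elements), sort(b$elements)))
    stop("pose_rmsd: element multisets differ")
  plain <- function(idx) sqrt(mean(rowSums((a$coords[idx, , drop = FALSE] -
                                              b$coords)^2)))
  if (!symmetry_aware) {
    if (!identical(a$elements, b$elements))
      stop("pose_rmsd: atom order differs; use symmetry_aware = TRUE")
    return(plain(seq_len(nrow(a$coords))))
  }
  perms <- .ligand_automorphisms(a, max_perms)
  perms <- Filter(function(pm) identical(a$elements[pm], b$elements), perms)
  if (length(perms) == 0L) perms <- list(seq_len(nrow(a$coords)))
  min(vapply(perms, plain, numeric(1)))
}

#' Select the best docking pose under the acceptance criterion
#'
#' Pools poses (e.g. 50 independent runs of 20 poses each), keeps those
#' with affinity energy below `ea_cut` and, when a reference pose is
#' given, RMSD to the reference below `rmsd_cut`, and selects the
#' lowest-energy survivor. The verdict is `"rejected"` when no pose
#' passes.
#'
#' @param poses List of `gt_pose` objects (non-empty).
#' @param reference Optional reference `gt_pose` (e.g. the crystallographic
#'   ligand); when `NULL` the RMSD filter is skipped.
#' @param ea_cut Affinity-energy cut in kcal/mol (default -6.0; strict `<`).
#' @param rmsd_cut RMSD cut in Angstrom (default 2.0; strict `<`).
#' @param symmetry_aware Use symmetry-aware RMSD (default `TRUE`).
#' @return A `gt_docking_result`: list with `poses`, `best` (a `gt_pose`
#'   or `NULL`), `best_rmsd`, `verdict` (`"accepted"`/`"rejected"`), and
#'   the cuts used.
#' @export
select_best_pose <- function(poses, reference = NULL, ea_cut = -6.0,
                             rmsd_cut = 2.0, symmetry_aware = TRUE) {
  if (length(poses) == 0L) stop("select_best_pose: empty pose set")
  stopifnot(all(vapply(poses, inherits, TRUE, "gt_pose")))
  ea <- vapply(poses, `[[`, numeric(1), "ea")
  if (any(is.na(ea))) stop("select_best_pose: every pose needs an affinity energy")
  rmsd <- if (is.null(reference)) rep(NA_real_, length(poses)) else
    vapply(poses, pose_rmsd, numeric(1), b = reference,
           symmetry_aware = symmetry_aware)
  pass <- ea < ea_cut & (is.null(reference) | (!is.na(rmsd) & rmsd < rmsd_cut))
  if (!any(pass)) {
    return(structure(list(poses = poses, ea = ea, rmsd = rmsd, best = NULL,
                          best_rmsd = NA_real_, verdict = "rejected",
                          ea_cut = ea_cut, rmsd_cut = rmsd_cut),
                     class = "gt_docking_result"))
  }
  idx <- which(pass)
  # deterministic, order-invariant tie-break: energy, then rmsd, run, index
  key <- order(ea[idx],
               ifelse(is.na(rmsd[idx]), Inf, rmsd[idx]),
               vapply(poses[idx], `[[`, integer(1), "run"),
               vapply(poses[idx], `[[`, integer(1), "index"))
  best_i <- idx[key[1]]
  structure(list(poses = poses, ea = ea, rmsd = rmsd,
                 best = poses[[best_i]], best_rmsd = rmsd[best_i],
                 verdict = "accepted", ea_cut = ea_cut, rmsd_cut = rmsd_cut),
            class = "gt_docking_result")
}

#' @export
print.gt_docking_result <- function(x, ...) {
  cat(sprintf("<gt_docking_result> %d poses, verdict: %s\n",
              length(x$poses), x$verdict))
  if (!is.null(x$best))
    cat(sprintf("  best: E_A = %.3f kcal/mol, RMSD = %s A\n",
                x$best$ea, format(x$best_rmsd)))
  invisible(x)
}

#' Fraction of ligand atoms inside a grid box
#'
#' Half-open axis-aligned convention: an atom on the minimum face is
#' inside, one exactly on the maximum face is outside.
#'
#' @param box A `gt_grid_box`.
#' @param p A `gt_pose`.
#' @return Fraction in `[0, 1]`.
#' @export
gridbox_contains <- function(box, p) {
  stopifnot(inherits(box, "gt_grid_box"), inherits(p, "gt_pose"))
  lo <- box$center - box$dims / 2
  hi <- box$center + box$dims / 2
  inside <- vapply(seq_len(nrow(p$coords)), function(i)
    all(p$coords[i, ] >= lo & p$coords[i, ] < hi), logical(1))
  mean(inside)
}

#' Read docked poses from a multi-record SDF file
#'
#' Each SDF record becomes one pose; the affinity energy is taken from the
#' data field named by `ea_field`.
#'
#' @param path SDF file path.
#' @param ea_field Name of the SDF data field holding E_A in kcal/mol
#'   (default `"E_A"`).
#' @return List of `gt_pose` objects.
#' @export
read_sdf_poses <- function(path, ea_field = "E_A") {
  sdfs <- ChemmineR::read.SDFset(path)
  lapply(seq_along(sdfs), function(i) {
    sdf <- sdfs[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    el <- gsub("_.*$", "", rownames(ab))
    dat <- ChemmineR::datablock(sdf)
    ea <- if (ea_field %in% names(dat)) as.numeric(dat[[ea_field]]) else NA_real_
    pose(ab[, 1:3, drop = FALSE], el, ea = ea, run = 1L, index = i,
         bonds = data.frame(a1 = as.integer(bb[, 1]),
                            a2 = as.integer(bb[, 2])))
  })
}

#' Read docked poses from a Vina-style PDBQT file
#'
#' Parses `MODEL` blocks, taking the affinity energy from each block's
#' `REMARK VINA RESULT` line and atom coordinates/elements from
#' ATOM/HETATM records.
#'
#' @param path PDBQT file path.
#' @return List of `gt_pose` objects (one per model).
#' @export
read_pdbqt_poses <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) starts <- 1L
  ends <- c(starts[-1] - 1L, length(lines))
  poses <- vector("list", length(starts))
  for (m in seq_along(starts)) {
    blk <- lines[starts[m]:ends[m]]
    vr <- grep("^REMARK VINA RESULT", blk, value = TRUE)
    ea <- if (length(vr) > 0L)
      as.numeric(strsplit(trimws(sub("^REMARK VINA RESULT:?", "", vr[1])),
                          "[ ]+")[[1]][1])
    else NA_real_
    at <- grep("^(ATOM|HETATM)", blk, value = TRUE)
    if (length(at) == 0L) stop("read_pdbqt_poses: model without atom records")
    coords <- cbind(as.numeric(substr(at, 31, 38)),
                    as.numeric(substr(at, 39, 46)),
                    as.numeric(substr(at, 47, 54)))
    # PDBQT atom types (column 78+) carry AutoDock types; map to elements
    typ <- toupper(trimws(substr(at, 78, 79)))
    el <- sub("^(BR|CL).*", "\\1", typ)
    el <- vapply(el, function(t) {
      if (t %in% c("BR", "CL")) {
        paste0(substr(t, 1, 1), tolower(substr(t, 2, 2)))
      } else substr(t, 1, 1)
    }, "")
    poses[[m]] <- pose(coords, unname(el), ea = ea, run = 1L, index = m)
  }
  poses
}
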