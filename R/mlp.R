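#' Default fragment lipophilicity constants
#'
#' A compact per-element atomic-contribution table in the spirit of the
#' Wildman-Crippen scheme (values are representative class means; the
#' table is fully configurable and any named numeric vector keyed by
#' element symbol may be substituted).
#'
#' @return Named numeric vector of lipophilicity constants f_i.
#' @export
lipophilicity_constants <- function() {
  c(H = 0.12, C = 0.27, N = -0.60, O = -0.23, F = 0.44, Cl = 0.65,
    Br = 0.86, I = 0.88, S = 0.41, P = 0.12)
}

.mlp_distance_fun <- function(id) {
  switch(id,
    exp = function(d) exp(-d / 2),
    fauchere = function(d) 1 / (1 + d),
    stop(sprintf("mlp_field: unknown distance function '%s'", id))
  )
}

#' Molecular lipophilicity potential field
#'
#' Evaluates, at each query point k, the sum over molecular fragments i of
#' `f_i * F(d_ik)`, where `f_i` is the fragment lipophilicity constant and
#' `F` a decreasing function of the fragment-point distance `d_ik` (in
#' Angstrom). Fragments are the heavy atoms of the molecule; constants are
#' looked up by element symbol.
#'
#' @param mol A `gt_molecule` with coordinates.
#' @param points Numeric matrix (n x 3) of evaluation points, or `NULL` to
#'   use a dotted solvent-accessible surface from [sas_points()].
#' @param constants Named numeric vector of fragment constants; must cover
#'   every element present.
#' @param distance_fun `"exp"` for `F(d) = exp(-d/2)` (default) or
#'   `"fauchere"` for `F(d) = 1/(1+d)`.
#' @return A `gt_mlp_field`: list with `points`, `mlp` (one value per
#'   point), `constants`, `distance_fun`, and `n_fragments`.
#' @export
mlp_field <- function(mol, points = NULL,
                      constants = lipophilicity_constants(),
                      distance_fun = "exp") {
  stopifnot(inherits(mol, "gt_molecule"))
  if (!mol$has_coords) stop("mlp_field: molecule has no coordinates")
  if (is.null(points)) points <- sas_points(mol)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("mlp_field: points must be an n x 3 matrix")
  missing_el <- setdiff(unique(mol$atoms$element), names(constants))
  if (length(missing_el) > 0L) {
    where <- vapply(missing_el, function(el)
      paste(which(mol$atoms$element == el), collapse = ","), "")
    stop("mlp_field: no fragment constant for atom environment(s): ",
         paste(sprintf("%s (atom %s)", missing_el, where), collapse = "; "))
  }
  FUN <- .mlp_distance_fun(distance_fun)
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  f <- constants[mol$atoms$element]
  mlp <- vapply(seq_len(nrow(points)), function(k) {
    d <- sqrt(colSums((t(xyz) - points[k, ])^2))
    sum(f * FUN(d))
  }, numeric(1))
  structure(list(points = points, mlp = mlp, constants = constants,
                 distance_fun = distance_fun, n_fragments = nrow(xyz)),
            class = "gt_mlp_field")
}

#' @export
print.gt_mlp_field <- function(x, ...) {
  cat(sprintf("<gt_mlp_field> %d points, %d fragments, F = %s; range [%.3f, %.3f]\n",
              nrow(x$points), x$n_fragments, x$distance_fun,
              min(x$mlp), max(x$mlp)))
  invisible(x)
}

#' Write an MLP field as CSV (`x,y,z,mlp`)
#'
#' @param field A `gt_mlp_field`.
#' @param path Output file path.
#' @export
write_mlp_csv <- function(field, path) {
  stopifnot(inherits(field, "gt_mlp_field"))
  df <- data.frame(x = field$points[, 1], y = field$points[, 2],
                   z = field$points[, 3], mlp = field$mlp)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, Cl = 1.75,
                Br = 1.85, I = 1.98, S = 1.80, P = 1.80)

#' Dotted solvent-accessible surface points
#'
#' Deterministic Fibonacci-lattice dots on each atom's solvent-accessible
#' sphere (van der Waals radius + probe), with dots buried inside any other
#' atom's accessible sphere removed.
#'
#' @param mol A `gt_molecule` with coordinates.
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param dots_per_atom Dots per atom before burial filtering (default 96).
#' @return Numeric matrix (n x 3) of surface points.
#' @export
sas_points <- function(mol, probe = 1.4, dots_per_atom = 96L) {
  stopifnot(inherits(mol, "gt_molecule"), mol$has_coords)
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  rad <- .vdw_radii[mol$atoms$element]
  rad[is.na(rad)] <- 1.7
  rad <- rad + probe
  # Fibonacci sphere: deterministic, seed-free
  i <- seq_len(dots_per_atom) - 0.5
  phi <- acos(1 - 2 * i / dots_per_atom)
  theta <- pi * (1 + sqrt(5)) * i
  unit <- cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  out <- vector("list", nrow(xyz))
  for (a in seq_len(nrow(xyz))) {
    pts <- sweep(unit * rad[a], 2, xyz[a, ], "+")
    keep <- rep(TRUE, nrow(pts))
    for (b in seq_len(nrow(xyz))) {
      if (b == a) next
      keep <- keep & (sqrt(rowSums(sweep(pts, 2, xyz[b, ])^2)) >= rad[b] - 1e-9)
    }
    out[[a]] <- pts[keep, , drop = FALSE]
  }
  do.call(rbind, out)
}
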