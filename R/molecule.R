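#' Parse a chemical structure from SMILES or an SDF/molfile record
#'
#' Reads a single structure from a SMILES line (optionally `SMILES<TAB>id`)
#' or a V2000 SDF/molfile record, sanitizes it through OpenBabel (aromaticity
#' perception, implicit hydrogens), and returns a `gt_molecule` object holding
#' the atom table, bond table and, when present, 3-D coordinates in Angstrom.
#'
#' @param text Character scalar: a SMILES string (optionally followed by a
#'   tab-separated identifier) or a full SDF/molfile record.
#' @param id Optional identifier; overrides any id carried by `text`.
#' @param format One of `"auto"`, `"smiles"`, `"sdf"`. With `"auto"`,
#'   multi-line input containing `V2000` is treated as SDF.
#' @return A `gt_molecule`: list with `id`, `atoms` (data.frame
#'   `element`, `charge`, `aromatic`, `x`, `y`, `z`), `bonds` (data.frame
#'   `a1`, `a2`, `order`), `has_coords`, `smiles` (canonical), and `molfile`.
#' @examples
#' mol <- parse_structure("C", id = "methane")
#' mol$n_atoms
#' @export
parse_structure <- function(text, id = NULL, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("parse_structure: input must be a non-empty character scalar")
  if (format == "auto")
    format <- if (grepl("\n", text) && grepl("V2000", text)) "sdf" else "smiles"

  if (format == "smiles") {
    parts <- strsplit(sub("\n.*$", "", text), "[\t ]+")[[1]]
    smi <- parts[1]
    if (is.null(id)) id <- if (length(parts) > 1L) parts[2] else "mol"
    .smiles_sanity(smi)
    molfile <- tryCatch(
      ChemmineOB::convertFormat("SMI", "SDF", paste0(smi, "\t", id)),
      error = function(e) ""
    )
    if (!nzchar(molfile) || !grepl("V2000", molfile))
      stop(sprintf("parse_structure: unparsable SMILES '%s'", smi))
  } else {
    molfile <- text
    if (!grepl("\\$\\$\\$\\$", molfile)) molfile <- paste0(molfile, "\n$$$$\n")
  }

  parsed <- .parse_v2000(molfile)
  if (format == "sdf" && is.null(id)) {
    hdr <- trimws(strsplit(molfile, "\n")[[1]][1])
    id <- if (nzchar(hdr)) hdr else "mol"
  }
  if (nrow(parsed$atoms) < 1L)
    stop("parse_structure: structure contains no atoms")

  smiles <- tryCatch(
    trimws(sub("[\t ].*$", "",
               ChemmineOB::convertFormat("SDF", "CAN", molfile))),
    error = function(e) NA_character_)

  structure(list(
    id = id,
    atoms = parsed$atoms,
    bonds = parsed$bonds,
    n_atoms = nrow(parsed$atoms),
    has_coords = parsed$has_coords,
    smiles = smiles,
    molfile = molfile
  ), class = "gt_molecule")
}

# quick pre-scan so common SMILES defects are reported with a position;
# OpenBabel itself only warns on stderr
.smiles_sanity <- function(smi) {
  chars <- strsplit(smi, "")[[1]]
  depth <- 0L
  ring <- integer(0)
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("parse_structure: unmatched ')' at position %d in '%s'", i, smi))
    }
    if (grepl("[0-9]", ch) && (i == 1L || chars[i - 1L] != "%")) {
      d <- as.integer(ch)
      if (d %in% ring) ring <- setdiff(ring, d) else ring <- c(ring, d)
    }
  }
  if (depth != 0L)
    stop(sprintf("parse_structure: unmatched '(' in '%s'", smi))
  if (length(ring) > 0L)
    stop(sprintf("parse_structure: unclosed ring bond %s in '%s'",
                 paste(ring, collapse = ","), smi))
  invisible(TRUE)
}

# minimal V2000 reader for the counts/atom/bond block; ChemmineR's SDF
# container rejects bond-less records (single heavy atoms), so the atom
# table is lifted directly from the text
.parse_v2000 <- function(molfile) {
  lines <- strsplit(molfile, "\n")[[1]]
  ci <- grep("V2000", lines)[1]
  if (is.na(ci)) stop("parse_structure: no V2000 counts line found")
  counts <- lines[ci]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  atom_lines <- lines[seq.int(ci + 1L, length.out = na)]
  atoms <- data.frame(
    element = trimws(substr(atom_lines, 32, 34)),
    charge = 0L,
    x = as.numeric(substr(atom_lines, 1, 10)),
    y = as.numeric(substr(atom_lines, 11, 20)),
    z = as.numeric(substr(atom_lines, 21, 30)),
    stringsAsFactors = FALSE
  )
  bonds <- if (nb > 0L) {
    bl <- lines[seq.int(ci + na + 1L, length.out = nb)]
    data.frame(
      a1 = as.integer(substr(bl, 1, 3)),
      a2 = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  } else {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }
  # M  CHG lines override the (deprecated) atom-block charge column
  for (cl in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", cl)), "[ ]+")[[1]])
    n <- toks[1]
    for (k in seq_len(n)) atoms$charge[toks[2 * k]] <- toks[2 * k + 1L]
  }
  if (nrow(bonds) > 0L &&
      (any(bonds$a1 < 1L | bonds$a1 > na) || any(bonds$a2 < 1L | bonds$a2 > na)))
    stop("parse_structure: bond references a non-existent atom")
  # aromaticity: bond order 4 in molfile, else from ring perception upstream
  atoms$aromatic <- FALSE
  if (nrow(bonds) > 0L) {
    ar <- unique(c(bonds$a1[bonds$order == 4L], bonds$a2[bonds$order == 4L]))
    atoms$aromatic[ar] <- TRUE
  }
  has_coords <- any(abs(atoms$x) > 1e-8 | abs(atoms$y) > 1e-8 | abs(atoms$z) > 1e-8) ||
    na == 1L
  list(atoms = atoms, bonds = bonds, has_coords = has_coords)
}

#' @export
print.gt_molecule <- function(x, ...) {
  cat(sprintf("<gt_molecule> %s: %d atoms, %d bonds%s\n", x$id, x$n_atoms,
              nrow(x$bonds), if (x$has_coords) " (3-D)" else ""))
  invisible(x)
}

#' Count atoms of each element in a molecule
#'
#' @param mol A `gt_molecule`.
#' @return Named integer vector of element counts (heavy atoms as drawn;
#'   implicit hydrogens are not counted).
#' @export
atom_counts <- function(mol) {
  stopifnot(inherits(mol, "gt_molecule"))
  tab <- table(mol$atoms$element)
  stats::setNames(as.integer(tab), names(tab))
}

#' Generate deterministic 3-D coordinates for a molecule
#'
#' Embeds the molecule with OpenBabel's distance-geometry/forcefield
#' generator. The generator is deterministic for a given input structure,
#' so repeated calls give identical coordinates.
#'
#' @param mol A `gt_molecule`.
#' @return A `gt_molecule` with coordinates filled in.
#' @export
embed_3d <- function(mol) {
  stopifnot(inherits(mol, "gt_molecule"))
  if (mol$has_coords && any(abs(mol$atoms$z) > 1e-8)) return(mol)
  out <- ChemmineOB::convertFormat(
    "SMI", "SDF", paste0(mol$smiles, "\t", mol$id),
    options = data.frame(names = "gen3d", args = "", stringsAsFactors = FALSE))
  if (!nzchar(out)) stop("embed_3d: 3-D embedding failed")
  parse_structure(out, id = mol$id, format = "sdf")
}

#' Read a multi-compound SMILES file
#'
#' One structure per line, `SMILES<TAB>id` (a second whitespace-separated
#' token is also accepted as the id).
#'
#' @param path File path.
#' @return List of `gt_molecule` objects, named by id.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  mols <- lapply(lines, parse_structure)
  stats::setNames(mols, vapply(mols, `[[`, "", "id"))
}
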