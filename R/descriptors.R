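#' Compute the six MPO physicochemical attributes for a molecule
#'
#' Molecular weight, Ertl topological polar surface area (TPSA) and the
#' H-bond donor count are computed from the structure through OpenBabel.
#' Intrinsic lipophilicity (logP) is computed by the Wildman-Crippen
#' atomic-contribution scheme only when not supplied; logD at pH 7.4 and
#' basic pKa are predictor outputs and can only be supplied. Supplied
#' values are never overwritten by computed ones, and the provenance of
#' every field is recorded.
#'
#' @param mol A `gt_molecule` (see [parse_structure()]).
#' @param supplied Named list/vector of predictor-supplied values; any of
#'   `mw`, `tpsa`, `hbd`, `logp`, `logd74`, `pka_basic`, `dg_hyd`.
#' @return A `gt_descriptor_set`: list with the seven fields plus
#'   `provenance` (named character, `"computed"` / `"supplied"` / `"absent"`)
#'   and `compound_id`.
#' @examples
#' d <- compute_descriptors(parse_structure("C", id = "methane"))
#' d$tpsa  # 0
#' @export
compute_descriptors <- function(mol, supplied = list()) {
  stopifnot(inherits(mol, "gt_molecule"))
  supplied <- as.list(supplied)
  bad <- setdiff(names(supplied),
                 c("mw", "tpsa", "hbd", "logp", "logd74", "pka_basic", "dg_hyd"))
  if (length(bad) > 0L)
    stop("compute_descriptors: unknown supplied field(s): ",
         paste(bad, collapse = ", "))

  p <- ChemmineOB::forEachMol("SDF", mol$molfile,
                              function(m) ChemmineOB::prop_OB(m))[[1]]
  fields <- list(
    mw = as.numeric(p$MW),
    tpsa = as.numeric(p$TPSA),
    hbd = as.integer(p$HBD),
    logp = as.numeric(p$logP),
    logd74 = NA_real_,
    pka_basic = NA_real_,
    dg_hyd = NA_real_
  )
  prov <- c(mw = "computed", tpsa = "computed", hbd = "computed",
            logp = "computed", logd74 = "absent", pka_basic = "absent",
            dg_hyd = "absent")
  for (nm in names(supplied)) {
    val <- supplied[[nm]]
    if (is.null(val) || is.na(val)) next
    fields[[nm]] <- if (nm == "hbd") as.integer(val) else as.numeric(val)
    prov[[nm]] <- "supplied"
  }
  stopifnot(fields$mw > 0, fields$tpsa >= 0, fields$hbd >= 0L)
  structure(c(list(compound_id = mol$id), fields, list(provenance = prov)),
            class = "gt_descriptor_set")
}

#' Assemble a descriptor set from a table row (no structure required)
#'
#' @param row Named list/one-row data.frame with `compound_id` and any of
#'   the descriptor columns `mw`, `tpsa`, `hbd`, `logp`, `logd74`,
#'   `pka_basic`, `dg_hyd`.
#' @return A `gt_descriptor_set` with all present fields marked `supplied`.
#' @export
descriptor_set <- function(row) {
  row <- as.list(row)
  fields <- list(mw = NA_real_, tpsa = NA_real_, hbd = NA_integer_,
                 logp = NA_real_, logd74 = NA_real_, pka_basic = NA_real_,
                 dg_hyd = NA_real_)
  prov <- stats::setNames(rep("absent", length(fields)), names(fields))
  for (nm in names(fields)) {
    if (!is.null(row[[nm]]) && !is.na(row[[nm]])) {
      fields[[nm]] <- if (nm == "hbd") as.integer(row[[nm]]) else as.numeric(row[[nm]])
      prov[[nm]] <- "supplied"
    }
  }
  structure(c(list(compound_id = if (is.null(row$compound_id)) "mol" else
                     as.character(row$compound_id)),
              fields, list(provenance = prov)),
            class = "gt_descriptor_set")
}

#' @export
print.gt_descriptor_set <- function(x, ...) {
  cat(sprintf("<gt_descriptor_set> %s\n", x$compound_id))
  for (nm in c("mw", "tpsa", "hbd", "logp", "logd74", "pka_basic", "dg_hyd"))
    cat(sprintf("  %-9s %10s  [%s]\n", nm, format(x[[nm]]), x$provenance[[nm]]))
  invisible(x)
}

#' Thermodynamic configuration for the logP/hydration-energy relation
#'
#' @param temperature Temperature in Kelvin (default 298.15).
#' @param gas_constant Gas constant in kcal mol^-1 K^-1; fixed default
#'   1.987e-3.
#' @param negate Sign-convention flag. The literal relation gives positive
#'   hydration free energy for positive logP; `negate = TRUE` flips the
#'   sign so that lipophilic compounds map onto the negative
#'   hydration-energy region used in solvation work.
#' @return A `gt_thermo_config`.
#' @export
thermo_config <- function(temperature = 298.15, gas_constant = 1.987e-3,
                          negate = FALSE) {
  if (!is.numeric(temperature) || temperature <= 0)
    stop("thermo_config: temperature must be > 0 K")
  structure(list(temperature = temperature, gas_constant = gas_constant,
                 negate = isTRUE(negate)),
            class = "gt_thermo_config")
}

#' Convert between logP and hydration free energy
#'
#' Implements the linear relation `logP = dG_hyd / (2.303 R T)` (and its
#' inverse), with `dG_hyd` in kcal/mol. The `negate` flag of the
#' configuration flips the sign of `dG_hyd` on both directions.
#'
#' @param value Finite numeric vector: logP values (`direction =
#'   "to_dghyd"`) or hydration free energies in kcal/mol (`direction =
#'   "to_logp"`).
#' @param cfg A [thermo_config()].
#' @param direction `"to_dghyd"` or `"to_logp"`.
#' @return Numeric vector of converted values.
#' @examples
#' logp_dghyd(1.0, thermo_config(), "to_dghyd")  # 1.364 kcal/mol
#' @export
logp_dghyd <- function(value, cfg = thermo_config(),
                       direction = c("to_dghyd", "to_logp")) {
  direction <- match.arg(direction)
  stopifnot(inherits(cfg, "gt_thermo_config"))
  if (!all(is.finite(value))) stop("logp_dghyd: value must be finite")
  k <- 2.303 * cfg$gas_constant * cfg$temperature
  s <- if (cfg$negate) -1 else 1
  if (direction == "to_dghyd") s * value * k else (s * value) / k
}
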