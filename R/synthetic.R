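#' Simulation specification for the synthetic-data generators
#'
#' Bundles the seed, group sizes, noise level and ground-truth parameters
#' shared by the generators. Identical specifications produce byte-identical
#' outputs (integer-seeded Mersenne-Twister).
#'
#' @param seed Integer seed.
#' @param n_per_group Animals (or replicates) per group; default 7, the
#'   study-design group size.
#' @param sigma Multiplicative noise scale (lognormal; default 0.02).
#' @param ... Generator-specific ground-truth parameters stored verbatim.
#' @return A `gt_sim_spec`.
#' @export
sim_spec <- function(seed = 2129L, n_per_group = 7L, sigma = 0.02, ...) {
  stopifnot(is.numeric(seed), n_per_group >= 1L, sigma >= 0)
  structure(c(list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
                   sigma = sigma), list(...)),
            class = "gt_sim_spec")
}

.spec_get <- function(spec, name, default) {
  if (!is.null(spec[[name]])) spec[[name]] else default
}

#' Generate a synthetic glucose tolerance test dataset
#'
#' The control group follows a rise-and-decay glycemia template
#' (piecewise-linear rise from baseline to peak at 15 min, exponential
#' decay back). Each treatment group reduces post-overload glycemia by its
#' reduction factor: with `scale = "raw"` (default) the raw glycemia at
#' t > 0 is multiplied by `1 - f`, so the group-mean percent reduction at
#' each timepoint equals `100 f` exactly at `sigma = 0`; with
#' `scale = "excursion"` only the above-baseline excursion is scaled, so
#' the baseline-corrected AUC is reduced by exactly `100 f` percent.
#' Animal-level noise is multiplicative lognormal.
#'
#' @param spec A [sim_spec()]; recognized fields: `reductions` (named
#'   numeric vector of per-group reduction factors in `[0, 1]`), `times`
#'   (default `c(0, 15, 30, 60, 180)` min), `baseline` (90 mg/dL), `peak`
#'   (270 mg/dL), `decay_tau` (60 min), `scale`, `control` (group label,
#'   default `"hyperglycemic"`).
#' @return A `gt_gtt_dataset` data frame
#'   `animal, group, time_min, glycemia_mg_dl` with ground truth in
#'   attribute `"truth"`.
#' @export
gen_gtt <- function(spec = sim_spec(reductions = c(treatment = 0.5))) {
  stopifnot(inherits(spec, "gt_sim_spec"))
  if (spec$n_per_group < 1L) stop("gen_gtt: n_per_group must be >= 1")
  times <- .spec_get(spec, "times", c(0, 15, 30, 60, 180))
  baseline <- .spec_get(spec, "baseline", 90)
  peak <- .spec_get(spec, "peak", 270)
  tau <- .spec_get(spec, "decay_tau", 60)
  reductions <- .spec_get(spec, "reductions", c(treatment = 0.5))
  ctrl <- .spec_get(spec, "control", "hyperglycemic")
  scale <- match.arg(.spec_get(spec, "scale", "raw"), c("raw", "excursion"))

  shape <- ifelse(times <= 15, times / 15, exp(-(times - 15) / tau))
  template <- baseline + (peak - baseline) * shape
  curves <- c(stats::setNames(list(template), ctrl),
              lapply(reductions, function(f) {
                if (scale == "raw")
                  ifelse(times > 0, template * (1 - f), template)
                else baseline + (1 - f) * (template - baseline)
              }))

  set.seed(spec$seed)
  rows <- list()
  for (g in names(curves)) for (a in seq_len(spec$n_per_group)) {
    noise <- if (spec$sigma > 0) exp(stats::rnorm(length(times), 0, spec$sigma))
             else rep(1, length(times))
    rows[[length(rows) + 1L]] <- data.frame(
      animal = sprintf("%s_%02d", g, a), group = g, time_min = times,
      glycemia_mg_dl = curves[[g]] * noise)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  truth <- list(reductions = reductions, baseline = baseline, peak = peak,
                times = times, scale = scale, sigma = spec$sigma,
                seed = spec$seed, control = ctrl,
                curves = curves,
                auc = vapply(curves, function(y)
                  gtt_auc(times, y, baseline_corrected = TRUE,
                          window = c(0, min(120, max(times)))), numeric(1)))
  attr(out, "truth") <- truth
  class(out) <- c("gt_gtt_dataset", class(out))
  out
}

#' Generate a synthetic insulin tolerance test dataset
#'
#' Glycemia decays as `G0 * exp(-(Kitt_true / 100) * t)` with per-animal
#' multiplicative lognormal noise; a group with `Kitt_true = 0` is flat
#' (insulin-resistant beyond measure).
#'
#' @param spec A [sim_spec()]; recognized fields: `kitt_true` (named
#'   numeric vector of true disappearance constants in %/min, >= 0),
#'   `times` (default `c(0, 7, 14, 28)` min), `g0` (150 mg/dL).
#' @return A `gt_itt_dataset` data frame
#'   `animal, group, time_min, glycemia_mg_dl` with ground truth in
#'   attribute `"truth"`.
#' @export
gen_itt <- function(spec = sim_spec(kitt_true = c(control = 2.31))) {
  stopifnot(inherits(spec, "gt_sim_spec"))
  kitt_true <- .spec_get(spec, "kitt_true", c(control = 2.31))
  if (any(kitt_true < 0)) stop("gen_itt: true Kitt must be >= 0")
  times <- .spec_get(spec, "times", c(0, 7, 14, 28))
  g0 <- .spec_get(spec, "g0", 150)

  set.seed(spec$seed + 1L)
  rows <- list()
  for (g in names(kitt_true)) for (a in seq_len(spec$n_per_group)) {
    mu <- g0 * exp(-(kitt_true[[g]] / 100) * times)
    noise <- if (spec$sigma > 0) exp(stats::rnorm(length(times), 0, spec$sigma))
             else rep(1, length(times))
    rows[[length(rows) + 1L]] <- data.frame(
      animal = sprintf("%s_%02d", g, a), group = g, time_min = times,
      glycemia_mg_dl = mu * noise)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(kitt_true = kitt_true, g0 = g0, times = times,
                             sigma = spec$sigma, seed = spec$seed)
  class(out) <- c("gt_itt_dataset", class(out))
  out
}

#' Generate synthetic descriptor, PK, toxicity and affinity tables
#'
#' Descriptor attributes are uniform draws within configurable ranges,
#' with an optional planted MPO-perfect lead (all six attributes strictly
#' inside the full-desirability thresholds, and the lowest affinity
#' energies) for end-to-end recovery tests. Toxicity endpoint
#' probabilities are Gaussian-copula draws with a planted correlation
#' `rho` between one endpoint pair.
#'
#' @param spec A [sim_spec()]; recognized fields: `n_compounds` (default
#'   12), `ranges` (named list `c(min, max)` per attribute), `plant_perfect`
#'   (default `TRUE`), `rho` (planted endpoint correlation, default 0.85),
#'   `rho_pair` (default `c("dili", "hht")`).
#' @return List `descriptors`, `pk`, `tox`, `ea` (data frames) and `truth`.
#' @export
gen_descriptor_table <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "gt_sim_spec"))
  n <- .spec_get(spec, "n_compounds", 12L)
  ranges <- .spec_get(spec, "ranges", list(
    logp = c(0.5, 4.5), logd74 = c(0, 3.5), mw = c(250, 480),
    tpsa = c(30, 110), hbd = c(0, 3), pka_basic = c(5, 10)))
  for (r in ranges) if (r[1] > r[2])
    stop("gen_descriptor_table: ranges must be well-ordered")
  plant <- isTRUE(.spec_get(spec, "plant_perfect", TRUE))
  rho <- .spec_get(spec, "rho", 0.85)
  rho_pair <- .spec_get(spec, "rho_pair", c("dili", "hht"))

  set.seed(spec$seed + 2L)
  runifr <- function(r) stats::runif(n, r[1], r[2])
  descriptors <- data.frame(
    compound_id = sprintf("CMP%03d", seq_len(n)),
    mw = runifr(ranges$mw), tpsa = runifr(ranges$tpsa),
    hbd = round(runifr(ranges$hbd)), logp = runifr(ranges$logp),
    logd74 = runifr(ranges$logd74), pka_basic = runifr(ranges$pka_basic))
  pk <- data.frame(
    compound_id = descriptors$compound_id,
    papp_caco2 = stats::runif(n, 1e-6, 30e-6),
    papp_mdck = stats::runif(n, 2e-6, 3e-5),
    vdss = stats::runif(n, 0.5, 8),
    f_oral = stats::runif(n, 0.5, 1),
    cl_hepa_human = stats::runif(n, 5, 120),
    cl_micro = stats::runif(n, 1, 12),
    fdamdd = stats::runif(n, 0.005, 0.05))
  endpoints <- c("dili", "ames", "roa", "fdamdd_tox", "hht", "neuro")
  rho_pair[rho_pair == "fdamdd"] <- "fdamdd_tox"
  z <- matrix(stats::rnorm(n * length(endpoints)), n,
              dimnames = list(NULL, endpoints))
  z[, rho_pair[2]] <- rho * z[, rho_pair[1]] +
    sqrt(max(0, 1 - rho^2)) * z[, rho_pair[2]]
  tox <- cbind(data.frame(compound_id = descriptors$compound_id),
               as.data.frame(stats::pnorm(z)))
  ea <- do.call(rbind, lapply(c("2IKH", "4IXC"), function(tg)
    data.frame(compound_id = descriptors$compound_id, target = tg,
               ea = stats::runif(n, -10, -6.5))))
  planted_id <- NULL
  if (plant) {
    planted_id <- "PLANTED_LEAD"
    descriptors <- rbind(descriptors, data.frame(
      compound_id = planted_id, mw = 330, tpsa = 65, hbd = 1,
      logp = 2.0, logd74 = 1.5, pka_basic = 7.0))
    pk <- rbind(pk, data.frame(
      compound_id = planted_id, papp_caco2 = 25e-6, papp_mdck = 2.2e-5,
      vdss = 5, f_oral = 0.95, cl_hepa_human = 12, cl_micro = 4,
      fdamdd = 0.03))
    tox <- rbind(tox, cbind(data.frame(compound_id = planted_id),
                            as.data.frame(stats::pnorm(
                              matrix(stats::rnorm(length(endpoints)), 1,
                                     dimnames = list(NULL, endpoints))))))
    ea <- rbind(ea, data.frame(compound_id = planted_id,
                               target = c("2IKH", "4IXC"),
                               ea = c(-12.0, -11.5)))
  }
  list(descriptors = descriptors, pk = pk, tox = tox, ea = ea,
       truth = list(planted_lead = planted_id, rho = rho,
                    rho_pair = rho_pair, seed = spec$seed,
                    n_compounds = n))
}

# template fragments used by gen_toy_complex ---------------------------

.hexagon <- function(center, radius = 1.39, plane = "xy") {
  ang <- 2 * pi * (0:5) / 6
  if (plane == "xy")
    cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang),
          center[3])
  else
    cbind(center[1], center[2] + radius * cos(ang),
          center[3] + radius * sin(ang))
}

#' Generate a toy receptor-ligand complex with planted contacts
#'
#' Builds a minimal receptor (one residue fragment per requested contact,
#' each in its own spatial zone 25 A apart so contacts cannot interfere)
#' and a matching ligand probe, such that every requested interaction sits
#' at exactly its requested distance: hydrophobic contacts place a
#' benzene probe a given carbon-carbon distance from a side-chain ring;
#' H-bonds place a carbonyl-type oxygen at a given distance from a ligand
#' nitrogen; pi-cation contacts place an aromatic six-ring centroid at a
#' given distance directly above a cationic ligand nitrogen.
#'
#' @param contacts Data frame `type` (`"hydrophobic"`, `"hbond"`,
#'   `"pication"`), `resname` (e.g. `"PHE"`), `resno`, `distance` (A).
#'   Zero rows give an empty receptor and a one-atom probe.
#' @param spec A [sim_spec()] (only the seed is used, for reproducible
#'   zone jitter-free output; the construction is deterministic).
#' @return List `receptor` (data frame `resid, resno, chain, elety, elesy,
#'   x, y, z`), `ligand` (a `gt_pose` with `attr(, "cation")` set), and
#'   `truth` (the contact table).
#' @export
gen_toy_complex <- function(contacts, spec = sim_spec()) {
  if (is.null(contacts) || nrow(contacts) == 0L) {
    lig <- pose(matrix(c(0, 0, 0), 1), "C", ea = -7)
    return(list(receptor = data.frame(resid = character(0),
                                      resno = integer(0), chain = character(0),
                                      elety = character(0), elesy = character(0),
                                      x = numeric(0), y = numeric(0),
                                      z = numeric(0)),
                ligand = lig, truth = contacts))
  }
  stopifnot(all(c("type", "resname", "resno", "distance") %in% names(contacts)))
  if (any(contacts$distance <= 1.0))
    stop("gen_toy_complex: conflicting geometry (distance must exceed 1 A)")

  lig_xyz <- NULL; lig_el <- character(0); cation <- integer(0)
  rec <- list()
  add_rec <- function(resname, resno, names, xyz) {
    rec[[length(rec) + 1L]] <<- data.frame(
      resid = resname, resno = resno, chain = "A", elety = names,
      elesy = substr(names, 1, 1), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  for (i in seq_len(nrow(contacts))) {
    zc <- c(25 * (i - 1L), 0, 0)   # zone center
    ty <- contacts$type[i]; d <- contacts$distance[i]
    rn <- toupper(contacts$resname[i]); no <- contacts$resno[i]
    if (ty == "hydrophobic") {
      ring <- .hexagon(zc)                       # ligand benzene probe
      lig_xyz <- rbind(lig_xyz, ring); lig_el <- c(lig_el, rep("C", 6))
      # residue ring: nearest-carbon gap equals d along +x
      rring <- .hexagon(zc + c(2 * 1.39 + d, 0, 0))
      nm <- .ring_atoms[[rn]]
      if (is.null(nm)) nm <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
      add_rec(rn, no, nm[seq_len(6)], rring)
    } else if (ty == "hbond") {
      lig_xyz <- rbind(lig_xyz, matrix(zc, 1)); lig_el <- c(lig_el, "N")
      oxy <- matrix(zc + c(d, 0, 0), 1)
      cc <- matrix(zc + c(d + 1.23, 0, 0), 1)
      add_rec(rn, no, c("OD1", "CG"), rbind(oxy, cc))
    } else if (ty == "pication") {
      lig_xyz <- rbind(lig_xyz, matrix(zc, 1)); lig_el <- c(lig_el, "N")
      cation <- c(cation, nrow(lig_xyz))
      ring <- .hexagon(zc + c(0, 0, d))          # centroid exactly at d
      nm <- .ring_atoms[[rn]]
      if (is.null(nm)) nm <- c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
      add_rec(rn, no, nm[seq_len(6)], ring)
    } else {
      stop(sprintf("gen_toy_complex: unknown contact type '%s'", ty))
    }
  }
  lig <- pose(lig_xyz, lig_el, ea = -7)
  attr(lig, "cation") <- cation
  list(receptor = do.call(rbind, rec), ligand = lig, truth = contacts)
}

#' Write generator output and its ground truth to disk
#'
#' Writes the dataset as CSV and its `"truth"` attribute (or supplied
#' truth list) as a JSON sidecar `<stem>_truth.json`, so downstream tests
#' never re-derive the generating parameters.
#'
#' @param data Data frame from a generator.
#' @param stem Output path stem (no extension).
#' @param truth Truth list; defaults to `attr(data, "truth")`.
#' @return Invisibly, the CSV path.
#' @export
write_synthetic <- function(data, stem, truth = attr(data, "truth")) {
  csv <- paste0(stem, ".csv")
  df <- as.data.frame(data)
  attr(df, "truth") <- NULL
  utils::write.csv(df, csv, row.names = FALSE)
  if (!is.null(truth))
    jsonlite::write_json(truth, paste0(stem, "_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csv)
}
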