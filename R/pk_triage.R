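#' Classify apparent membrane permeability (BCS-style bands)
#'
#' Applies the permeability rule: `Papp(A->B) > 20e-6 cm/s` is high
#' permeability with an expected human intestinal absorption (HIA) of
#' about 96%. Below 1e-6 cm/s is low; in between, moderate. The
#' order-of-magnitude band of the measurement (e.g. `1e-05`) is reported
#' alongside `logPapp = log10(Papp)`.
#'
#' @param papp Apparent permeability in cm/s (positive numeric vector).
#' @param line Cell line label, `"Caco-2"` or `"MDCK"` (annotation only).
#' @return Data frame `papp, line, log_papp, band, class, hia` where `hia`
#'   is 0.96 for high-permeability compounds and `NA` otherwise.
#' @examples
#' classify_permeability(25e-6)$class    # "high"
#' classify_permeability(1.77e-5)$class  # "moderate"
#' @export
classify_permeability <- function(papp, line = c("Caco-2", "MDCK")) {
  line <- match.arg(line)
  if (!all(is.finite(papp)) || any(papp <= 0))
    stop("classify_permeability: papp must be positive and finite")
  log_papp <- log10(papp)
  cls <- ifelse(papp > 20e-6, "high", ifelse(papp < 1e-6, "low", "moderate"))
  data.frame(
    papp = papp,
    line = line,
    log_papp = log_papp,
    band = 10^floor(log_papp),
    class = cls,
    hia = ifelse(cls == "high", 0.96, NA_real_)
  )
}

#' Metabolic-stability flags from clearance values
#'
#' Strict-threshold rules: hepatocyte clearance `Cl_Hepa < 100`
#' uL/min/10^6 cells flags `stable`; `Cl_Hepa < 20` additionally flags
#' `enhanced` stability; microsomal clearance `Cl_Micro < 8.0` uL/min/mg
#' flags `microsomal_stable`. Absent values leave the corresponding flag
#' undetermined (`NA`).
#'
#' @param cl_hepa Hepatocyte clearance (uL/min/10^6 cells) or `NA`.
#' @param cl_micro Microsomal clearance (uL/min/mg) or `NA`.
#' @return Named logical vector `stable`, `enhanced`, `microsomal_stable`.
#' @export
stability_flags <- function(cl_hepa = NA, cl_micro = NA) {
  if (all(is.na(c(cl_hepa, cl_micro))))
    stop("stability_flags: at least one clearance value is required")
  c(stable = if (is.na(cl_hepa)) NA else cl_hepa < 100,
    enhanced = if (is.na(cl_hepa)) NA else cl_hepa < 20,
    microsomal_stable = if (is.na(cl_micro)) NA else cl_micro < 8.0)
}

#' Oral-bioavailability and lipophilicity-risk flags
#'
#' `oral_risk` flags the combination logD7.4 > 2.8 with MW > 450 g/mol
#' (high-lipophilicity bioavailability risk); `high_f` flags predicted
#' oral bioavailability fraction >= 0.9 (inclusive); `fdamdd_exceeded`
#' flags an FDA maximum-daily-dose bound below 0.011 mmol/kg-bw/day.
#'
#' @param logd74 Distribution coefficient at pH 7.4.
#' @param mw Molecular weight (g/mol).
#' @param f_oral Predicted oral bioavailability fraction in `[0, 1]`
#'   (optional).
#' @param fdamdd Predicted maximum daily dose bound (mmol/kg-bw/day,
#'   optional).
#' @param dose_limit Dose threshold (default 0.011 mmol/kg-bw/day).
#' @return Named logical vector `oral_risk`, `high_f`, `fdamdd_exceeded`
#'   (`NA` where inputs are absent).
#' @export
bioavailability_and_risk <- function(logd74, mw, f_oral = NA, fdamdd = NA,
                                     dose_limit = 0.011) {
  if (is.na(logd74) || is.na(mw))
    stop("bioavailability_and_risk: logd74 and mw are required")
  c(oral_risk = logd74 > 2.8 && mw > 450,
    high_f = if (is.na(f_oral)) NA else f_oral >= 0.9,
    fdamdd_exceeded = if (is.na(fdamdd)) NA else fdamdd < dose_limit)
}

#' Pearson similarity matrix of toxicity endpoints
#'
#' Correlates predicted toxicity-endpoint probabilities across compounds
#' (columns = endpoints, rows = compounds by default; set
#' `orientation = "compounds"` to correlate compounds instead). Constant
#' columns yield `NaN` rows/columns with a warning rather than being
#' coerced to zero.
#'
#' @param profiles Numeric matrix or data frame of probabilities in
#'   `[0, 1]`; rows are compounds, columns endpoints.
#' @param orientation `"endpoints"` (default) or `"compounds"`.
#' @return Symmetric correlation matrix with unit diagonal (where defined).
#' @export
tox_similarity <- function(profiles, orientation = c("endpoints", "compounds")) {
  orientation <- match.arg(orientation)
  m <- as.matrix(profiles)
  if (!is.numeric(m)) stop("tox_similarity: profiles must be numeric")
  if (any(m < 0 | m > 1, na.rm = TRUE))
    stop("tox_similarity: probabilities must lie in [0, 1]")
  if (orientation == "compounds") m <- t(m)
  if (nrow(m) < 3L) stop("tox_similarity: need >= 3 observations")
  if (ncol(m) < 2L) stop("tox_similarity: need >= 2 variables")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    warning("tox_similarity: constant column(s) ",
            paste(colnames(m)[sds == 0], collapse = ", "),
            " yield undefined correlations (NaN)")
  suppressWarnings(stats::cor(m, method = "pearson"))
}

#' Rank lead compounds by MPO score, then affinity energy
#'
#' Lexicographic ranking convention: higher MPO desirability score first;
#' ties broken by lower mean affinity energy across targets; remaining
#' ties by compound id.
#'
#' @param mpo Data frame `compound_id, D` (e.g. from [mpo_table()]).
#' @param ea Data frame `compound_id, target, ea` of affinity energies in
#'   kcal/mol (at least one row per compound).
#' @return Data frame ordered by rank: `rank, compound_id, D, mean_ea`.
#' @export
rank_leads <- function(mpo, ea) {
  stopifnot(all(c("compound_id", "D") %in% names(mpo)),
            all(c("compound_id", "ea") %in% names(ea)))
  if (!all(mpo$compound_id %in% ea$compound_id))
    stop("rank_leads: every compound needs at least one affinity energy")
  mean_ea <- tapply(ea$ea, ea$compound_id, mean)
  out <- data.frame(compound_id = mpo$compound_id, D = mpo$D,
                    mean_ea = as.numeric(mean_ea[mpo$compound_id]))
  ord <- order(-out$D, out$mean_ea, out$compound_id)
  out <- out[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Rule-based triage report for a compound panel
#'
#' Combines permeability classes, stability flags, bioavailability and
#' risk flags into one table; every flag is traceable to its rule id.
#'
#' @param descriptors Descriptor table (`compound_id, mw, ..., logd74`).
#' @param pk PK table with any of `papp_caco2`, `papp_mdck` (cm/s),
#'   `vdss`, `f_oral`, `cl_hepa_human`, `cl_hepa_rat`, `cl_micro`,
#'   `cl_int_u`, `fdamdd` columns, keyed by `compound_id`.
#' @return Data frame, one row per compound, with flag columns; rule ids
#'   in attribute `"rules"`.
#' @export
triage_report <- function(descriptors, pk) {
  stopifnot("compound_id" %in% names(descriptors),
            "compound_id" %in% names(pk))
  ids <- descriptors$compound_id
  pk <- pk[match(ids, pk$compound_id), , drop = FALSE]
  getcol <- function(df, nm) if (nm %in% names(df)) df[[nm]] else rep(NA_real_, length(ids))
  caco <- getcol(pk, "papp_caco2"); mdck <- getcol(pk, "papp_mdck")
  rows <- lapply(seq_along(ids), function(i) {
    perm_c <- if (is.na(caco[i])) NULL else classify_permeability(caco[i], "Caco-2")
    perm_m <- if (is.na(mdck[i])) NULL else classify_permeability(mdck[i], "MDCK")
    stab <- tryCatch(
      stability_flags(getcol(pk, "cl_hepa_human")[i], getcol(pk, "cl_micro")[i]),
      error = function(e) c(stable = NA, enhanced = NA, microsomal_stable = NA))
    bar <- bioavailability_and_risk(descriptors$logd74[i], descriptors$mw[i],
                                    getcol(pk, "f_oral")[i],
                                    getcol(pk, "fdamdd")[i])
    data.frame(
      compound_id = ids[i],
      perm_caco2 = if (is.null(perm_c)) NA_character_ else perm_c$class,
      perm_mdck = if (is.null(perm_m)) NA_character_ else perm_m$class,
      hia = if (is.null(perm_c)) NA_real_ else perm_c$hia,
      stable = stab[["stable"]], enhanced = stab[["enhanced"]],
      microsomal_stable = stab[["microsomal_stable"]],
      oral_risk = bar[["oral_risk"]], high_f = bar[["high_f"]],
      fdamdd_exceeded = bar[["fdamdd_exceeded"]]
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "rules") <- c(
    perm_caco2 = "papp>20e-6 high / <1e-6 low (Caco-2)",
    perm_mdck = "papp>20e-6 high / <1e-6 low (MDCK)",
    hia = "HIA ~0.96 when high permeability",
    stable = "Cl_Hepa < 100 uL/min/1e6 cells",
    enhanced = "Cl_Hepa < 20 uL/min/1e6 cells",
    microsomal_stable = "Cl_Micro < 8.0 uL/min/mg",
    oral_risk = "logD7.4 > 2.8 & MW > 450",
    high_f = "%F >= 0.9",
    fdamdd_exceeded = "FDAMDD dose bound < 0.011 mmol/kg-bw/day")
  out
}
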