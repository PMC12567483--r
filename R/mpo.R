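#' Multiparameter-optimization (MPO) configuration
#'
#' Defines, for each of the six physicochemical attributes
#' (logP, logD at pH 7.4, MW, TPSA, HBD, basic pKa), the desirability
#' ramp and weight. Five attributes use a monotone-decreasing ramp: full
#' desirability (T = 1) at or below `threshold`, zero at or beyond `zero`,
#' linear in between. TPSA uses a hump with four ascending breakpoints
#' `(z_lo, t_lo, t_hi, z_hi)`: zero outside `[z_lo, z_hi]`, one inside
#' `[t_lo, t_hi]`, linear ramps between.
#'
#' The default full-desirability thresholds are logP <= 3, logD7.4 <= 2,
#' MW <= 360 g/mol, TPSA 40-90 A^2, HBD <= 1, pKa <= 8, scored out of 6
#' with unit weights. `calibrated = TRUE` selects the calibrated
#' zero-desirability limits (logP zero limit 6, MW zero limit 455) under
#' which the reference descriptor table reproduces the published scores
#' 5.5 / 5.3 / 4.4 at one decimal; see the methods vignette.
#'
#' @param calibrated Use the calibrated zero limits (default `FALSE`).
#' @param weights Named numeric vector of per-attribute weights
#'   (default all 1).
#' @param limits Optional named list overriding per-attribute breakpoints:
#'   monotone attributes take `c(threshold, zero)`, `tpsa` takes the four
#'   hump breakpoints.
#' @return A `gt_mpo_config`.
#' @export
mpo_config <- function(calibrated = FALSE, weights = NULL, limits = NULL) {
  attrs <- c("logp", "logd74", "mw", "tpsa", "hbd", "pka_basic")
  lim <- list(
    logp = c(threshold = 3, zero = if (calibrated) 6 else 5),
    logd74 = c(threshold = 2, zero = 4),
    mw = c(threshold = 360, zero = if (calibrated) 455 else 500),
    tpsa = c(z_lo = 20, t_lo = 40, t_hi = 90, z_hi = 120),
    hbd = c(threshold = 1, zero = 3.5),
    pka_basic = c(threshold = 8, zero = 10)
  )
  if (!is.null(limits)) {
    bad <- setdiff(names(limits), attrs)
    if (length(bad)) stop("mpo_config: unknown attribute(s): ",
                          paste(bad, collapse = ", "))
    for (nm in names(limits)) {
      v <- as.numeric(limits[[nm]])
      need <- if (nm == "tpsa") 4L else 2L
      if (length(v) != need || is.unsorted(v, strictly = TRUE))
        stop(sprintf("mpo_config: '%s' needs %d strictly ascending breakpoints",
                     nm, need))
      names(v) <- names(lim[[nm]])
      lim[[nm]] <- v
    }
  }
  w <- stats::setNames(rep(1, 6), attrs)
  if (!is.null(weights)) {
    if (any(weights <= 0)) stop("mpo_config: weights must be positive")
    w[names(weights)] <- weights
  }
  structure(list(attributes = attrs, limits = lim, weights = w,
                 calibrated = isTRUE(calibrated)),
            class = "gt_mpo_config")
}

#' Per-attribute desirability T(x)
#'
#' Piecewise-linear desirability in `[0, 1]`: 1 at or inside the
#' full-desirability threshold, 0 at or beyond the zero limit, linear
#' between; the TPSA hump ramps up then down.
#'
#' @param attribute One of `"logp"`, `"logd74"`, `"mw"`, `"tpsa"`,
#'   `"hbd"`, `"pka_basic"`.
#' @param value Finite numeric vector of attribute values.
#' @param cfg A [mpo_config()].
#' @return Numeric vector of desirabilities in `[0, 1]`.
#' @examples
#' desirability("logp", 2.0)   # 1
#' desirability("tpsa", 65)    # 1
#' @export
desirability <- function(attribute, value, cfg = mpo_config()) {
  stopifnot(inherits(cfg, "gt_mpo_config"))
  if (!attribute %in% cfg$attributes)
    stop(sprintf("desirability: unknown attribute '%s'", attribute))
  if (!all(is.finite(value)))
    stop("desirability: value must be finite")
  lm <- cfg$limits[[attribute]]
  if (attribute == "tpsa") {
    up <- (value - lm["z_lo"]) / (lm["t_lo"] - lm["z_lo"])
    down <- (lm["z_hi"] - value) / (lm["z_hi"] - lm["t_hi"])
    unname(pmax(0, pmin(1, pmin(up, down))))
  } else {
    unname(pmax(0, pmin(1, (lm["zero"] - value) / (lm["zero"] - lm["threshold"]))))
  }
}

#' Six-attribute MPO desirability score
#'
#' Computes `D = sum_k w_k T_k(x_k)` over the six attributes. With unit
#' weights D ranges from 0 to 6; any attribute with `T_k < 1` is reported
#' as a violation.
#'
#' @param descr A `gt_descriptor_set` (or anything coercible via
#'   [descriptor_set()]) carrying all six attributes.
#' @param cfg A [mpo_config()].
#' @return A `gt_mpo_result`: list with `compound_id`, `values`,
#'   `desirability` (per-attribute T), `weights`, `score`, `violations`.
#' @export
mpo_score <- function(descr, cfg = mpo_config()) {
  if (!inherits(descr, "gt_descriptor_set")) descr <- descriptor_set(descr)
  stopifnot(inherits(cfg, "gt_mpo_config"))
  vals <- c(logp = descr$logp, logd74 = descr$logd74, mw = descr$mw,
            tpsa = descr$tpsa, hbd = as.numeric(descr$hbd),
            pka_basic = descr$pka_basic)
  missing <- names(vals)[!is.finite(vals)]
  if (length(missing) > 0L)
    stop("mpo_score: missing attribute(s) for '", descr$compound_id, "': ",
         paste(missing, collapse = ", "))
  T_k <- vapply(cfg$attributes, function(a) desirability(a, vals[[a]], cfg),
                numeric(1))
  score <- sum(cfg$weights * T_k)
  structure(list(
    compound_id = descr$compound_id,
    values = vals,
    desirability = T_k,
    weights = cfg$weights,
    score = score,
    violations = cfg$attributes[T_k < 1]
  ), class = "gt_mpo_result")
}

#' @export
print.gt_mpo_result <- function(x, ...) {
  cat(sprintf("<gt_mpo_result> %s: D = %.1f (unrounded %.4f)\n",
              x$compound_id, round(x$score, 1), x$score))
  if (length(x$violations))
    cat("  violations:", paste(x$violations, collapse = ", "), "\n")
  invisible(x)
}

#' Score a whole descriptor table
#'
#' @param descriptors Data frame in the descriptor-table dialect
#'   (`compound_id, mw, tpsa, hbd, logp, logd74, pka_basic[, dg_hyd]`).
#' @param cfg A [mpo_config()].
#' @return Data frame with `compound_id`, the rounded reporting score `D`
#'   (one decimal), the unrounded `D_raw`, per-attribute `T_*` columns and
#'   a semicolon-joined `violations` column. Attached attribute
#'   `"results"` carries the full `gt_mpo_result` list.
#' @export
mpo_table <- function(descriptors, cfg = mpo_config()) {
  res <- lapply(seq_len(nrow(descriptors)),
                function(i) mpo_score(descriptors[i, ], cfg))
  out <- data.frame(
    compound_id = vapply(res, `[[`, "", "compound_id"),
    D = vapply(res, function(r) round(r$score, 1), numeric(1)),
    D_raw = vapply(res, `[[`, numeric(1), "score")
  )
  for (a in cfg$attributes)
    out[[paste0("T_", a)]] <- vapply(res, function(r) r$desirability[[a]],
                                     numeric(1))
  out$violations <- vapply(res, function(r)
    paste(r$violations, collapse = ";"), "")
  attr(out, "results") <- res
  out
}

#' Radar-plot coordinates for an MPO result
#'
#' Six vertices in the fixed attribute order
#' (logP, logD7.4, MW, TPSA, HBD, pKa), each at radius equal to the
#' attribute value normalized to its zero-limit/threshold span and clamped
#' to `[0, 1]` (i.e. the desirability), starting at angle pi/2 and
#' proceeding clockwise.
#'
#' @param result A `gt_mpo_result`.
#' @return Data frame `attribute, radius, angle, x, y`.
#' @export
radar_coordinates <- function(result) {
  stopifnot(inherits(result, "gt_mpo_result"))
  n <- length(result$desirability)
  angle <- pi / 2 - 2 * pi * (seq_len(n) - 1L) / n
  r <- unname(result$desirability)
  data.frame(attribute = names(result$desirability), radius = r,
             angle = angle, x = r * cos(angle), y = r * sin(angle))
}
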