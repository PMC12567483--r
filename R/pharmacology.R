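#' Per-group summary (mean, SEM, n) of a measurement column
#'
#' @param data Data frame.
#' @param value Name of the numeric column to summarize.
#' @param group Name of the grouping column (default `"group"`).
#' @return Data frame `group, mean, sem, n`.
#' @export
group_summary <- function(data, value, group = "group") {
  sp <- split(data[[value]], data[[group]])
  data.frame(
    group = names(sp),
    mean = vapply(sp, mean, numeric(1)),
    sem = vapply(sp, function(x) stats::sd(x) / sqrt(length(x)), numeric(1)),
    n = vapply(sp, length, integer(1)),
    row.names = NULL
  )
}

#' Percent reduction in group-mean glycemia at a timepoint
#'
#' `100 * (mean_control - mean_treated) / mean_control` on the raw group
#' means at the requested time; negative when the treated group exceeds
#' the control.
#'
#' @param data GTT table `animal, group, time_min, glycemia_mg_dl`.
#' @param treated,control Group labels.
#' @param time Timepoint (min) present in both groups.
#' @return Percent reduction (numeric scalar).
#' @export
percent_reduction <- function(data, treated, control, time) {
  sel <- function(g) data$glycemia_mg_dl[data$group == g & data$time_min == time]
  x_t <- sel(treated); x_c <- sel(control)
  if (length(x_t) == 0L || length(x_c) == 0L)
    stop(sprintf("percent_reduction: no records at t = %s min for '%s'",
                 format(time), if (length(x_t) == 0L) treated else control))
  100 * (mean(x_c) - mean(x_t)) / mean(x_c)
}

#' Trapezoidal area under a glycemia-time curve
#'
#' Integrates glycemia over `window` by the trapezoid rule, linearly
#' interpolating the window endpoints when unsampled. With
#' `baseline_corrected = TRUE` the time-zero glycemia is subtracted from
#' every point first and negative excursions contribute negatively
#' (the Delta-AUC convention).
#'
#' @param times Strictly increasing sampling times (min).
#' @param glycemia Glycemia values (mg/dL), same length.
#' @param baseline_corrected Subtract the time-0 value first
#'   (default `TRUE`).
#' @param window Integration window `c(t_start, t_end)` in min
#'   (default `c(0, 120)`).
#' @return AUC in mg.min/dL.
#' @examples
#' gtt_auc(c(0, 60, 120), c(100, 200, 100))  # 6000
#' @export
gtt_auc <- function(times, glycemia, baseline_corrected = TRUE,
                    window = c(0, 120)) {
  stopifnot(length(times) == length(glycemia), length(times) >= 2L)
  if (is.unsorted(times, strictly = TRUE))
    stop("gtt_auc: times must be strictly increasing")
  if (window[1] < times[1] || window[2] > times[length(times)])
    stop("gtt_auc: window extends beyond the sampled range")
  y <- glycemia
  if (baseline_corrected) {
    if (times[1] > window[1]) stop("gtt_auc: no baseline (time-0) record")
    y <- y - glycemia[times == min(times)][1]
  }
  tt <- sort(unique(c(times, window)))
  tt <- tt[tt >= window[1] & tt <= window[2]]
  yy <- stats::approx(times, y, xout = tt)$y
  sum(diff(tt) * (yy[-length(yy)] + yy[-1]) / 2)
}

#' Glucose disappearance constant (Kitt) from an insulin tolerance test
#'
#' Ordinary least squares of `ln(glycemia)` on time gives the decay slope;
#' `t_half = 0.693 / |slope|` and `Kitt = 0.693 * 100 / t_half` (%/min),
#' so Kitt equals `100 |slope|` under the consistent 0.693 convention.
#' A non-negative slope (no measurable glucose disappearance) flags the
#' result invalid rather than returning a negative constant. With
#' `per_animal = TRUE` (default) the regression is run per animal and the
#' group value is the mean of valid animal Kitts; otherwise one pooled
#' regression per group is used.
#'
#' @param data ITT table `animal, group, time_min, glycemia_mg_dl`
#'   (>= 3 timepoints per animal, positive glycemia).
#' @param per_animal Per-animal regressions averaged per group (default)
#'   or one pooled regression per group.
#' @return A `gt_kitt_result`: data.frame `group, kitt, t_half, slope,
#'   r_squared, n, valid`; per-animal fits (when applicable) in attribute
#'   `"animals"`.
#' @export
kitt <- function(data, per_animal = TRUE) {
  stopifnot(all(c("animal", "group", "time_min", "glycemia_mg_dl") %in%
                  names(data)))
  if (any(data$glycemia_mg_dl <= 0))
    stop("kitt: glycemia must be positive")
  fit_one <- function(df) {
    if (length(unique(df$time_min)) < 3L)
      stop("kitt: need >= 3 timepoints")
    m <- stats::lm(log(glycemia_mg_dl) ~ time_min, data = df)
    slope <- unname(stats::coef(m)[2])
    r2 <- suppressWarnings(summary(m)$r.squared)  # exact fits warn in summary.lm
    if (!is.finite(slope) || slope >= 0)
      return(data.frame(slope = slope, t_half = NA_real_, kitt = NA_real_,
                        r_squared = r2, valid = FALSE))
    t_half <- 0.693 / abs(slope)
    data.frame(slope = slope, t_half = t_half, kitt = 0.693 * 100 / t_half,
               r_squared = r2, valid = TRUE)
  }
  groups <- split(data, data$group)
  if (per_animal) {
    animals <- do.call(rbind, lapply(names(groups), function(g) {
      per <- lapply(split(groups[[g]], groups[[g]]$animal), fit_one)
      cbind(group = g, animal = names(per), do.call(rbind, per))
    }))
    rownames(animals) <- NULL
    res <- do.call(rbind, lapply(split(animals, animals$group), function(a) {
      ok <- a$valid
      data.frame(group = a$group[1],
                 kitt = if (any(ok)) mean(a$kitt[ok]) else NA_real_,
                 t_half = if (any(ok)) mean(a$t_half[ok]) else NA_real_,
                 slope = mean(a$slope),
                 r_squared = mean(a$r_squared),
                 n = nrow(a), valid = any(ok))
    }))
    rownames(res) <- NULL
    attr(res, "animals") <- animals
  } else {
    res <- do.call(rbind, lapply(names(groups), function(g) {
      f <- fit_one(groups[[g]])
      data.frame(group = g, kitt = f$kitt, t_half = f$t_half,
                 slope = f$slope, r_squared = f$r_squared,
                 n = length(unique(groups[[g]]$animal)), valid = f$valid)
    }))
  }
  class(res) <- c("gt_kitt_result", class(res))
  res
}

#' Fold change of a treated group over a control mean
#'
#' @param treated Numeric vector of treated-group measurements (non-empty).
#' @param control Numeric vector of control measurements, or a
#'   pre-computed control mean (length 1).
#' @return `mean(treated) / mean(control)`.
#' @export
fold_change <- function(treated, control) {
  if (length(treated) == 0L) stop("fold_change: empty treated set")
  cm <- mean(control)
  if (!is.finite(cm) || cm <= 0)
    stop("fold_change: control mean must be positive")
  mean(treated) / cm
}

#' Relative qPCR quantification (2^-ddCt)
#'
#' `dCt = Ct_target - Ct_ref` per sample; `ddCt = dCt - mean(dCt)` of the
#' control group; fold = `2^-ddCt`. Shifting every Ct by a constant leaves
#' all folds unchanged (reference-gene normalization).
#'
#' @param records Data frame `sample, group, ct_target, ct_ref`
#'   (Ct values in (0, 45)).
#' @param control Control group label.
#' @return Data frame `sample, group, dct, ddct, fold`; per-group mean
#'   folds in attribute `"groups"`.
#' @export
ddct <- function(records, control) {
  stopifnot(all(c("sample", "group", "ct_target", "ct_ref") %in%
                  names(records)))
  ct <- c(records$ct_target, records$ct_ref)
  if (any(!is.finite(ct)) || any(ct <= 0 | ct >= 45))
    stop("ddct: Ct values must lie in (0, 45)")
  if (!any(records$group == control))
    stop(sprintf("ddct: empty control group '%s'", control))
  dct <- records$ct_target - records$ct_ref
  ddct_v <- dct - mean(dct[records$group == control])
  out <- data.frame(sample = records$sample, group = records$group,
                    dct = dct, ddct = ddct_v, fold = 2^(-ddct_v))
  attr(out, "groups") <- group_summary(out, "fold")
  out
}

#' MTT viability relative to a control condition
#'
#' `100 * mean(absorbance_condition) / mean(absorbance_control)` per
#' condition; the complementary reduction is `100 - viability`.
#'
#' @param records Data frame `well, condition, abs570` (absorbance >= 0).
#' @param control Control condition label.
#' @return Data frame `condition, viability_pct, reduction_pct, n`.
#' @export
viability <- function(records, control) {
  stopifnot(all(c("condition", "abs570") %in% names(records)))
  if (any(records$abs570 < 0)) stop("viability: absorbance must be >= 0")
  cm <- mean(records$abs570[records$condition == control])
  if (!is.finite(cm) || cm <= 0)
    stop("viability: control mean absorbance must be positive")
  sp <- split(records$abs570, records$condition)
  out <- data.frame(
    condition = names(sp),
    viability_pct = vapply(sp, function(x) 100 * mean(x) / cm, numeric(1)),
    n = vapply(sp, length, integer(1)),
    row.names = NULL
  )
  out$reduction_pct <- 100 - out$viability_pct
  out[, c("condition", "viability_pct", "reduction_pct", "n")]
}
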