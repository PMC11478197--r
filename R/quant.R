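# Quantification: calibration, external-standard method (ESM), single-marker
# QAMS via relative correction factors (RCFs), relative-retention-time peak
# localization, durability analysis, method-validation statistics.

#' Construct a calibration curve
#'
#' @param analyte label.
#' @param slope area per ug/mL (> 0).
#' @param intercept area units.
#' @param r_squared in `[0, 1]`.
#' @param range c(c_min, c_max) validated concentration range, ug/mL.
#' @return object of class `calibration_curve`.
#' @export
calibration_curve <- function(analyte, slope, intercept, r_squared = NA,
                              range = c(NA, NA)) {
  if (!is.finite(slope) || slope <= 0) stop("slope must be > 0")
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop("r_squared must be in [0, 1]")
  if (all(is.finite(range)) && range[1] >= range[2])
    stop("range must satisfy c_min < c_max")
  structure(list(analyte = analyte, slope = slope, intercept = intercept,
                 r_squared = r_squared, range = range),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: y = %.4gx %+.4g (R2 = %s)\n",
              x$analyte, x$slope, x$intercept, format(x$r_squared)))
  invisible(x)
}

#' Calibration curve of a published reference analyte
#' @param analyte name as in [amb_reference_curves()].
#' @return a [calibration_curve()].
#' @export
reference_curve <- function(analyte) {
  rc <- amb_reference_curves()
  i <- match(analyte, rc$analyte)
  if (is.na(i)) stop("unknown reference analyte: ", analyte)
  calibration_curve(analyte, rc$slope[i], rc$intercept[i],
                    rc$r_squared[i], c(rc$c_min[i], rc$c_max[i]))
}

#' Fit a calibration line by ordinary least squares
#'
#' Regresses peak area on concentration; R-squared is the squared Pearson
#' correlation and the validated range is the span of the input
#' concentrations.
#'
#' @param points data.frame with columns `concentration` and `area` (>= 2
#'   distinct concentrations).
#' @param analyte label stored on the curve.
#' @return a [calibration_curve()].
#' @export
fit_calibration <- function(points, analyte = "analyte") {
  if (!all(c("concentration", "area") %in% names(points)))
    stop("points must have columns concentration, area")
  x <- points$concentration; y <- points$area
  if (length(unique(x)) < 2)
    stop("degenerate calibration design: all concentrations equal")
  fit <- stats::lm.fit(cbind(1, x), y)
  r2 <- if (stats::sd(y) == 0) 1 else stats::cor(x, y)^2
  calibration_curve(analyte, unname(fit$coefficients[2]),
                    unname(fit$coefficients[1]), r2, range(x))
}

#' External-standard quantification
#'
#' Inverts the calibration line to a concentration and converts to content:
#' `c = (area - intercept) / slope`; `content = c * volume / mass`. With the
#' default 2.00 g sample mass and 2 mL extract volume, content (ug/g) equals
#' concentration (ug/mL) numerically.
#'
#' @param area peak area (counts x min).
#' @param curve a `calibration_curve`.
#' @param sample_mass g (default 2.00).
#' @param extract_volume mL (default 2).
#' @return content in ug/g, with attribute `extrapolated` set to TRUE when
#'   the back-calculated concentration falls outside the curve's validated
#'   range. Negative back-calculated concentrations are clipped to 0 with a
#'   warning.
#' @export
esm_quantify <- function(area, curve, sample_mass = 2.00,
                         extract_volume = 2) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (sample_mass <= 0 || extract_volume <= 0)
    stop("sample_mass and extract_volume must be > 0")
  conc <- (area - curve$intercept) / curve$slope
  if (conc < 0) {
    warning("area below the calibration intercept; clipping content to 0")
    conc <- 0
  }
  content <- conc * extract_volume / sample_mass
  extrap <- all(is.finite(curve$range)) &&
    (conc < curve$range[1] || conc > curve$range[2])
  attr(content, "extrapolated") <- extrap
  content
}

#' Relative correction factor of an analyte versus the internal reference
#'
#' The RCF is the response ratio of internal reference s to analyte i,
#' `RCF = (A_s / C_s) / (A_i / C_i) = (A_s * C_i) / (A_i * C_s)`, computed
#' per concentration level (levels paired by index in the dilution series)
#' and summarized by its mean and RSD. Optional per-level retention times
#' give the relative retention time `Rt = t_i / t_s` and its RSD.
#'
#' @param ref_points data.frame `concentration`, `area` for the internal
#'   reference (>= 3 levels).
#' @param analyte_points data.frame of the same shape for the analyte; the
#'   level counts must match.
#' @param analyte,internal_ref labels.
#' @param ref_rt,analyte_rt optional per-level retention times, minutes.
#' @return object of class `rcf_record`: `per_level_rcf`, `mean_rcf`,
#'   `rcf_rsd` (%), `mean_rrt`, `rrt_rsd` (%; NA without retention input).
#' @export
compute_rcf <- function(ref_points, analyte_points, analyte = "analyte",
                        internal_ref = "reference", ref_rt = NULL,
                        analyte_rt = NULL) {
  if (nrow(ref_points) != nrow(analyte_points))
    stop("mismatched level counts between reference and analyte")
  if (nrow(ref_points) < 3) stop("at least 3 levels required")
  cs <- ref_points$concentration; as_ <- ref_points$area
  ci <- analyte_points$concentration; ai <- analyte_points$area
  if (any(c(cs, as_, ci, ai) <= 0))
    stop("areas and concentrations must all be positive")
  r <- (as_ * ci) / (ai * cs)
  rrt <- rrt_rsd <- NA_real_
  if (!is.null(ref_rt) && !is.null(analyte_rt)) {
    rt <- analyte_rt / ref_rt
    rrt <- mean(rt)
    rrt_rsd <- stats::sd(rt) / rrt * 100
  }
  structure(list(analyte = analyte, internal_ref = internal_ref,
                 per_level_rcf = r, mean_rcf = mean(r),
                 rcf_rsd = stats::sd(r) / mean(r) * 100,
                 mean_rrt = rrt, rrt_rsd = rrt_rsd),
            class = "rcf_record")
}

#' @export
print.rcf_record <- function(x, ...) {
  cat(sprintf("<rcf_record> %s vs %s: RCF %.4g (RSD %.2f%%)\n",
              x$analyte, x$internal_ref, x$mean_rcf, x$rcf_rsd))
  invisible(x)
}

#' Locate an analyte peak by relative retention time
#'
#' Picks the peak whose relative retention time `Rt = apex / t_s` is closest
#' to `expected_rrt`, provided the relative deviation does not exceed
#' `tolerance` (default 0.5%).
#'
#' @param peaks `peak_list` of candidate peaks.
#' @param internal_ref_peak the internal reference peak (a one-row
#'   `peak_list` subset) or its apex time in minutes.
#' @param expected_rrt expected relative retention time (> 0).
#' @param tolerance maximal relative deviation (fraction, > 0).
#' @return the selected peak row, with attribute `rrt` (achieved Rt).
#' @export
locate_peak_by_rrt <- function(peaks, internal_ref_peak, expected_rrt,
                               tolerance = 0.005) {
  if (tolerance <= 0) stop("tolerance must be > 0")
  t_s <- if (is.numeric(internal_ref_peak)) internal_ref_peak
    else internal_ref_peak$apex_time[1]
  if (!nrow(peaks)) stop("no candidate peaks")
  rrt <- peaks$apex_time / t_s
  dev <- abs(rrt - expected_rrt) / expected_rrt
  i <- which.min(dev)
  if (dev[i] > tolerance)
    stop(sprintf(
      "peak not located: nearest candidate has Rt %.4f (expected %.4f, tolerance %.2f%%)",
      rrt[i], expected_rrt, tolerance * 100))
  out <- peaks[i, , drop = FALSE]
  attr(out, "rrt") <- rrt[i]
  out
}

#' Single-marker (QAMS) quantification
#'
#' Computes the analyte concentration from the internal reference's signal:
#' `C_i = rcf * A_i * C_s / A_s` (the inverse of the RCF definition), then
#' converts to content as in [esm_quantify()].
#'
#' @param area_i analyte peak area (> 0).
#' @param area_s internal reference peak area (> 0; 0 means the reference
#'   peak is missing and is an error).
#' @param conc_s internal reference concentration in the extract, ug/mL.
#' @param rcf relative correction factor (scalar or `rcf_record`).
#' @param sample_mass,extract_volume as in [esm_quantify()].
#' @return content in ug/g.
#' @export
qams_quantify <- function(area_i, area_s, conc_s, rcf, sample_mass = 2.00,
                          extract_volume = 2) {
  if (inherits(rcf, "rcf_record")) rcf <- rcf$mean_rcf
  if (area_s <= 0) stop("internal reference peak missing (A_s <= 0)")
  if (any(c(area_i, conc_s, rcf, sample_mass, extract_volume) <= 0))
    stop("all QAMS inputs must be positive")
  conc_i <- rcf * area_i * conc_s / area_s
  conc_i * extract_volume / sample_mass
}

# round half away from zero (table formatting convention)
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Relative deviation between QAMS and ESM contents
#'
#' `RD = (qams - esm) / esm * 100`, rounded half-away-from-zero to 2
#' decimals (table formatting convention).
#'
#' @param esm external-standard content (> 0).
#' @param qams single-marker content.
#' @return RD in percent, 2 decimals.
#' @export
relative_deviation <- function(esm, qams) {
  if (any(esm <= 0)) stop("esm content must be > 0")
  round_half_up((qams - esm) / esm * 100, 2)
}

#' Default durability perturbation factors
#'
#' Four instrument factors at three levels each (chromatographic column,
#' flow rate, column temperature, injection volume), each level carrying a
#' multiplicative detector-response scale applied equally to every analyte
#' (instrument-level effects shift absolute response, not response ratios).
#'
#' @return named list of named numeric vectors (area scale per level).
#' @export
default_durability_factors <- function() {
  list(
    column = c(Hypersil_ODS = 0.97, Agilent_TC_C18 = 1.00,
               COSMOSIL_5C18 = 1.03),
    flow_rate = c(`0.6` = 1.30, `0.8` = 1.00, `1.0` = 0.82),
    temperature = c(`25` = 0.99, `30` = 1.00, `35` = 1.01),
    injection_volume = c(`10` = 0.50, `15` = 0.75, `20` = 1.00)
  )
}

#' Durability analysis of the relative correction factors
#'
#' For each perturbation factor and level, simulates calibration series for
#' the internal reference and each analyte under the condition's response
#' scale with multiplicative area noise, recomputes the RCF, and reports the
#' RSD of the RCF across the factor's levels. Verdict per factor and
#' analyte: RSD below `bound` (default 2.0%).
#'
#' @param internal_ref a [constituent_spec()] for the internal reference.
#' @param analytes list of `constituent_spec`s to be measured.
#' @param factors named list of perturbation levels (named numeric area
#'   scales); factors with < 2 levels are skipped with a warning. Default
#'   [default_durability_factors()].
#' @param n_levels calibration levels per series (default 5).
#' @param area_noise_cv multiplicative area noise CV (default 0.01).
#' @param conc_range_frac fraction of each constituent's nominal range used
#'   for the level grid (levels span `base_concentration * c(0.5, 1.5)`).
#' @param seed integer seed.
#' @param bound RSD acceptance bound in percent (default 2.0).
#' @return object of class `durability_result`: `conditions` (data.frame
#'   factor, level, analyte, rcf), `summary` (factor x analyte RSDs with
#'   verdicts), `bound`.
#' @export
durability_study <- function(internal_ref, analytes,
                             factors = default_durability_factors(),
                             n_levels = 5, area_noise_cv = 0.01,
                             conc_range_frac = c(0.5, 1.5), seed = 1,
                             bound = 2.0) {
  stopifnot(inherits(internal_ref, "constituent_spec"))
  if (inherits(analytes, "constituent_spec")) analytes <- list(analytes)
  keep <- vapply(factors, length, integer(1)) >= 2
  if (any(!keep)) {
    warning("skipping factor(s) with < 2 conditions: ",
            paste(names(factors)[!keep], collapse = ", "))
    factors <- factors[keep]
  }
  if (!length(factors)) stop("no usable durability factors")
  levels_of <- function(spec) seq(conc_range_frac[1], conc_range_frac[2],
                                  length.out = n_levels) *
    spec$base_concentration
  cond <- NULL
  with_seed(seed, {
    for (f in names(factors)) {
      for (l in names(factors[[f]])) {
        scale <- factors[[f]][[l]]
        ref_ser <- simulate_calibration_series(
          internal_ref, levels_of(internal_ref), area_noise_cv)
        ref_ser$area <- ref_ser$area * scale
        for (an in analytes) {
          ser <- simulate_calibration_series(an, levels_of(an),
                                             area_noise_cv)
          ser$area <- ser$area * scale
          rec <- compute_rcf(ref_ser, ser, analyte = an$id,
                             internal_ref = internal_ref$id)
          cond <- rbind(cond, data.frame(
            factor = f, level = l, analyte = an$id,
            rcf = rec$mean_rcf))
        }
      }
    }
    smry <- do.call(rbind, lapply(split(
      cond, list(cond$factor, cond$analyte), drop = TRUE), function(d)
        data.frame(factor = d$factor[1], analyte = d$analyte[1],
                   mean_rcf = mean(d$rcf),
                   rsd = stats::sd(d$rcf) / mean(d$rcf) * 100)))
    smry$pass <- smry$rsd < bound
    rownames(smry) <- NULL
    structure(list(conditions = cond, summary = smry, bound = bound),
              class = "durability_result")
  })
}

#' Relative standard deviation of replicates
#' @param x numeric replicates (>= 2 values; mean must be non-zero).
#' @return RSD in percent (sample sd, n - 1 denominator).
#' @export
rsd <- function(x) {
  if (length(x) < 2) stop("at least 2 replicates required")
  m <- mean(x)
  if (m == 0) stop("RSD undefined for zero mean")
  stats::sd(x) / m * 100
}

#' Spike recovery
#' @param measured_total content measured in the spiked sample.
#' @param base content of the unspiked sample (> 0).
#' @param spiked amount spiked (> 0), same units.
#' @return recovery in percent.
#' @export
recovery <- function(measured_total, base, spiked) {
  if (base <= 0 || spiked <= 0) stop("base and spiked must be > 0")
  (measured_total - base) / spiked * 100
}

#' Method-validation statistics for a replicate set
#'
#' @param replicates numeric vector of replicate areas or contents.
#' @param base,spiked,measured_total optional recovery inputs (see
#'   [recovery()]).
#' @return list with `rsd` (%) and, when recovery inputs are given,
#'   `recovery` (%).
#' @export
validation_metrics <- function(replicates, base = NULL, spiked = NULL,
                               measured_total = NULL) {
  out <- list(rsd = rsd(replicates))
  if (!is.null(base) && !is.null(spiked) && !is.null(measured_total))
    out$recovery <- recovery(measured_total, base, spiked)
  out
}
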