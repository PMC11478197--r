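#' Define a chemical constituent of the simulated material
#'
#' A constituent is a single chromatographic species: where it elutes, how
#' wide its peak is, and its (linear) ELSD response `area = slope * C +
#' intercept`, floored at zero. The six identified constituents default to
#' the published regression lines of [amb_reference_curves()]; unnamed
#' constituents take configurable values.
#'
#' @param id character label.
#' @param retention_time apex retention time, minutes (> 0).
#' @param peak_sigma Gaussian peak width (sd), minutes (> 0).
#' @param response_slope area units per ug/mL (> 0).
#' @param response_intercept area units.
#' @param base_concentration nominal concentration in a standard batch,
#'   ug/mL (>= 0).
#' @return object of class `constituent_spec`.
#' @export
constituent_spec <- function(id, retention_time, peak_sigma = 0.08,
                             response_slope = 1000,
                             response_intercept = 0,
                             base_concentration = 50) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!is.finite(retention_time) || retention_time <= 0)
    stop("retention_time must be > 0")
  if (!is.finite(peak_sigma) || peak_sigma <= 0)
    stop("peak_sigma must be > 0")
  if (!is.finite(response_slope) || response_slope <= 0)
    stop("response_slope must be > 0")
  if (!is.finite(base_concentration) || base_concentration < 0)
    stop("base_concentration must be >= 0")
  structure(list(id = id, retention_time = retention_time,
                 peak_sigma = peak_sigma,
                 response_slope = response_slope,
                 response_intercept = response_intercept,
                 base_concentration = base_concentration),
            class = "constituent_spec")
}

#' Ideal (noise-free) peak area of a constituent at a concentration
#' @param spec a `constituent_spec`.
#' @param concentration ug/mL.
#' @return area units, floored at zero.
#' @export
ideal_area <- function(spec, concentration) {
  pmax(spec$response_slope * concentration + spec$response_intercept, 0)
}

#' Default constituent panel
#'
#' Builds the default set of shared constituents for the panel simulator:
#' the six identified analytes (published responses; retention times placed
#' so that the relative retention times of macrostemonosides T and U versus
#' macrostemonoside A are 0.9394 and 1.0098) plus unnamed constituents with
#' deterministic mid-range responses. The elution layout mirrors the
#' reference fingerprint's peak numbering — adenosine and syringin first,
#' the bulk of the unnamed peaks between syringin and macrostemonoside T,
#' three between T and A, and two late peaks after V — so the identified
#' markers bracket nearly the whole run and marker-anchored retention
#' correction is interpolation, not long extrapolation.
#'
#' @param n_shared total number of shared constituents (>= 6, default 30).
#'   Counts below 30 drop late unnamed peaks first; counts above 30 append
#'   extra late peaks at 1.5-min spacing.
#' @return list of `constituent_spec` (length `n_shared`), ordered by
#'   retention time.
#' @export
default_constituents <- function(n_shared = 30) {
  stopifnot(n_shared >= 6)
  curves <- amb_reference_curves()
  t_s <- 45.0  # internal reference (macrostemonoside A) apex, min
  named_rt <- c(adenosine = 6.80, syringin = 12.40,
                macrostemonoside_T = 0.9394 * t_s,
                macrostemonoside_A = t_s,
                macrostemonoside_U = 1.0098 * t_s,
                macrostemonoside_V = 48.20)
  named <- lapply(seq_len(nrow(curves)), function(i) {
    a <- curves$analyte[i]
    constituent_spec(a, retention_time = unname(named_rt[a]),
                     peak_sigma = 0.08,
                     response_slope = curves$slope[i],
                     response_intercept = curves$intercept[i],
                     base_concentration = round(
                       (curves$c_min[i] + curves$c_max[i]) / 2, 2))
  })
  # canonical unnamed layout for the 30-peak fingerprint
  unnamed_rt <- c(seq(14, 41, length.out = 19),  # between syringin and T
                  43.0, 43.7, 44.4,              # between T and A
                  49.6, 51.2)                    # after V
  n_extra <- n_shared - length(named)
  if (n_extra > length(unnamed_rt))
    unnamed_rt <- c(unnamed_rt,
                    51.2 + 1.5 * seq_len(n_extra - length(unnamed_rt)))
  rts <- unnamed_rt[seq_len(n_extra)]
  extras <- lapply(seq_len(max(n_extra, 0)), function(k) {
    constituent_spec(sprintf("unnamed_%02d", k),
                     retention_time = rts[k], peak_sigma = 0.08,
                     response_slope = 800 + 60 * ((7 * k) %% 25),
                     response_intercept = -50 - 5 * (k %% 7),
                     base_concentration = 30 + 2 * ((3 * k) %% 26))
  })
  all <- c(named, extras)
  all[order(vapply(all, `[[`, numeric(1), "retention_time"))]
}
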