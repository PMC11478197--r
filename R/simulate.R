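# Synthetic-data generator: chromatograms, multi-batch panels, calibration
# series. The signal model is a sum of Gaussian (optionally exponentially
# modified Gaussian) peaks whose areas follow each constituent's linear ELSD
# response, on top of a low-order baseline and additive detector noise.

#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded simulations do
#' not perturb the global random stream. `seed = NULL` runs unseeded.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Unit-area peak shape on grid `t`, apex `rt`, width `sigma`.
# EMG uses exponential tail constant `tau` (minutes).
peak_shape <- function(t, rt, sigma, shape = "gaussian", tau = 0.1) {
  if (shape == "gaussian") {
    stats::dnorm(t, mean = rt, sd = sigma)
  } else if (shape == "emg") {
    # exponentially modified Gaussian density (unit area)
    z <- (sigma^2 / tau - (t - rt)) / (sigma * sqrt(2))
    (1 / (2 * tau)) * exp(sigma^2 / (2 * tau^2) - (t - rt) / tau) *
      (2 * stats::pnorm(-z * sqrt(2)))
  } else stop("unknown peak shape: ", shape)
}

#' Simulate a single chromatogram
#'
#' Each constituent contributes a peak of area
#' \eqn{\max(slope \cdot C + intercept, 0)} (its ideal ELSD response,
#' optionally perturbed by multiplicative log-normal noise of coefficient of
#' variation `area_noise_cv`), centred at its retention time plus a
#' batch-level shift and per-peak jitter. A smooth low-order baseline of
#' amplitude `drift_amplitude` and additive Gaussian detector noise complete
#' the trace.
#'
#' @param constituents list of [constituent_spec()] objects.
#' @param concentrations numeric vector, ug/mL, same length as
#'   `constituents`; all >= 0.
#' @param time_range c(start, end) of the acquisition window, minutes.
#' @param dt grid spacing, minutes.
#' @param area_noise_cv multiplicative area noise CV (fraction, >= 0).
#' @param rt_shift systematic retention shift applied to every peak, minutes.
#' @param rt_jitter_sd per-peak retention jitter sd, minutes.
#' @param drift_amplitude baseline drift amplitude, counts.
#' @param detector_noise_sd additive white detector noise sd, counts.
#' @param shape `"gaussian"` (default) or `"emg"` for tailing peaks.
#' @param tau EMG tail constant, minutes (used when `shape = "emg"`).
#' @param seed integer seed for reproducibility, or NULL.
#' @param meta metadata list stored on the chromatogram.
#' @return a [chromatogram()]. Attributes `peak_areas` (realized areas after
#'   noise, in elution order) and `apex_times` (realized apexes) record the
#'   generator ground truth.
#' @export
simulate_chromatogram <- function(constituents, concentrations,
                                  time_range = c(0, 60), dt = 0.02,
                                  area_noise_cv = 0, rt_shift = 0,
                                  rt_jitter_sd = 0, drift_amplitude = 0,
                                  detector_noise_sd = 0,
                                  shape = c("gaussian", "emg"), tau = 0.1,
                                  seed = NULL, meta = list()) {
  shape <- match.arg(shape)
  if (inherits(constituents, "constituent_spec"))
    constituents <- list(constituents)
  n <- length(constituents)
  if (length(concentrations) != n)
    stop("concentrations must match constituents in length")
  if (any(concentrations < 0))
    stop("negative concentration rejected")
  if (area_noise_cv < 0) stop("area_noise_cv must be >= 0")
  rts <- vapply(constituents, `[[`, numeric(1), "retention_time") + rt_shift
  sig <- vapply(constituents, `[[`, numeric(1), "peak_sigma")
  if (any(rts - 4 * sig < time_range[1] | rts + 4 * sig > time_range[2]))
    stop("retention time outside grid: every apex must lie within the ",
         "acquisition window with a 4-sigma margin")
  with_seed(seed, {
    t <- seq(time_range[1], time_range[2], by = dt)
    areas <- vapply(seq_len(n), function(k)
      ideal_area(constituents[[k]], concentrations[k]), numeric(1))
    if (area_noise_cv > 0)
      areas <- areas * exp(stats::rnorm(n, 0, area_noise_cv))
    apex <- rts + if (rt_jitter_sd > 0) stats::rnorm(n, 0, rt_jitter_sd)
      else 0
    y <- numeric(length(t))
    for (k in seq_len(n)) {
      if (areas[k] <= 0) next
      y <- y + areas[k] * peak_shape(t, apex[k], sig[k], shape, tau)
    }
    if (drift_amplitude != 0) {
      span <- diff(time_range)
      y <- y + drift_amplitude *
        (0.5 + 0.5 * sin(2 * pi * (t - time_range[1]) / (1.6 * span)))
    }
    if (detector_noise_sd > 0)
      y <- y + stats::rnorm(length(t), 0, detector_noise_sd)
    ord <- order(apex)
    out <- chromatogram(t, y, meta = meta)
    attr(out, "peak_areas") <- areas[ord]
    attr(out, "apex_times") <- apex[ord]
    attr(out, "constituent_ids") <-
      vapply(constituents, `[[`, character(1), "id")[ord]
    out
  })
}

#' Panel simulation configuration
#'
#' Describes an 18-batch (default) panel in three groups — southern origin,
#' northern directly dried, and northern freeze/post-steaming dried — with
#' multiplicative group effects on designated constituent subsets,
#' multiplicative area noise, retention drift, and batch-specific extra
#' peaks.
#'
#' @param batches data.frame with columns `batch`, `region`
#'   (`northern`/`southern`) and `processing` (`post_steaming_dried` /
#'   `directly_dried` / `freeze_dried`); defaults to [amb_batch_layout()].
#' @param constituents shared constituent list; default
#'   [default_constituents()] (30 peaks).
#' @param origin_effect fold-change applied to `origin_peaks` in southern
#'   batches (default 2.5, sized so unsupervised clustering separates the
#'   groups).
#' @param origin_peaks constituent ids affected by origin; default six
#'   unnamed peaks.
#' @param processing_effect fold-change applied to `processing_peaks` in
#'   northern directly dried batches (default 2.5), so the three effect
#'   cells coincide with the three panel groups.
#' @param processing_peaks constituent ids affected by processing; default
#'   the three macrostemonosides (A, T, U) plus two unnamed peaks.
#' @param area_noise_cv multiplicative area noise CV (default 0.01).
#' @param rt_shift_sd per-batch systematic retention shift sd, minutes
#'   (default 0.02).
#' @param rt_jitter_sd per-peak retention jitter sd, minutes (default
#'   0.005).
#' @param drift_amplitude baseline amplitude, counts (default 0).
#' @param detector_noise_sd additive detector noise sd, counts (default 0).
#' @param extras_per_batch batch-specific extra peaks per batch (default 2).
#' @param time_range,dt acquisition grid.
#' @param seed integer seed (default 1).
#' @return object of class `panel_config`.
#' @export
panel_config <- function(batches = NULL, constituents = NULL,
                         origin_effect = 2.5, origin_peaks = NULL,
                         processing_effect = 2.5, processing_peaks = NULL,
                         area_noise_cv = 0.01, rt_shift_sd = 0.02,
                         rt_jitter_sd = 0.005, drift_amplitude = 0,
                         detector_noise_sd = 0, extras_per_batch = 2,
                         time_range = c(0, 60), dt = 0.02, seed = 1) {
  if (is.null(batches))
    batches <- amb_batch_layout()[, c("batch", "region", "processing")]
  need <- c("batch", "region", "processing")
  if (!all(need %in% names(batches)))
    stop("batches must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(batches$batch))
    stop("duplicate batch ids in group assignment")
  if (!all(batches$region %in% c("northern", "southern")))
    stop("region must be northern or southern")
  ok_proc <- c("post_steaming_dried", "directly_dried", "freeze_dried")
  if (!all(batches$processing %in% ok_proc))
    stop("processing must be one of: ", paste(ok_proc, collapse = ", "))
  if (is.null(constituents)) constituents <- default_constituents(30)
  ids <- vapply(constituents, `[[`, character(1), "id")
  unnamed <- ids[grepl("^unnamed_", ids)]
  if (is.null(origin_peaks)) origin_peaks <- utils::head(unnamed, 6)
  if (is.null(processing_peaks))
    processing_peaks <- c("macrostemonoside_A", "macrostemonoside_T",
                          "macrostemonoside_U",
                          utils::head(setdiff(unnamed, origin_peaks), 2))
  if (!all(origin_peaks %in% ids) || !all(processing_peaks %in% ids))
    stop("effect subsets must name known constituents")
  if (area_noise_cv < 0) stop("area_noise_cv must be >= 0")
  if (origin_effect <= 0 || processing_effect <= 0)
    stop("fold-change effects must be > 0")
  structure(list(batches = batches, constituents = constituents,
                 origin_effect = origin_effect, origin_peaks = origin_peaks,
                 processing_effect = processing_effect,
                 processing_peaks = processing_peaks,
                 area_noise_cv = area_noise_cv, rt_shift_sd = rt_shift_sd,
                 rt_jitter_sd = rt_jitter_sd,
                 drift_amplitude = drift_amplitude,
                 detector_noise_sd = detector_noise_sd,
                 extras_per_batch = extras_per_batch,
                 time_range = time_range, dt = dt, seed = seed),
            class = "panel_config")
}

#' Group label of a batch (three-group structure)
#'
#' Southern batches form one group regardless of processing; northern
#' batches split into directly dried versus freeze/post-steaming dried.
#' @param region,processing character vectors.
#' @return character vector of group labels.
#' @export
panel_group <- function(region, processing) {
  ifelse(region == "southern", "southern",
         ifelse(processing == "directly_dried", "northern_directly_dried",
                "northern_other_dried"))
}

#' Ideal concentration matrix implied by a panel configuration
#'
#' Base concentrations with the configured multiplicative origin and
#' processing effects applied; no noise. Rows are batches, columns shared
#' constituents (elution order).
#' @param config a [panel_config()].
#' @return numeric matrix with dimnames (batch, constituent id).
#' @export
panel_concentrations <- function(config) {
  ids <- vapply(config$constituents, `[[`, character(1), "id")
  base <- vapply(config$constituents, `[[`, numeric(1),
                 "base_concentration")
  b <- config$batches
  conc <- matrix(rep(base, each = nrow(b)), nrow = nrow(b),
                 dimnames = list(b$batch, ids))
  south <- b$region == "southern"
  direct <- b$processing == "directly_dried" & b$region == "northern"
  conc[south, ids %in% config$origin_peaks] <-
    conc[south, ids %in% config$origin_peaks] * config$origin_effect
  conc[direct, ids %in% config$processing_peaks] <-
    conc[direct, ids %in% config$processing_peaks] * config$processing_effect
  conc
}

#' Simulate a multi-batch chromatogram panel
#'
#' Generates one chromatogram per configured batch: shared constituents at
#' group-adjusted concentrations with multiplicative area noise, a per-batch
#' systematic retention shift plus per-peak jitter, and optional
#' batch-specific extra peaks (placed deterministically per batch, away from
#' shared apexes, so they never align across batches).
#'
#' @param config a [panel_config()].
#' @return object of class `chrom_panel`: list with `chromatograms` (named
#'   list of [chromatogram()]), `truth` (list: `concentrations`, `areas` —
#'   realized shared-peak areas —, `apex_times`, `rt_shifts`, `groups`), and
#'   `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  b <- config$batches
  nb <- nrow(b)
  ids <- vapply(config$constituents, `[[`, character(1), "id")
  conc <- panel_concentrations(config)
  groups <- panel_group(b$region, b$processing)
  with_seed(config$seed, {
    shifts <- if (config$rt_shift_sd > 0)
      stats::rnorm(nb, 0, config$rt_shift_sd) else numeric(nb)
    chroms <- vector("list", nb)
    areas <- matrix(NA_real_, nb, length(ids),
                    dimnames = list(b$batch, ids))
    apexes <- matrix(NA_real_, nb, length(ids),
                     dimnames = list(b$batch, ids))
    for (i in seq_len(nb)) {
      specs <- config$constituents
      cc <- conc[i, ]
      if (config$extras_per_batch > 0) {
        shared_rt <- vapply(config$constituents, `[[`, numeric(1),
                            "retention_time")
        for (e in seq_len(config$extras_per_batch)) {
          # deterministic, batch-unique position in 15..70 min
          rt_e <- 15 + ((i * 7.3 + e * 13.7) %% 40)
          while (min(abs(rt_e - shared_rt)) < 0.7) rt_e <- rt_e + 0.9
          specs <- c(specs, list(constituent_spec(
            sprintf("extra_%s_%d", b$batch[i], e), retention_time = rt_e,
            peak_sigma = 0.08, response_slope = 1200,
            response_intercept = -60, base_concentration = 40)))
          cc <- c(cc, 40)
        }
      }
      ch <- simulate_chromatogram(
        specs, cc, time_range = config$time_range, dt = config$dt,
        area_noise_cv = config$area_noise_cv, rt_shift = shifts[i],
        rt_jitter_sd = config$rt_jitter_sd,
        drift_amplitude = config$drift_amplitude,
        detector_noise_sd = config$detector_noise_sd, seed = NULL,
        meta = list(batch = b$batch[i], region = b$region[i],
                    processing = b$processing[i], group = groups[i]))
      keep <- match(ids, attr(ch, "constituent_ids"))
      areas[i, ] <- attr(ch, "peak_areas")[keep]
      apexes[i, ] <- attr(ch, "apex_times")[keep]
      chroms[[i]] <- ch
    }
    names(chroms) <- b$batch
    structure(list(chromatograms = chroms,
                   truth = list(concentrations = conc, areas = areas,
                                apex_times = apexes, rt_shifts = shifts,
                                groups = stats::setNames(groups, b$batch)),
                   config = config),
              class = "chrom_panel")
  })
}

#' Simulate a calibration series for one constituent
#'
#' Draws areas from the constituent's linear response at the requested
#' concentration levels, with multiplicative log-normal noise of CV
#' `replicate_cv`.
#'
#' @param constituent a [constituent_spec()].
#' @param levels numeric vector of concentrations, ug/mL (>= 2 values, all
#'   positive; conventionally 5).
#' @param replicate_cv multiplicative noise CV (fraction).
#' @param seed integer seed or NULL.
#' @return data.frame with columns `concentration`, `area`.
#' @export
simulate_calibration_series <- function(constituent, levels,
                                        replicate_cv = 0, seed = NULL) {
  stopifnot(inherits(constituent, "constituent_spec"))
  if (length(levels) < 2) stop("at least 2 concentration levels required")
  if (any(levels <= 0)) stop("concentration levels must be positive")
  if (replicate_cv < 0) stop("replicate_cv must be >= 0")
  with_seed(seed, {
    area <- ideal_area(constituent, levels)
    if (replicate_cv > 0)
      area <- area * exp(stats::rnorm(length(levels), 0, replicate_cv))
    data.frame(concentration = levels, area = area)
  })
}
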