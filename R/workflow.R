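# Configuration-driven end-to-end pipeline:
# simulate/ingest -> peaks -> fingerprint -> chemometrics -> QAMS,
# with report tables mirroring the similarity / validation / durability /
# content-determination summaries and a machine-readable run manifest.

derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + 7919 * stage) %% 2147483647)
}

#' Pipeline configuration
#'
#' Validated bundle of all stage parameters. A single global `seed` is
#' expanded into per-stage seeds by a fixed counter scheme so stages are
#' independently reproducible.
#'
#' @param mode `"synthetic"` (simulate a panel) or `"files"` (read a
#'   manifest of chromatogram CSVs).
#' @param panel a [panel_config()] (synthetic mode).
#' @param manifest path to a JSON manifest (files mode).
#' @param min_snr,smoothing_window,smoothing_order peak detection settings.
#' @param window common-peak matching half-window, minutes (> 0).
#' @param marker_window half-window for identifying marker peaks, minutes.
#' @param noise_region peak-free interval for noise estimation, minutes.
#' @param scaling chemometric scaling label (see [preprocess()]).
#' @param pca_k PCA components.
#' @param hca_k HCA cluster count (NULL = silhouette-selected).
#' @param linkage HCA linkage (`"ward"` or `"average"`).
#' @param contrast column of the batch metadata used as the OPLS-DA
#'   two-class response (default `"region"`).
#' @param n_orthogonal,n_perm OPLS-DA settings.
#' @param internal_reference internal reference analyte for QAMS.
#' @param qams_analytes analytes quantified by QAMS.
#' @param expected_rrt named expected relative retention times for
#'   localization.
#' @param rrt_tolerance relative Rt tolerance (fraction).
#' @param calibration_cv area noise CV for the simulated calibration series.
#' @param similarity_on `"peaks"` (common-peak vectors, default) or
#'   `"curve"` (full sampled trace).
#' @param write_chromatograms also export per-batch chromatogram CSVs plus a
#'   manifest (synthetic mode).
#' @param seed global integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            panel = panel_config(), manifest = NULL,
                            min_snr = 5, smoothing_window = 11,
                            smoothing_order = 3, window = 0.1,
                            marker_window = 0.3,
                            noise_region = c(56, 60),
                            scaling = "uv", pca_k = 2, hca_k = NULL,
                            linkage = "ward", contrast = "region",
                            n_orthogonal = 1, n_perm = 200,
                            internal_reference = "macrostemonoside_A",
                            qams_analytes = c("macrostemonoside_T",
                                              "macrostemonoside_U"),
                            expected_rrt = c(macrostemonoside_T = 0.9394,
                                             macrostemonoside_U = 1.0098),
                            rrt_tolerance = 0.005, calibration_cv = 0.01,
                            similarity_on = c("peaks", "curve"),
                            write_chromatograms = FALSE, seed = 1) {
  mode <- match.arg(mode)
  similarity_on <- match.arg(similarity_on)
  if (window <= 0) stop("matching window must be > 0")
  if (marker_window <= 0) stop("marker_window must be > 0")
  if (mode == "files" && is.null(manifest))
    stop("files mode requires a manifest path")
  if (mode == "synthetic" && !inherits(panel, "panel_config"))
    stop("synthetic mode requires a panel_config")
  if (!all(names(expected_rrt) == qams_analytes))
    stop("expected_rrt must be named by qams_analytes")
  structure(list(mode = mode, panel = panel, manifest = manifest,
                 min_snr = min_snr, smoothing_window = smoothing_window,
                 smoothing_order = smoothing_order, window = window,
                 marker_window = marker_window,
                 noise_region = noise_region, scaling = scaling,
                 pca_k = pca_k, hca_k = hca_k, linkage = linkage,
                 contrast = contrast, n_orthogonal = n_orthogonal,
                 n_perm = n_perm, internal_reference = internal_reference,
                 qams_analytes = qams_analytes,
                 expected_rrt = expected_rrt,
                 rrt_tolerance = rrt_tolerance,
                 calibration_cv = calibration_cv,
                 similarity_on = similarity_on,
                 write_chromatograms = write_chromatograms, seed = seed),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
}

write_table <- function(df, outdir, name) {
  path <- file.path(outdir, name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full fingerprint / chemometrics / QAMS pipeline
#'
#' Executes every stage on a synthetic panel or a directory of chromatogram
#' CSVs and writes the report tables to `outdir`: batch similarities,
#' calibration/validation metrics with LOD/LOQ, RCFs with durability RSDs,
#' per-batch ESM/QAMS contents with relative deviations, PCA/OPLS-DA scores
#' and VIPs, HCA clusters with a Newick-format dendrogram, and a
#' machine-readable `manifest.json` (configuration, seeds, package version)
#' from which every table is recomputable.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return (invisibly) a list of all report tables and fitted models.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  # -- acquire ------------------------------------------------------------
  acq <- stage("acquire", {
    if (config$mode == "synthetic") {
      panel <- simulate_panel(config$panel)
      meta <- config$panel$batches
      meta$group <- panel_group(meta$region, meta$processing)
      list(chroms = panel$chromatograms, meta = meta, panel = panel)
    } else {
      man <- read_manifest(config$manifest)
      chroms <- lapply(seq_len(nrow(man)), function(i)
        read_chromatogram(
          file.path(dirname(config$manifest), man$file[i]),
          meta = as.list(man[i, setdiff(names(man), "file")])))
      names(chroms) <- man$batch
      meta <- man[, c("batch", "region", "processing")]
      meta$group <- panel_group(meta$region, meta$processing)
      list(chroms = chroms, meta = meta, panel = NULL)
    }
  })
  chroms <- acq$chroms
  meta <- acq$meta
  batches <- meta$batch
  if (config$mode == "synthetic" && config$write_chromatograms) {
    stage("export", {
      files <- sprintf("%s.csv", batches)
      for (i in seq_along(batches))
        write_chromatogram(chroms[[i]], file.path(outdir, files[i]))
      man <- cbind(meta[, c("batch", "region", "processing")],
                   file = files)
      write_manifest(man, file.path(outdir, "panel_manifest.json"))
    })
  }

  # -- peak detection -----------------------------------------------------
  peaks <- stage("peaks", lapply(chroms, detect_peaks,
                                 min_snr = config$min_snr,
                                 window = config$smoothing_window,
                                 order = config$smoothing_order))

  # -- retention correction + common peaks --------------------------------
  marker_rt <- stage("markers", {
    named <- default_constituents(30)
    rts <- vapply(named, `[[`, numeric(1), "retention_time")
    ids <- vapply(named, `[[`, character(1), "id")
    known <- ids %in% amb_reference_curves()$analyte
    stats::setNames(rts[known], ids[known])
  })
  find_markers <- function(pk) {
    hit <- vapply(marker_rt, function(mt) {
      d <- abs(pk$apex_time - mt)
      if (min(d) <= config$marker_window) pk$apex_time[which.min(d)]
      else NA_real_
    }, numeric(1))
    hit[!is.na(hit)]
  }
  table <- stage("fingerprint", {
    mk <- lapply(peaks, find_markers)
    ref_batch <- batches[1]
    corrected <- correct_retention_times(peaks, mk, mk[[ref_batch]])
    match_common_peaks(corrected, ref_batch, window = config$window,
                       markers = marker_rt)
  })

  # -- similarity ---------------------------------------------------------
  sim <- stage("similarity", {
    st <- if (config$similarity_on == "peaks") similarity_table(table)
      else {
        avg <- chroms[[1]]
        mint <- Reduce(`+`, lapply(chroms, function(ch)
          stats::approx(ch$time, ch$intensity, xout = avg$time,
                        rule = 2)$y)) / length(chroms)
        ref <- chromatogram(avg$time, mint)
        data.frame(batch = batches, similarity = vapply(
          chroms, function(ch) curve_similarity(ref, ch), numeric(1)),
          row.names = NULL)
      }
    st <- merge(meta, st, by = "batch", sort = FALSE)
    st$method <- config$similarity_on
    st[match(batches, st$batch), ]
  })

  # -- chemometrics -------------------------------------------------------
  chemo <- stage("chemometrics", {
    scaled <- preprocess(table$areas, config$scaling)
    pca <- pca_fit(scaled, k = config$pca_k)
    hca <- hca_fit(scaled, k = config$hca_k, linkage = config$linkage)
    y <- meta[[config$contrast]]
    opls <- oplsda_fit(scaled, y, n_orthogonal = config$n_orthogonal)
    perm <- permutation_test(scaled, y, n_perm = config$n_perm,
                             seed = derive_seed(config$seed, 3),
                             n_orthogonal = config$n_orthogonal)
    list(scaled = scaled, pca = pca, hca = hca, opls = opls, perm = perm)
  })

  # -- calibration / validation ------------------------------------------
  valid <- stage("validation", {
    rc <- amb_reference_curves()
    noise <- tryCatch(
      estimate_noise(chroms[[1]], config$noise_region),
      error = function(e) structure(list(sd = 0,
                                         region = config$noise_region),
                                    class = "noise_estimate"))
    rows <- list(); curves <- list(); series <- list()
    for (i in seq_len(nrow(rc))) {
      spec <- constituent_spec(rc$analyte[i], retention_time = 10,
                               response_slope = rc$slope[i],
                               response_intercept = rc$intercept[i])
      ser <- simulate_calibration_series(
        spec, seq(rc$c_min[i], rc$c_max[i], length.out = 5),
        replicate_cv = config$calibration_cv,
        seed = derive_seed(config$seed, 10 + i))
      cv <- fit_calibration(ser, rc$analyte[i])
      sens <- cv$slope / (0.08 * sqrt(2 * pi))  # height per ug/mL
      ll <- lod_loq(noise, sens)
      rows[[i]] <- data.frame(analyte = rc$analyte[i], slope = cv$slope,
                              intercept = cv$intercept,
                              r_squared = cv$r_squared,
                              c_min = cv$range[1], c_max = cv$range[2],
                              lod = ll$lod, loq = ll$loq)
      curves[[rc$analyte[i]]] <- cv
      series[[rc$analyte[i]]] <- ser
    }
    list(table = do.call(rbind, rows), curves = curves, series = series)
  })

  # -- QAMS ---------------------------------------------------------------
  qams <- stage("qams", {
    iref <- config$internal_reference
    if (!iref %in% names(table$markers))
      stop("internal reference analyte not among matched markers: ", iref)
    rcfs <- lapply(config$qams_analytes, function(an)
      compute_rcf(valid$series[[iref]], valid$series[[an]],
                  analyte = an, internal_ref = iref))
    names(rcfs) <- config$qams_analytes
    pid_s <- table$markers[[iref]]
    rows <- list()
    for (b in batches) {
      a_s <- table$areas[b, pid_s]
      t_s <- table$apex[b, pid_s]
      esm_s <- esm_quantify(a_s, valid$curves[[iref]])
      conc_s <- as.numeric(esm_s)  # 2.00 g / 2 mL: content == concentration
      cand <- data.frame(apex_time = table$apex[b, ],
                         area = table$areas[b, ])
      for (an in config$qams_analytes) {
        pk <- locate_peak_by_rrt(cand, t_s, config$expected_rrt[[an]],
                                 config$rrt_tolerance)
        esm <- esm_quantify(pk$area, valid$curves[[an]])
        qm <- qams_quantify(pk$area, a_s, conc_s, rcfs[[an]])
        rows[[paste(b, an)]] <- data.frame(
          batch = b, analyte = an,
          esm_internal_ref = round(as.numeric(esm_s), 2),
          esm_ug_per_g = round(as.numeric(esm), 2),
          qams_ug_per_g = round(qm, 2),
          rd_percent = relative_deviation(as.numeric(esm), qm))
      }
    }
    list(table = do.call(rbind, rows), rcfs = rcfs)
  })

  # -- durability ---------------------------------------------------------
  durab <- stage("durability", {
    rc <- amb_reference_curves()
    mk_spec <- function(an) {
      i <- match(an, rc$analyte)
      constituent_spec(an, retention_time = 10,
                       response_slope = rc$slope[i],
                       response_intercept = rc$intercept[i],
                       base_concentration = (rc$c_min[i] + rc$c_max[i]) / 2)
    }
    durability_study(mk_spec(config$internal_reference),
                     lapply(config$qams_analytes, mk_spec),
                     area_noise_cv = config$calibration_cv,
                     seed = derive_seed(config$seed, 20))
  })

  # -- report -------------------------------------------------------------
  stage("report", {
    write_table(sim, outdir, "similarity.csv")
    write_peak_table(table, file.path(outdir, "peak_table.csv"))
    write_table(valid$table, outdir, "validation.csv")
    rcf_tab <- do.call(rbind, lapply(qams$rcfs, function(r)
      data.frame(analyte = r$analyte, internal_ref = r$internal_ref,
                 mean_rcf = r$mean_rcf, rcf_rsd = r$rcf_rsd)))
    write_table(rcf_tab, outdir, "rcf.csv")
    write_table(durab$summary, outdir, "durability.csv")
    write_table(qams$table, outdir, "qams.csv")
    write_table(data.frame(batch = rownames(chemo$pca$scores),
                           chemo$pca$scores, check.names = FALSE),
                outdir, "pca_scores.csv")
    write_table(data.frame(peak = rownames(chemo$pca$loadings),
                           chemo$pca$loadings, check.names = FALSE),
                outdir, "pca_loadings.csv")
    write_table(data.frame(batch = batches, group = meta$group,
                           cluster = unname(chemo$hca$labels)),
                outdir, "hca_clusters.csv")
    writeLines(hclust_to_newick(chemo$hca$hclust),
               file.path(outdir, "dendrogram.nwk"))
    v <- vip(chemo$opls)
    write_table(data.frame(peak = names(v), vip = as.numeric(v),
                           flagged = as.numeric(v) > 1),
                outdir, "vip.csv")
    write_table(chemo$perm$record, outdir, "permutation.csv")
    manifest <- list(
      package = "herbfp",
      version = as.character(utils::packageVersion("herbfp")),
      seed = config$seed,
      mode = config$mode,
      parameters = config[setdiff(names(config), c("panel", "manifest"))],
      panel = if (config$mode == "synthetic")
        config$panel[setdiff(names(config$panel), "constituents")]
      else config$manifest,
      chemometrics = list(
        pca_r2 = chemo$pca$r2, pca_q2 = chemo$pca$q2,
        hca_k = chemo$hca$k, oplsda_r2x = chemo$opls$r2x,
        oplsda_r2y = chemo$opls$r2y, oplsda_q2 = chemo$opls$q2,
        permutation_q2_intercept = chemo$perm$q2_intercept,
        permutation_verdict = chemo$perm$verdict))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  })

  invisible(list(similarity = sim, peak_table = table,
                 validation = valid$table, rcf = qams$rcfs,
                 qams = qams$table, durability = durab,
                 chemometrics = chemo, meta = meta,
                 panel = acq$panel, config = config, outdir = outdir))
}
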