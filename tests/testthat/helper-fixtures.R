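# shared fixtures and small oracles

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# adjusted Rand index (independent oracle for cluster agreement)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# panels are reused across tests; build lazily, once per configuration
.panel_cache <- new.env()
cached_panel <- function(key = "default", ...) {
  if (is.null(.panel_cache[[key]]))
    .panel_cache[[key]] <- simulate_panel(panel_config(...))
  .panel_cache[[key]]
}

# noiseless, jitter-free panel (ground-truth comparisons)
clean_panel <- function() {
  cached_panel("clean", area_noise_cv = 0, rt_shift_sd = 0,
               rt_jitter_sd = 0, extras_per_batch = 0)
}

# detection -> correction -> matching, as the pipeline wires it
match_panel <- function(panel, window = 0.1) {
  pks <- lapply(panel$chromatograms, detect_peaks)
  named <- default_constituents(30)
  rts <- vapply(named, `[[`, numeric(1), "retention_time")
  ids <- vapply(named, `[[`, character(1), "id")
  marker_rt <- stats::setNames(rts, ids)[
    ids %in% amb_reference_curves()$analyte]
  mk <- lapply(pks, function(pk) {
    hit <- vapply(marker_rt, function(mt) {
      d <- abs(pk$apex_time - mt)
      if (min(d) <= 0.3) pk$apex_time[which.min(d)] else NA_real_
    }, numeric(1))
    hit[!is.na(hit)]
  })
  corrected <- correct_retention_times(pks, mk, mk[[1]])
  match_common_peaks(corrected, names(pks)[1], window = window,
                     markers = marker_rt)
}

ref_spec <- function(analyte, rt = 10) {
  rc <- amb_reference_curves()
  i <- match(analyte, rc$analyte)
  constituent_spec(analyte, retention_time = rt,
                   response_slope = rc$slope[i],
                   response_intercept = rc$intercept[i],
                   base_concentration = (rc$c_min[i] + rc$c_max[i]) / 2)
}

table2_levels <- function(analyte, n = 5) {
  rc <- amb_reference_curves()
  i <- match(analyte, rc$analyte)
  seq(rc$c_min[i], rc$c_max[i], length.out = n)
}
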