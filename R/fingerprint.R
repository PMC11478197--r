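# Fingerprint construction: marker-anchored retention-time correction,
# common-peak matching across batches, averaged reference fingerprint,
# cosine similarity scoring.

#' Piecewise-linear time warp through marker anchors
#'
#' Maps times so that `from` anchors land exactly on `to` anchors; times
#' between anchors are interpolated linearly and times beyond the terminal
#' anchors are extrapolated with the terminal segment slopes.
#'
#' @param t times to warp (minutes).
#' @param from,to anchor times in the source and target scale; equal length
#'   >= 2, both strictly increasing after ordering by `from`.
#' @return warped times.
#' @export
warp_times <- function(t, from, to) {
  if (length(from) != length(to) || length(from) < 2)
    stop("at least 2 marker anchors required")
  o <- order(from)
  from <- from[o]; to <- to[o]
  if (any(diff(from) <= 0) || any(diff(to) <= 0))
    stop("non-monotone marker correspondence")
  n <- length(from)
  res <- stats::approx(from, to, xout = t, rule = 2)$y
  s1 <- (to[2] - to[1]) / (from[2] - from[1])
  sn <- (to[n] - to[n - 1]) / (from[n] - from[n - 1])
  lo <- t < from[1]; hi <- t > from[n]
  res[lo] <- to[1] + (t[lo] - from[1]) * s1
  res[hi] <- to[n] + (t[hi] - from[n]) * sn
  res
}

#' Correct retention times against a reference batch
#'
#' Multipoint correction by marker-peak matching: each batch's identified
#' marker apexes are mapped exactly onto the reference marker times and all
#' other peak times (apex and bounds) are warped piecewise-linearly.
#'
#' @param peak_lists named list of `peak_list` data.frames, one per batch.
#' @param markers named list (same names) of named numeric vectors: marker
#'   apex times per batch.
#' @param reference_markers named numeric vector of marker apex times on the
#'   reference time scale. Each batch must share >= 2 marker names with it.
#' @return list of corrected `peak_list`s (same names and shapes).
#' @export
correct_retention_times <- function(peak_lists, markers,
                                    reference_markers) {
  stopifnot(is.list(peak_lists), is.list(markers))
  lapply(stats::setNames(names(peak_lists), names(peak_lists)),
         function(b) {
    pk <- peak_lists[[b]]
    mk <- markers[[b]]
    shared <- intersect(names(mk), names(reference_markers))
    if (length(shared) < 2)
      stop("batch ", b, ": fewer than 2 markers shared with the reference")
    from <- unname(mk[shared])
    to <- unname(reference_markers[shared])
    pk$apex_time <- warp_times(pk$apex_time, from, to)
    if (!is.null(pk$left)) pk$left <- warp_times(pk$left, from, to)
    if (!is.null(pk$right)) pk$right <- warp_times(pk$right, from, to)
    pk[order(pk$apex_time), , drop = FALSE]
  })
}

#' Match peaks across batches into a common-peak table
#'
#' One-pass greedy nearest-apex matching of every batch's peaks to the
#' reference batch's peaks inside a retention-time window (default 0.1 min):
#' candidate pairs are taken in order of increasing time difference (ties:
#' earlier apex first) and each peak is used at most once. Reference peaks
#' matched in every batch form the common set.
#'
#' @param peak_lists named list of (corrected) `peak_list`s.
#' @param reference_batch name of the reference batch in `peak_lists`.
#' @param window matching half-window, minutes (> 0).
#' @param allow_missing if TRUE, batches with an empty peak list are dropped
#'   (with a message) and the common set is computed over the rest;
#'   otherwise an empty batch is an error.
#' @param markers optional named numeric vector of reference marker apex
#'   times; matched to common peaks for annotation.
#' @return object of class `peak_table`: list with `batches`, `peak_ids`,
#'   `ref_times` (reference-batch apexes of the common peaks), `areas` and
#'   `apex` (batches x common peaks matrices), and `markers` (named map
#'   analyte -> peak id, possibly empty).
#' @export
match_common_peaks <- function(peak_lists, reference_batch, window = 0.1,
                               allow_missing = FALSE, markers = NULL) {
  if (window <= 0) stop("window must be > 0")
  if (!reference_batch %in% names(peak_lists))
    stop("reference batch not present: ", reference_batch)
  empty <- vapply(peak_lists, nrow, integer(1)) == 0L
  if (any(empty)) {
    if (!allow_missing || empty[[reference_batch]])
      stop("empty peak list for batch(es): ",
           paste(names(peak_lists)[empty], collapse = ", "))
    message("dropping batch(es) with no peaks: ",
            paste(names(peak_lists)[empty], collapse = ", "))
    peak_lists <- peak_lists[!empty]
  }
  ref <- peak_lists[[reference_batch]]
  nr <- nrow(ref)
  batches <- names(peak_lists)
  areas <- apex <- matrix(NA_real_, length(batches), nr,
                          dimnames = list(batches, NULL))
  for (b in batches) {
    pk <- peak_lists[[b]]
    cand <- expand.grid(i = seq_len(nr), j = seq_len(nrow(pk)))
    cand$d <- abs(ref$apex_time[cand$i] - pk$apex_time[cand$j])
    cand <- cand[cand$d <= window, , drop = FALSE]
    cand <- cand[order(cand$d, pk$apex_time[cand$j]), , drop = FALSE]
    used_i <- logical(nr); used_j <- logical(nrow(pk))
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (used_i[i] || used_j[j]) next
      used_i[i] <- TRUE; used_j[j] <- TRUE
      areas[b, i] <- pk$area[j]
      apex[b, i] <- pk$apex_time[j]
    }
  }
  common <- which(colSums(is.na(areas)) == 0L)
  if (!length(common)) stop("no common peaks across batches")
  peak_ids <- sprintf("peak_%02d", seq_along(common))
  areas <- areas[, common, drop = FALSE]
  apex <- apex[, common, drop = FALSE]
  colnames(areas) <- colnames(apex) <- peak_ids
  ref_times <- ref$apex_time[common]
  marker_map <- character(0)
  if (!is.null(markers)) {
    hit <- vapply(markers, function(mt) {
      d <- abs(ref_times - mt)
      if (min(d) <= window) which.min(d) else NA_integer_
    }, integer(1))
    marker_map <- stats::setNames(peak_ids[hit], names(markers))
    marker_map <- marker_map[!is.na(hit)]
  }
  structure(list(batches = batches, peak_ids = peak_ids,
                 ref_times = ref_times, areas = areas, apex = apex,
                 markers = marker_map),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> %d batches x %d common peaks\n",
              length(x$batches), length(x$peak_ids)))
  invisible(x)
}

#' Build the standardized reference fingerprint
#'
#' The averaged ("control") fingerprint: per-peak arithmetic mean of areas
#' across batches, with reference times as the mean matched apex times.
#'
#' @param table a [match_common_peaks()] result.
#' @param method only `"average"` is supported.
#' @return object of class `reference_fingerprint`: list with `peak_ids`,
#'   `ref_times`, `mean_areas`, `method`.
#' @export
build_reference_fingerprint <- function(table, method = "average") {
  stopifnot(inherits(table, "peak_table"))
  if (!identical(method, "average"))
    stop("unsupported fingerprint method: ", method)
  if (!length(table$peak_ids)) stop("empty peak table")
  structure(list(peak_ids = table$peak_ids,
                 ref_times = colMeans(table$apex),
                 mean_areas = colMeans(table$areas),
                 method = method),
            class = "reference_fingerprint")
}

#' Cosine similarity between two fingerprint vectors
#'
#' Congruence coefficient `sum(x*y) / (||x|| ||y||)`: symmetric, invariant
#' to positive rescaling of either argument, 1 for proportional vectors.
#'
#' @param x,y numeric vectors of equal length >= 1; neither all-zero.
#' @return score in `[-1, 1]` (in `[0, 1]` for non-negative area vectors).
#' @export
similarity <- function(x, y) {
  if (length(x) != length(y) || !length(x))
    stop("vectors must have equal positive length")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero vector rejected")
  sum(x * y) / (nx * ny)
}

#' Similarity of every batch to the reference fingerprint
#'
#' @param table a `peak_table`.
#' @param reference a `reference_fingerprint`; default the average
#'   fingerprint of `table`.
#' @return data.frame with columns `batch`, `similarity`.
#' @export
similarity_table <- function(table,
                             reference = build_reference_fingerprint(table)) {
  stopifnot(inherits(table, "peak_table"))
  data.frame(
    batch = table$batches,
    similarity = vapply(table$batches, function(b)
      similarity(table$areas[b, ], reference$mean_areas), numeric(1)),
    row.names = NULL)
}

#' Full-curve cosine similarity between two chromatograms
#'
#' Comparison variant computed on the sampled intensity curves rather than
#' the common-peak vector (the convention of the reference software is
#' unpublished; both variants are labelled in pipeline output).
#'
#' @param a,b chromatograms; `b` is interpolated onto `a`'s grid.
#' @return cosine score.
#' @export
curve_similarity <- function(a, b) {
  stopifnot(inherits(a, "chromatogram"), inherits(b, "chromatogram"))
  yb <- stats::approx(b$time, b$intensity, xout = a$time, rule = 2)$y
  similarity(a$intensity, yb)
}

#' Write a peak table and its sidecar metadata
#'
#' Areas go to `<path>` as CSV (rows = batches, columns = peak ids); the
#' reference times and marker annotations go to `<path>.json`.
#' @param table a `peak_table`.
#' @param path CSV path.
#' @export
write_peak_table <- function(table, path) {
  df <- data.frame(batch = table$batches, table$areas, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(peak_ids = table$peak_ids, ref_times = table$ref_times,
         markers = as.list(table$markers)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
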