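#' Construct a chromatogram
#'
#' A chromatogram is the raw unit of all processing: a strictly increasing,
#' uniformly spaced time grid (minutes) with a detector intensity trace
#' (counts) and free-form sample metadata (batch id, origin, processing
#' method, acquisition parameters).
#'
#' @param time numeric vector of acquisition times in minutes; strictly
#'   increasing, uniform spacing (relative tolerance 1e-9).
#' @param intensity numeric vector of detector counts, finite, same length
#'   as `time`.
#' @param meta named list of sample metadata (e.g. `batch`, `origin`,
#'   `processing`).
#' @return An object of class `chromatogram`: a list with elements `time`,
#'   `intensity`, `meta`.
#' @export
chromatogram <- function(time, intensity, meta = list()) {
  time <- as.numeric(time)
  intensity <- as.numeric(intensity)
  if (length(time) != length(intensity) || length(time) < 2L)
    stop("time and intensity must have equal length >= 2")
  if (!all(is.finite(time)) || !all(is.finite(intensity)))
    stop("time and intensity must be finite")
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9 * max(abs(dt)))
    stop("time grid must be uniform (relative tolerance 1e-9)")
  structure(list(time = time, intensity = intensity, meta = as.list(meta)),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %d points, %.3f-%.3f min", length(x$time),
              x$time[1], x$time[length(x$time)]))
  if (!is.null(x$meta$batch)) cat(sprintf(", batch %s", x$meta$batch))
  cat("\n")
  invisible(x)
}

#' Grid spacing of a chromatogram
#' @param chrom a `chromatogram`.
#' @return scalar spacing in minutes.
#' @keywords internal
grid_dt <- function(chrom) (chrom$time[length(chrom$time)] - chrom$time[1]) /
  (length(chrom$time) - 1L)

#' Read / write chromatograms as two-column CSV
#'
#' The on-disk interchange format is a UTF-8 CSV with header
#' `time_min,intensity` and decimal points.
#'
#' @param chrom a `chromatogram`.
#' @param path file path.
#' @param meta metadata list to attach on read.
#' @return `write_chromatogram` returns `path` invisibly;
#'   `read_chromatogram` returns a `chromatogram`.
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  df <- data.frame(time_min = chrom$time, intensity = chrom$intensity)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_chromatogram
#' @export
read_chromatogram <- function(path, meta = list()) {
  df <- utils::read.csv(path)
  if (!all(c("time_min", "intensity") %in% names(df)))
    stop("chromatogram CSV must have columns time_min,intensity: ", path)
  chromatogram(df$time_min, df$intensity, meta = meta)
}

#' Write / read a panel manifest
#'
#' JSON manifest listing, per batch, the chromatogram file and its sample
#' metadata (`batch`, `origin`, `region`, `processing`).
#'
#' @param batches data.frame with at least columns `batch`, `file`,
#'   `region`, `processing`.
#' @param path manifest path.
#' @export
write_manifest <- function(batches, path) {
  jsonlite::write_json(batches, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- jsonlite::fromJSON(path)
  need <- c("batch", "file", "region", "processing")
  if (!all(need %in% names(df)))
    stop("manifest must provide columns: ", paste(need, collapse = ", "))
  df
}
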