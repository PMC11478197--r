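#' Published calibration lines for the six identified constituents
#'
#' Regression lines (peak area \eqn{y} on concentration \eqn{x},
#' \eqn{\mu g\,mL^{-1}}) for the six constituents identified in the Allii
#' Macrostemonis Bulbus (AMB) fingerprint, together with the validated
#' concentration range, coefficient of determination, and the limits of
#' detection and quantification. These are the reference ELSD responses used
#' as simulator defaults and as inputs to the quantification stage.
#'
#' @return A data.frame with one row per analyte and columns `analyte`,
#'   `slope` (area per ug/mL), `intercept` (area), `r_squared`, `c_min`,
#'   `c_max` (ug/mL), `lod`, `loq` (ug/mL).
#' @export
#' @examples
#' amb_reference_curves()
amb_reference_curves <- function() {
  data.frame(
    analyte = c("adenosine", "syringin", "macrostemonoside_T",
                "macrostemonoside_A", "macrostemonoside_U",
                "macrostemonoside_V"),
    slope = c(2463.0, 1254.7, 861.0, 2223.2, 1308.1, 1638.4),
    intercept = c(-127.53, -78.93, -69.574, -117.7, -71.569, -80.186),
    r_squared = c(0.9988, 0.9974, 0.9968, 0.9970, 0.9965, 0.9983),
    c_min = c(6.62, 14.24, 25.83, 21.42, 24.37, 31.08),
    c_max = c(109.11, 96.31, 81.35, 72.31, 86.44, 89.37),
    lod = c(1.43, 3.53, 5.71, 5.67, 5.76, 8.16),
    loq = c(4.76, 11.78, 19.05, 18.90, 19.19, 27.20),
    stringsAsFactors = FALSE
  )
}

#' Reference batch layout for the 18-batch AMB panel
#'
#' Batch identifiers, geographic origin and processing method for the 18
#' reference batches (S1--S18): nine northern-province and six
#' southern-province batches, each processed by post-steaming drying, direct
#' drying or freeze drying. This layout drives the default group structure of
#' the panel simulator.
#'
#' @return data.frame with columns `batch`, `origin` (city, province),
#'   `region` (`northern`/`southern`) and `processing`
#'   (`post_steaming_dried`/`directly_dried`/`freeze_dried`).
#' @export
amb_batch_layout <- function() {
  origin <- c(rep("Changchun, Jilin", 3), rep("Benxi, Liaoning", 3),
              rep("Luoyang, Henan", 3), rep("Zigong, Sichuan", 3),
              rep("Bijie, Guizhou", 3), rep("Changchun, Jilin", 3))
  data.frame(
    batch = paste0("S", 1:18),
    origin = origin,
    region = c(rep("northern", 9), rep("southern", 6), rep("northern", 3)),
    processing = rep(c("post_steaming_dried", "directly_dried",
                       "freeze_dried"), 6),
    stringsAsFactors = FALSE
  )
}

#' Reference ESM/QAMS content determinations for the 18-batch panel
#'
#' Published external-standard (ESM) and single-marker (QAMS) contents of
#' macrostemonosides T and U (internal reference: macrostemonoside A, ESM
#' only) for batches S1--S18, with the relative deviation (RD, %) between the
#' two quantification routes. Used as input for internal-consistency checks
#' of the RD formula and of the stated RD envelope.
#'
#' @return data.frame with columns `batch`, `esm_A`, `esm_T`, `qams_T`,
#'   `rd_T`, `esm_U`, `qams_U`, `rd_U`; contents in ug/g, RD in percent.
#' @export
amb_reference_contents <- function() {
  x <- rbind(
    c(66.33, 102.20, 101.73, -0.46, 77.98, 77.15, -1.06),
    c(168.46, 346.97, 345.51, -0.42, 98.59, 97.94, -0.66),
    c(95.77, 101.75, 101.78, 0.03, 198.86, 197.75, -0.56),
    c(89.38, 101.75, 101.31, -0.43, 84.27, 84.07, -0.24),
    c(180.09, 344.05, 344.87, 0.24, 98.09, 97.90, -0.19),
    c(96.92, 102.25, 102.10, -0.15, 191.63, 191.15, -0.25),
    c(75.26, 108.41, 108.12, -0.27, 92.24, 91.92, -0.35),
    c(162.42, 352.36, 351.77, -0.17, 97.51, 96.54, -0.99),
    c(76.65, 137.22, 136.67, -0.40, 79.35, 80.11, 0.96),
    c(72.07, 104.73, 103.82, -0.87, 135.57, 134.61, -0.71),
    c(154.23, 309.27, 308.73, -0.17, 102.24, 101.81, -0.42),
    c(63.67, 98.22, 98.12, -0.10, 116.00, 115.63, -0.32),
    c(63.02, 97.46, 97.08, -0.39, 114.26, 114.95, 0.60),
    c(82.52, 234.76, 234.73, -0.01, 261.21, 261.09, -0.05),
    c(66.13, 104.19, 104.18, -0.01, 111.98, 112.00, 0.02),
    c(68.12, 98.34, 98.79, 0.46, 69.06, 69.84, 1.13),
    c(78.46, 250.43, 250.31, -0.05, 70.26, 70.39, 0.19),
    c(63.51, 99.26, 99.17, -0.09, 79.52, 79.87, 0.44)
  )
  out <- data.frame(batch = paste0("S", 1:18), x, stringsAsFactors = FALSE)
  names(out) <- c("batch", "esm_A", "esm_T", "qams_T", "rd_T",
                  "esm_U", "qams_U", "rd_U")
  out
}
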