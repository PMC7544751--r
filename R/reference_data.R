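# Reference constants from the benchmark GEANT4 study this package
# re-implements at desk scale, plus literature normalized-dose rows.
# These are comparison targets, never recomputed.

#' Reference per-finger dose slopes (Gy per decay)
#'
#' Fitted slopes reported by the benchmark GEANT4 simulation of the same
#' scenario (300 MBq F-18 in a 9 mm tungsten-shielded syringe).
#' @return named numeric vector, one entry per finger.
#' @export
reference_slopes <- function() {
  c(thumb = 1.82e-16, index = 5.68e-15, middle = 5.25e-15,
    ring = 2.16e-15, small = 1.07e-15)
}

#' Reference absorbed doses for 300 MBq x 120 s (mGy)
#'
#' As printed in the benchmark study. Note: the thumb entry (0.006) is not
#' consistent with its printed slope at 3-decimal rounding
#' (1.82e-16 x 3.6e10 = 0.00655, which rounds to 0.007).
#' @return named numeric vector.
#' @export
reference_doses_mGy <- function() {
  c(thumb = 0.006, index = 0.204, middle = 0.189, ring = 0.078,
    small = 0.039)
}

#' Literature normalized Hp(0.07) summaries (mSv/GBq)
#'
#' Published maximum normalized-dose statistics for F-18 FDG handling,
#' stored for side-by-side reporting.
#' @return data.frame: study, range_lo, range_hi, mean, median.
#' @export
reference_normalized <- function() {
  data.frame(
    study = c("benchmark simulation (this scenario)",
              "quality-control dispensing study",
              "F-18 preparation study A",
              "F-18 preparation study B",
              "F-18 preparation study C"),
    range_lo = c(0.13, 0.02, 0.29, 0.03, 0.10),
    range_hi = c(0.68, 0.85, 0.85, 2.06, 4.43),
    mean = c(0.35, 0.50, 0.57, 0.43, 1.20),
    median = c(0.29, 0.35, 0.57, 0.25, 0.83),
    stringsAsFactors = FALSE)
}

#' Published per-finger Hp(0.07) measurements
#'
#' The measured thermoluminescent-dosimeter records (four workers at about
#' 300 MBq: three nurses at two diagnostic centres and one
#' quality-control chemist at a production centre) shipped with the
#' package as a plain-text fixture.
#' @return data.frame of [load_measurements] records.
#' @export
published_measurements <- function() {
  load_measurements(system.file("extdata", "measured_hp007_published.csv",
                                package = "handdose", mustWork = TRUE))
}
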