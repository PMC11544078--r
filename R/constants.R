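#' Isotopic constants for strontium data reduction
#'
#' Fixed constants used throughout the reduction chain: the canonical
#' 86Sr/88Sr ratio used by the exponential-law mass-fractionation
#' correction, the accepted 87Sr/86Sr value of the NIST SRM987 strontium
#' carbonate standard, and the atomic masses of the three isotopes involved.
#'
#' @param canonical_86_88 canonical 86Sr/88Sr ratio (dimensionless).
#' @param srm987_accepted accepted 87Sr/86Sr of NIST SRM987.
#' @param mass_86,mass_87,mass_88 atomic masses of 86Sr, 87Sr and 88Sr (u).
#' @return A list of class `"sr_constants"`.
#' @examples
#' sr_constants()
#' @export
sr_constants <- function(canonical_86_88 = 0.1194,
                         srm987_accepted = 0.71025,
                         mass_86 = 85.9092607,
                         mass_87 = 86.9088775,
                         mass_88 = 87.9056122) {
  stopifnot(canonical_86_88 > 0, srm987_accepted > 0,
            mass_86 < mass_87, mass_87 < mass_88)
  structure(list(canonical_86_88 = canonical_86_88,
                 srm987_accepted = srm987_accepted,
                 mass_86 = mass_86, mass_87 = mass_87, mass_88 = mass_88),
            class = "sr_constants")
}

#' Describe a measurement batch of the SRM987 standard
#'
#' A batch groups sample measurements with the mean 87Sr/86Sr obtained for
#' the SRM987 standard on the same instrument run, used to normalize sample
#' ratios to the standard's accepted value.
#'
#' @param batch_id identifier of the instrument run.
#' @param measured_standard_mean mean measured 87Sr/86Sr of the standard.
#' @param n_standards number of standard measurements behind the mean.
#' @return A list of class `"standard_batch"`.
#' @examples
#' standard_batch("triton", 0.710231, 42)
#' @export
standard_batch <- function(batch_id, measured_standard_mean, n_standards = NA_integer_) {
  if (!is.numeric(measured_standard_mean) || measured_standard_mean <= 0)
    stop("`measured_standard_mean` must be a positive number")
  structure(list(batch_id = as.character(batch_id),
                 measured_standard_mean = as.numeric(measured_standard_mean),
                 n_standards = as.integer(n_standards)),
            class = "standard_batch")
}

#' Describe the procedural blank of a clean-room measurement environment
#'
#' @param blank_sr_ng strontium mass contributed by the blank (ng).
#' @param blank_ratio 87Sr/86Sr ratio of the blank strontium.
#' @return A list of class `"blank_model"`.
#' @examples
#' blank_model(0.175, 0.70905)
#' @export
blank_model <- function(blank_sr_ng, blank_ratio) {
  if (!is.numeric(blank_sr_ng) || blank_sr_ng < 0)
    stop("`blank_sr_ng` must be a non-negative mass in ng")
  if (!is.numeric(blank_ratio) || blank_ratio <= 0)
    stop("`blank_ratio` must be a positive ratio")
  structure(list(blank_sr_ng = as.numeric(blank_sr_ng),
                 blank_ratio = as.numeric(blank_ratio)),
            class = "blank_model")
}
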