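# Reduction chain for thermal-ionization 87Sr/86Sr measurements:
# exponential-law mass-fractionation correction, normalization to the
# SRM987 standard, blank-contamination mixing, and the paired
# cleaned/uncleaned evaluation.

#' Exponential-law mass-fractionation correction
#'
#' Corrects a measured 87Sr/86Sr ratio for instrumental mass fractionation
#' using the simultaneously measured 86Sr/88Sr and the exponential law: the
#' fractionation exponent is
#' `beta = log(canonical / measured_86_88) / log(M86 / M88)` and the
#' corrected ratio is `measured_87_86 * (M87 / M86)^beta`. When the
#' measured 86Sr/88Sr equals the canonical 0.1194 the correction is the
#' identity.
#'
#' @param measured_87_86 measured 87Sr/86Sr ratio(s), positive.
#' @param measured_86_88 measured 86Sr/88Sr ratio(s), positive; `NA` entries
#'   (ratio not recorded) pass the input through unchanged and are flagged
#'   in the `"corrected"` attribute.
#' @param constants an [sr_constants()] object.
#' @return Numeric vector of corrected ratios with a logical attribute
#'   `"corrected"` saying which elements actually received a correction.
#' @examples
#' fractionation_correct(0.71000, 0.1194)  # identity
#' fractionation_correct(0.71000, 0.1200)
#' @export
fractionation_correct <- function(measured_87_86, measured_86_88 = NA_real_,
                                  constants = sr_constants()) {
  if (any(!is.finite(measured_87_86) | measured_87_86 <= 0))
    stop("`measured_87_86` must be positive and finite")
  measured_86_88 <- rep_len(measured_86_88, length(measured_87_86))
  if (any(!is.na(measured_86_88) & measured_86_88 <= 0))
    stop("`measured_86_88` must be positive where present")
  has <- !is.na(measured_86_88)
  beta <- rep(0, length(measured_87_86))
  beta[has] <- log(constants$canonical_86_88 / measured_86_88[has]) /
    log(constants$mass_86 / constants$mass_88)
  out <- measured_87_86 * (constants$mass_87 / constants$mass_86)^beta
  attr(out, "corrected") <- has
  out
}

#' Normalize sample ratios to the SRM987 standard
#'
#' Adjusts measured 87Sr/86Sr ratios so that the batch mean of the SRM987
#' standard sits at its accepted value (0.71025). The default is an
#' additive offset, `ratio + (accepted - batch mean)`, which preserves
#' differences between samples of the same batch; a multiplicative variant
#' (`ratio * accepted / batch mean`) is available and differs by less than
#' 1e-6 at typical drift magnitudes.
#'
#' @param ratio ratio(s) to normalize.
#' @param batch a [standard_batch()] object.
#' @param constants an [sr_constants()] object.
#' @param method `"additive"` (default) or `"multiplicative"`.
#' @return Numeric vector of normalized ratios.
#' @examples
#' b <- standard_batch("triton", 0.710231, 42)
#' normalize_to_srm987(0.71100, b)
#' @export
normalize_to_srm987 <- function(ratio, batch, constants = sr_constants(),
                                method = c("additive", "multiplicative")) {
  stopifnot(inherits(batch, "standard_batch"))
  method <- match.arg(method)
  if (method == "additive")
    ratio + (constants$srm987_accepted - batch$measured_standard_mean)
  else
    ratio * constants$srm987_accepted / batch$measured_standard_mean
}

#' Blank-contamination mixing model
#'
#' Predicts the ratio actually measured when a sample of known true ratio is
#' mixed with the procedural blank, by mass-weighted two-component mixing:
#' `measured = (true * m_sample + blank_ratio * m_blank) / (m_sample +
#' m_blank)`. The contamination error is `measured - true`. Reported values
#' are rounded to 5 decimal places, the precision at which ratios are
#' printed.
#'
#' @param true_ratio true 87Sr/86Sr of the sample strontium.
#' @param sample_sr_ng strontium mass of the sample (ng).
#' @param blank a [blank_model()] object.
#' @param digits decimal places for the reported (rounded) values.
#' @return A list of class `"blank_mixing"` with full-precision
#'   `measured_ratio` and `contamination_error` plus their rounded
#'   `*_reported` counterparts.
#' @examples
#' blank_mixing(0.71000, 7.278, blank_model(0.175, 0.70905))
#' @export
blank_mixing <- function(true_ratio, sample_sr_ng, blank, digits = 5) {
  stopifnot(inherits(blank, "blank_model"))
  if (!is.numeric(true_ratio) || true_ratio <= 0)
    stop("`true_ratio` must be positive")
  if (!is.numeric(sample_sr_ng) || sample_sr_ng < 0)
    stop("`sample_sr_ng` must be non-negative")
  total <- sample_sr_ng + blank$blank_sr_ng
  if (total <= 0)
    stop("sample and blank strontium masses are both zero")
  measured <- (true_ratio * sample_sr_ng + blank$blank_ratio * blank$blank_sr_ng) / total
  err <- measured - true_ratio
  structure(list(measured_ratio = measured,
                 contamination_error = err,
                 measured_ratio_reported = round(measured, digits),
                 contamination_error_reported = round(err, digits)),
            class = "blank_mixing")
}

#' @export
print.blank_mixing <- function(x, ...) {
  cat("Blank-contamination mixing\n")
  cat(sprintf("  measured ratio     : %.5f\n", x$measured_ratio_reported))
  cat(sprintf("  contamination error: %+.5f\n", x$contamination_error_reported))
  invisible(x)
}

#' Paired cleaned/uncleaned sample evaluation
#'
#' Summarizes a surface-cleaning experiment in which each specimen was split
#' and one half cleaned: an ordinary least-squares regression of the cleaned
#' on the uncleaned ratio (slope, intercept, R squared) and the sample
#' standard deviation of the cleaned-minus-uncleaned differences.
#'
#' @param cleaned,uncleaned paired ratio vectors of equal length (>= 3).
#' @return A list of class `"cleaning_stats"` with `slope`, `intercept`,
#'   `r_squared`, `sd_of_differences` and `n`.
#' @examples
#' u <- c(0.708, 0.709, 0.710, 0.711, 0.712)
#' paired_cleaning_stats(u + 0.0001, u)
#' @export
paired_cleaning_stats <- function(cleaned, uncleaned) {
  if (length(cleaned) != length(uncleaned))
    stop("`cleaned` and `uncleaned` must be paired (equal length)")
  if (length(cleaned) < 3)
    stop("at least 3 pairs are required")
  if (var(uncleaned) == 0)
    stop("`uncleaned` has zero variance; regression undefined")
  fit <- lm(cleaned ~ uncleaned)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((cleaned - mean(cleaned))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 sd_of_differences = sd(cleaned - uncleaned),
                 n = length(cleaned)),
            class = "cleaning_stats")
}

#' @export
print.cleaning_stats <- function(x, ...) {
  cat(sprintf("Cleaned vs uncleaned (n = %d): y = %.4fx %+.4f, R^2 = %.3f\n",
              x$n, x$slope, x$intercept, x$r_squared))
  cat(sprintf("  sd of paired differences: %.5f\n", x$sd_of_differences))
  invisible(x)
}

#' Reduce a table of raw measurements to corrected, normalized ratios
#'
#' Applies, per row, the exponential-law fractionation correction (where a
#' measured 86Sr/88Sr is present) followed by SRM987 normalization using the
#' row's standard batch. The order (fractionation first) is configurable.
#'
#' @param measurements data frame with at least `sample_id` and
#'   `measured_87_86`; optional columns `measured_86_88`, `standard_batch_id`,
#'   `site_code`, `country`, `material`, `sr_mass_ng`, `body_parts`.
#' @param batches a list of [standard_batch()] objects (named by batch id, or
#'   carrying `batch_id` fields); `NULL` skips normalization.
#' @param constants an [sr_constants()] object.
#' @param order `"fractionation_first"` (default) or `"normalization_first"`.
#' @param method normalization method, see [normalize_to_srm987()].
#' @return The input data frame with columns `fractionation_corrected_87_86`,
#'   `normalized_87_86`, `ratio` (the final value) and logical provenance
#'   flags `flag_fractionation`, `flag_normalized`.
#' @export
reduce_measurements <- function(measurements, batches = NULL,
                                constants = sr_constants(),
                                order = c("fractionation_first",
                                          "normalization_first"),
                                method = "additive") {
  order <- match.arg(order)
  req <- c("sample_id", "measured_87_86")
  if (!all(req %in% names(measurements)))
    stop("`measurements` needs columns: ", paste(req, collapse = ", "))
  m8688 <- if ("measured_86_88" %in% names(measurements))
    measurements$measured_86_88 else rep(NA_real_, nrow(measurements))

  batch_mean_for <- function(ids) {
    if (is.null(batches)) return(rep(NA_real_, length(ids)))
    if (inherits(batches, "standard_batch")) batches <- list(batches)
    nm <- names(batches)
    if (is.null(nm) || any(nm == ""))
      nm <- vapply(batches, function(b) b$batch_id, character(1))
    means <- vapply(batches, function(b) b$measured_standard_mean, numeric(1))
    names(means) <- nm
    if (length(batches) == 1L && all(is.na(ids)))
      return(rep(means[[1]], length(ids)))
    unname(means[as.character(ids)])
  }

  ids <- if ("standard_batch_id" %in% names(measurements))
    measurements$standard_batch_id else rep(NA_character_, nrow(measurements))
  bm <- batch_mean_for(ids)

  frac <- function(x) fractionation_correct(x, m8688, constants)
  norm <- function(x) ifelse(is.na(bm), x,
                             if (method == "additive")
                               x + (constants$srm987_accepted - bm)
                             else x * constants$srm987_accepted / bm)

  raw <- measurements$measured_87_86
  if (order == "fractionation_first") {
    fc <- frac(raw)
    fin <- norm(as.numeric(fc))
  } else {
    nz <- norm(raw)
    fc <- frac(nz)
    fin <- as.numeric(fc)
  }
  measurements$fractionation_corrected_87_86 <- as.numeric(frac(raw))
  measurements$normalized_87_86 <- fin
  measurements$ratio <- fin
  measurements$flag_fractionation <- attr(fc, "corrected")
  measurements$flag_normalized <- !is.na(bm)
  measurements
}

#' Read and write measurement tables
#'
#' Plain-CSV readers/writers for raw and corrected measurement tables. A
#' column mapping (`c(file_column = "canonical_name")` reversed:
#' `c(canonical = "file_column")`) tolerates other dialects.
#'
#' @param path CSV file path.
#' @param col_map optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(measured_87_86 = "Sr87_86")`.
#' @return `read_measurements()`: a data frame with canonical column names.
#' @export
read_measurements <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("measurement table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(df))
        stop("mapped column not in file: ", src)
      names(df)[names(df) == src] <- canon
    }
  }
  if (!"sample_id" %in% names(df))
    stop("measurement table needs a `sample_id` column (map it via `col_map`)")
  if (any(c("measured_87_86", "ratio") %in% names(df)) == FALSE)
    stop("measurement table needs `measured_87_86` or `ratio`")
  df
}

#' @param x data frame of measurements.
#' @rdname read_measurements
#' @export
write_measurements <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}
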