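# Reflectance-spectra processing: instrument-artefact correction at
# 654-659 nm, per-individual averaging of the 10 replicate spectra, and the
# mean-brightness summary over 300-1000 nm.

#' Construct a reflectance spectrum
#'
#' @param individual_id Individual identifier.
#' @param body_part `"dorsal_pronotum"` or `"lateral_lobe"`.
#' @param replicate Replicate index 1-5 within body part.
#' @param reflectance Reflectance in % of the white standard on the fixed
#'   1 nm grid 300-1000 nm (701 values), or on `wavelength` if supplied
#'   (then linearly resampled onto the fixed grid).
#' @param wavelength Optional native wavelength grid (nm).
#' @return A `reflectance_spectrum`: list with `individual_id`, `body_part`,
#'   `replicate`, `wavelength` (300:1000), `reflectance`.
#' @export
reflectance_spectrum <- function(individual_id, body_part, replicate,
                                 reflectance, wavelength = NULL) {
  body_part <- match.arg(body_part, BODY_PARTS)
  if (!is.null(wavelength)) {
    if (length(wavelength) != length(reflectance))
      stopf("wavelength and reflectance must have equal length")
    if (min(wavelength) > 300 || max(wavelength) < 1000)
      stopf("native grid must cover 300-1000 nm")
    reflectance <- approx(wavelength, reflectance, xout = WL_GRID)$y
  }
  if (length(reflectance) != length(WL_GRID))
    stopf("reflectance must have %d samples (300-1000 nm at 1 nm)",
          length(WL_GRID))
  if (any(!is.finite(reflectance))) stopf("reflectance must be finite")
  if (any(reflectance < 0)) stopf("reflectance must be >= 0")
  structure(list(individual_id = as.character(individual_id),
                 body_part = body_part, replicate = as.integer(replicate),
                 wavelength = WL_GRID,
                 reflectance = as.numeric(reflectance)),
            class = "reflectance_spectrum")
}

#' Remove the spectrometer artefact at 654-659 nm
#'
#' The instrument shows a spurious narrow reflectance peak between 654 and
#' 659 nm. Samples at 655-658 nm are replaced by the scalar mean of the
#' flanking samples at 650-654 and 659-664 nm (654 and 659 count as flank);
#' no other sample changes, so the operation is idempotent.
#'
#' @param spectrum A [reflectance_spectrum()].
#' @return The corrected `reflectance_spectrum`.
#' @export
correct_artefact <- function(spectrum) {
  stopifnot(inherits(spectrum, "reflectance_spectrum"))
  wl <- spectrum$wavelength
  if (min(wl) > 650 || max(wl) < 664)
    stopf("spectrum grid must cover 650-664 nm")
  flank <- (wl >= 650 & wl <= 654) | (wl >= 659 & wl <= 664)
  target <- wl >= 655 & wl <= 658
  spectrum$reflectance[target] <- mean(spectrum$reflectance[flank])
  spectrum
}

#' Average replicate spectra of one individual
#'
#' Pointwise arithmetic mean across the replicates of both body parts
#' (implicitly weighting parts by replicate count, 5 + 5).
#'
#' @param spectra Non-empty list of [reflectance_spectrum()] objects sharing
#'   one individual id.
#' @return A `reflectance_spectrum` with `body_part` left as the first
#'   input's and `replicate = NA`, carrying attribute `n_spectra`.
#' @export
aggregate_spectra <- function(spectra) {
  if (!length(spectra)) stopf("cannot aggregate an empty list of spectra")
  ids <- unique(vapply(spectra, `[[`, "", "individual_id"))
  if (length(ids) != 1L)
    stopf("spectra from multiple individuals: %s", paste(ids, collapse = ", "))
  m <- vapply(spectra, `[[`, numeric(length(WL_GRID)), "reflectance")
  out <- reflectance_spectrum(ids, spectra[[1L]]$body_part, NA_integer_,
                              rowMeans(m))
  attr(out, "n_spectra") <- length(spectra)
  out
}

#' Mean brightness of a spectrum
#'
#' Arithmetic mean of reflectance over the entire 300-1000 nm range (all
#' 701 grid points), in % of the white standard.
#'
#' @param spectrum A [reflectance_spectrum()].
#' @return Mean brightness (%).
#' @export
mean_brightness <- function(spectrum) {
  stopifnot(inherits(spectrum, "reflectance_spectrum"))
  if (any(!is.finite(spectrum$reflectance)))
    stopf("reflectance must be finite")
  mean(spectrum$reflectance)
}

#' Process all spectra of a cohort
#'
#' Artefact-corrects every raw spectrum, averages the 10 replicates per
#' individual, and summarises mean brightness.
#'
#' @param spectra Named list (by individual id) of lists of raw
#'   [reflectance_spectrum()] objects — e.g. `cohort$spectra`.
#' @return List with `mean_spectra` (named list of averaged spectra) and
#'   `brightness` (data.frame: `individual_id`, `brightness_pct`,
#'   `n_spectra_used`).
#' @export
process_spectra <- function(spectra) {
  mean_spectra <- lapply(spectra, function(sl)
    aggregate_spectra(lapply(sl, correct_artefact)))
  brightness <- data.frame(
    individual_id = names(mean_spectra),
    brightness_pct = vapply(mean_spectra, mean_brightness, 0),
    n_spectra_used = vapply(mean_spectra, function(s)
      attr(s, "n_spectra"), 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(mean_spectra = mean_spectra, brightness = brightness)
}
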