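#' Deconvoluted spectrum
#'
#' A deconvoluted MS/MS spectrum: a spectrum id, an optional precursor neutral
#' monoisotopic mass, and a peak list of neutral monoisotopic masses with
#' intensities. Peaks are sorted by ascending mass on construction; masses
#' must be strictly positive and intensities non-negative.
#'
#' @param id Spectrum id, a non-empty string, unique within a dataset.
#' @param masses Numeric vector of neutral monoisotopic peak masses (Da).
#' @param intensities Numeric vector of peak intensities (default all 1).
#' @param precursor_mass Precursor neutral monoisotopic mass in Da, or `NA`
#'   if unknown.
#' @param extra Named character vector of additional header key/value pairs
#'   (preserved on msalign round trip).
#' @return An object of class `deconv_spectrum`: a list with elements `id`,
#'   `precursor_mass`, `peaks` (data frame with columns `mass`, `intensity`)
#'   and `extra`.
#' @examples
#' deconv_spectrum("sp1", c(200.1, 100.05), c(3, 7), precursor_mass = 450.2)
#' @export
deconv_spectrum <- function(id, masses, intensities = rep(1, length(masses)),
                            precursor_mass = NA_real_, extra = character()) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("`id` must be a single non-empty string", call. = FALSE)
  }
  masses <- as.numeric(masses)
  intensities <- as.numeric(intensities)
  if (length(masses) != length(intensities)) {
    stop("`masses` and `intensities` must have equal length", call. = FALSE)
  }
  if (anyNA(masses) || any(masses <= 0)) {
    stop("peak masses must be strictly positive", call. = FALSE)
  }
  if (anyNA(intensities) || any(intensities < 0)) {
    stop("peak intensities must be non-negative", call. = FALSE)
  }
  precursor_mass <- as.numeric(precursor_mass)
  stopifnot(length(precursor_mass) == 1L)
  o <- order(masses)
  structure(
    list(id = id, precursor_mass = precursor_mass,
         peaks = data.frame(mass = masses[o], intensity = intensities[o]),
         extra = extra),
    class = "deconv_spectrum"
  )
}

#' @export
print.deconv_spectrum <- function(x, ...) {
  cat(sprintf("<deconv_spectrum> id=%s, %d peaks, precursor=%s Da\n",
              x$id, nrow(x$peaks),
              if (is.na(x$precursor_mass)) "NA" else
                format(x$precursor_mass, nsmall = 4)))
  invisible(x)
}

#' Peak table of a spectrum
#'
#' @param spectrum A [deconv_spectrum()].
#' @return Data frame with columns `mass` and `intensity`, sorted by mass.
#' @export
peak_table <- function(spectrum) {
  stopifnot(inherits(spectrum, "deconv_spectrum"))
  spectrum$peaks
}

# Internal: rebuild a spectrum with new peaks, keeping id/precursor/extra.
.with_peaks <- function(spectrum, masses, intensities) {
  deconv_spectrum(spectrum$id, masses, intensities,
                  precursor_mass = spectrum$precursor_mass,
                  extra = spectrum$extra)
}

.check_unique_ids <- function(spectra) {
  ids <- vapply(spectra, `[[`, character(1), "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate spectrum id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  ids
}
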