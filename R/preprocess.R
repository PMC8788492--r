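# Peak-list preprocessing applied before tag generation: reflection against
# the precursor mass (so that b- and y-type ladders reinforce each other),
# merging of nearby peaks, and optional water-loss peak removal.

#' Reflect peaks against the precursor mass
#'
#' Adds, for every peak at mass m, a reflected peak at `M - m` with the same
#' intensity, where `M` is the precursor neutral mass. Because
#' `b_i + y_(n-i) = M` for complementary fragments, reflection superimposes
#' the y-ion ladder onto b-ion coordinates (and vice versa). Reflected masses
#' that are not strictly positive are dropped.
#'
#' @param spectrum A [deconv_spectrum()] with a known precursor mass.
#' @return The spectrum with original plus reflected peaks.
#' @export
reflect_peaks <- function(spectrum) {
  stopifnot(inherits(spectrum, "deconv_spectrum"))
  M <- spectrum$precursor_mass
  if (is.na(M)) {
    stop("cannot reflect peaks: spectrum '", spectrum$id,
         "' has no precursor mass", call. = FALSE)
  }
  m <- spectrum$peaks$mass
  int <- spectrum$peaks$intensity
  refl <- M - m
  keep <- refl > 0
  .with_peaks(spectrum, c(m, refl[keep]), c(int, int[keep]))
}

#' Merge nearby peaks
#'
#' Single-linkage clustering of the sorted peak list: consecutive peaks
#' closer than `tol` chain into one cluster, which is replaced by a single
#' peak at the intensity-weighted mean mass with the summed intensity.
#'
#' @param spectrum A [deconv_spectrum()].
#' @param tol Merge tolerance in Da (> 0); defaults to the 4 mDa tag
#'   tolerance.
#' @return The spectrum with merged peaks.
#' @export
merge_peaks <- function(spectrum, tol = 0.004) {
  stopifnot(inherits(spectrum, "deconv_spectrum"), tol > 0)
  m <- spectrum$peaks$mass
  if (length(m) < 2L) return(spectrum)
  int <- spectrum$peaks$intensity
  grp <- cumsum(c(1L, as.integer(diff(m) > tol)))
  w <- int
  # zero-intensity clusters fall back to the unweighted mean
  wsum <- as.numeric(tapply(w, grp, sum))
  mm <- ifelse(wsum > 0,
               as.numeric(tapply(m * w, grp, sum)) / wsum,
               as.numeric(tapply(m, grp, mean)))
  .with_peaks(spectrum, mm, as.numeric(tapply(int, grp, sum)))
}

#' Remove water-loss peaks
#'
#' Removes every peak whose mass lies 18.010565 Da (one water) below a
#' strictly more intense peak, within `tol`. Removal decisions are taken
#' against the original peak list, not cascaded.
#'
#' @param spectrum A [deconv_spectrum()].
#' @param tol Mass matching tolerance in Da (> 0).
#' @return The spectrum without water-loss peaks.
#' @export
remove_water_loss <- function(spectrum, tol = 0.02) {
  stopifnot(inherits(spectrum, "deconv_spectrum"), tol > 0)
  m <- spectrum$peaks$mass
  int <- spectrum$peaks$intensity
  if (length(m) < 2L) return(spectrum)
  drop <- vapply(seq_along(m), function(i) {
    hit <- abs(m - (m[i] + .WATER)) <= tol & int > int[i]
    any(hit)
  }, logical(1))
  .with_peaks(spectrum, m[!drop], int[!drop])
}

#' Preprocess one spectrum for tag generation
#'
#' Applies, in order: peak reflection (if enabled and a precursor mass is
#' known; otherwise skipped with a warning), water-loss removal (if enabled)
#' and merging of nearby peaks.
#'
#' @param spectrum A [deconv_spectrum()].
#' @param reflect Reflect peaks against the precursor mass?
#' @param water_loss Remove water-loss peaks?
#' @param merge_tol Merge tolerance in Da; `NULL` skips merging.
#' @param water_tol Water-loss matching tolerance in Da.
#' @return The preprocessed spectrum.
#' @export
preprocess_spectrum <- function(spectrum, reflect = TRUE, water_loss = FALSE,
                                merge_tol = 0.004, water_tol = 0.02) {
  if (reflect) {
    if (is.na(spectrum$precursor_mass)) {
      warning("spectrum '", spectrum$id,
              "' has no precursor mass; reflection skipped", call. = FALSE)
    } else {
      spectrum <- reflect_peaks(spectrum)
    }
  }
  if (water_loss) spectrum <- remove_water_loss(spectrum, water_tol)
  if (!is.null(merge_tol)) spectrum <- merge_peaks(spectrum, merge_tol)
  spectrum
}
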