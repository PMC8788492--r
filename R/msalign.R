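# msalign dialect as emitted by MS-Deconv: BEGIN IONS / END IONS blocks with
# KEY=VALUE headers (ID, SCANS, PRECURSOR_MASS, ...) followed by
# mass <tab> intensity [<tab> charge] lines. Masses are already neutral
# monoisotopic, so the charge column is ignored after parsing.

#' Read deconvoluted spectra from an msalign file
#'
#' Parses the MS-Deconv msalign dialect: `BEGIN IONS`/`END IONS` blocks with
#' `ID=` and optional `PRECURSOR_MASS=` headers followed by
#' mass/intensity(/charge) peak lines. Unknown header keys are preserved and
#' written back by [write_msalign()]. Spectrum ids must be unique within the
#' file.
#'
#' @param path Path to an msalign file.
#' @return List of [deconv_spectrum()] objects (empty list for an empty file).
#' @seealso [write_msalign()], [read_peaks_tsv()]
#' @export
read_msalign <- function(path) {
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) { i <- i + 1L; next }
    if (line != "BEGIN IONS") {
      stop(sprintf("%s:%d: expected 'BEGIN IONS', got '%s'", path, i, line),
           call. = FALSE)
    }
    begin_line <- i
    i <- i + 1L
    headers <- character()
    masses <- numeric()
    intens <- numeric()
    closed <- FALSE
    while (i <= n) {
      line <- trimws(lines[[i]])
      if (line == "END IONS") { closed <- TRUE; i <- i + 1L; break }
      if (!nzchar(line)) { i <- i + 1L; next }
      if (grepl("=", line, fixed = TRUE) && !grepl("^[0-9.+-]", line)) {
        key <- sub("=.*$", "", line)
        headers[key] <- sub("^[^=]*=", "", line)
      } else {
        fields <- strsplit(line, "[\t ]+")[[1L]]
        if (length(fields) < 2L) {
          stop(sprintf("%s:%d: malformed peak line '%s'", path, i, line),
               call. = FALSE)
        }
        mz <- suppressWarnings(as.numeric(fields[1:2]))
        if (anyNA(mz)) {
          stop(sprintf("%s:%d: non-numeric mass or intensity in '%s'",
                       path, i, line), call. = FALSE)
        }
        masses <- c(masses, mz[1L])
        intens <- c(intens, mz[2L])
      }
      i <- i + 1L
    }
    if (!closed) {
      stop(sprintf("%s:%d: block opened here has no END IONS", path,
                   begin_line), call. = FALSE)
    }
    if (!"ID" %in% names(headers)) {
      stop(sprintf("%s:%d: block has no ID header", path, begin_line),
           call. = FALSE)
    }
    prec <- if ("PRECURSOR_MASS" %in% names(headers)) {
      p <- suppressWarnings(as.numeric(headers[["PRECURSOR_MASS"]]))
      if (is.na(p)) {
        stop(sprintf("%s:%d: non-numeric PRECURSOR_MASS", path, begin_line),
             call. = FALSE)
      }
      p
    } else NA_real_
    extra <- headers[setdiff(names(headers), c("ID", "PRECURSOR_MASS"))]
    spectra[[length(spectra) + 1L]] <-
      deconv_spectrum(headers[["ID"]], masses, intens,
                      precursor_mass = prec, extra = extra)
  }
  .check_unique_ids(spectra)
  spectra
}

#' Write deconvoluted spectra to an msalign file
#'
#' Inverse of [read_msalign()]: `read_msalign(write_msalign(S, f))`
#' reproduces `S` up to the 1e-6 Da/intensity formatting precision.
#'
#' @param spectra List of [deconv_spectrum()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_msalign <- function(spectra, path) {
  if (inherits(spectra, "deconv_spectrum")) spectra <- list(spectra)
  .check_unique_ids(spectra)
  out <- unlist(lapply(spectra, function(sp) {
    hdr <- c(sprintf("ID=%s", sp$id),
             if (length(sp$extra))
               sprintf("%s=%s", names(sp$extra), unname(sp$extra)),
             if (!is.na(sp$precursor_mass))
               sprintf("PRECURSOR_MASS=%.6f", sp$precursor_mass))
    pk <- sprintf("%.6f\t%.6f\t1", sp$peaks$mass, sp$peaks$intensity)
    c("BEGIN IONS", hdr, pk, "END IONS", "")
  }))
  writeLines(as.character(out), path)
  invisible(path)
}

#' Read a single spectrum from a plain two-column peak list
#'
#' Fallback plain-TSV peak-list format: optional `# KEY=VALUE` header lines
#' (`# PRECURSOR_MASS=...` and `# ID=...` are honoured), then one
#' mass/intensity pair per line.
#'
#' @param path Path to the TSV file.
#' @param id Spectrum id; defaults to the `# ID=` header or the file name
#'   without extension.
#' @return A [deconv_spectrum()].
#' @export
read_peaks_tsv <- function(path, id = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_hdr <- startsWith(trimws(lines), "#")
  headers <- character()
  for (h in trimws(lines[is_hdr])) {
    h <- trimws(sub("^#+", "", h))
    if (grepl("=", h, fixed = TRUE)) {
      headers[sub("=.*$", "", h)] <- trimws(sub("^[^=]*=", "", h))
    }
  }
  if (is.null(id)) {
    id <- if ("ID" %in% names(headers)) headers[["ID"]] else
      tools::file_path_sans_ext(basename(path))
  }
  prec <- if ("PRECURSOR_MASS" %in% names(headers)) {
    as.numeric(headers[["PRECURSOR_MASS"]])
  } else NA_real_
  body <- lines[!is_hdr]
  if (!length(body)) {
    return(deconv_spectrum(id, numeric(), numeric(), precursor_mass = prec))
  }
  fields <- do.call(rbind, strsplit(trimws(body), "[\t ]+"))
  if (ncol(fields) < 2L) {
    stop(path, ": expected two columns (mass, intensity)", call. = FALSE)
  }
  m <- suppressWarnings(as.numeric(fields[, 1L]))
  int <- suppressWarnings(as.numeric(fields[, 2L]))
  if (anyNA(m) || anyNA(int)) {
    stop(path, ": non-numeric mass or intensity", call. = FALSE)
  }
  deconv_spectrum(id, m, int, precursor_mass = prec)
}
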