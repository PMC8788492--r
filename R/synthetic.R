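# Synthetic fixture generation: theoretical b-/y-ion spectra, the toy
# four-spectrum dataset, and a seeded simulator that plants true peptides
# with decoy candidates for end-to-end testing with known ground truth.

#' Theoretical fragment spectrum of a peptide
#'
#' Emits neutral monoisotopic fragment masses: b fragments are prefix
#' residue sums, y fragments are suffix residue sums plus one water, and the
#' precursor is the full residue sum plus one water. Fragment index ranges
#' may be restricted to emulate partial ladders; index `n` (the full-length
#' species: the dehydrated precursor for b, the intact precursor for y) is
#' allowed.
#'
#' @param peptide Amino-acid string.
#' @param series Ion series to emit, a subset of `c("b", "y")`.
#' @param b_range,y_range Integer vectors of fragment indices to emit
#'   (default `1:(n-1)`, i.e. the full conventional ladder).
#' @param id Spectrum id.
#' @param intensity Peak intensity given to every fragment.
#' @param table Residue mass table.
#' @return A [deconv_spectrum()] with the precursor neutral mass set.
#' @export
theoretical_spectrum <- function(peptide, series = c("b", "y"),
                                 b_range = NULL, y_range = NULL,
                                 id = peptide, intensity = 1,
                                 table = residue_mass_table()) {
  series <- match.arg(series, several.ok = TRUE)
  chars <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (!n) stop("peptide must be non-empty", call. = FALSE)
  rm <- unname(table[chars])
  if (anyNA(rm)) {
    bad <- which(is.na(rm))[1L]
    stop(sprintf("unknown residue '%s' at position %d of \"%s\"",
                 chars[bad], bad, peptide), call. = FALSE)
  }
  masses <- numeric()
  if ("b" %in% series && n > 1L) {
    if (is.null(b_range)) b_range <- seq_len(n - 1L)
    stopifnot(all(b_range >= 1L & b_range <= n))
    masses <- c(masses, cumsum(rm)[b_range])
  }
  if ("y" %in% series && n > 1L) {
    if (is.null(y_range)) y_range <- seq_len(n - 1L)
    stopifnot(all(y_range >= 1L & y_range <= n))
    masses <- c(masses, cumsum(rev(rm))[y_range] + .WATER)
  }
  deconv_spectrum(id, masses, rep(intensity, length(masses)),
                  precursor_mass = sum(rm) + .WATER)
}

#' The toy four-spectrum dataset
#'
#' Four theoretical spectra over the toy protein `AVTDPVLSGNATSMPGST`,
#' constructed so that tag generation at `k = 3`, `eps = 4` mDa recovers
#' exactly six 3-tags: `DPV` and `PVL` from a b-ion ladder (peaks b3..b7),
#' `SMP` from b12..b15, and the y-ion tags `STA` (y5..y8), `GSL` (y9..y12)
#' and `VPD` (y12..y15). The partial ladders are distributed over the four
#' spectra so that no two ladders share a peak or connect through an
#' accidental residue-mass gap, keeping each in its own graph component.
#'
#' @param table Residue mass table.
#' @return List with `spectra` (four [deconv_spectrum()]s), `tags` (data
#'   frame of the six expected tags with their theoretical offsets and
#'   source spectrum ids) and `protein` (the toy sequence).
#' @export
toy_dataset <- function(table = residue_mass_table()) {
  prot <- "AVTDPVLSGNATSMPGST"
  rm <- unname(table[strsplit(prot, "", fixed = TRUE)[[1L]]])
  b <- cumsum(rm)
  y <- cumsum(rev(rm)) + .WATER
  spectra <- list(
    theoretical_spectrum(prot, "b", b_range = 3:7, id = "toy1", table = table),
    theoretical_spectrum(prot, c("b", "y"), b_range = 12:15, y_range = 5:8,
                         id = "toy2", table = table),
    theoretical_spectrum(prot, "y", y_range = 9:12, id = "toy3",
                         table = table),
    theoretical_spectrum(prot, "y", y_range = 12:15, id = "toy4",
                         table = table)
  )
  tags <- data.frame(
    tag = c("DPV", "PVL", "SMP", "STA", "GSL", "VPD"),
    offset = c(b[3L], b[4L], b[12L], y[5L], y[9L], y[12L]),
    spectrum_id = c("toy1", "toy1", "toy2", "toy2", "toy3", "toy4"),
    series = c("b", "b", "b", "y", "y", "y"))
  list(spectra = spectra, tags = tags, protein = prot)
}

#' Specification of a simulated dataset
#'
#' Describes the study conditions emulated by [simulate_dataset()]: a source
#' protein is cut into overlapping peptides; each peptide yields one
#' b-series and one y-series spectrum with complete noiseless ladders
#' (including the full-length b_n / y_n species) at uniform signal
#' intensity, optionally with low-intensity noise peaks; and each peptide's
#' candidate list contains the true sequence first, followed by decoys
#' (isobaric I/L swaps, shuffled interiors, large-mass substitutions).
#'
#' @param protein Source protein sequence.
#' @param peptide_length Length of the overlapping peptide windows.
#' @param step Offset between consecutive windows.
#' @param n_noise Number of uniform noise peaks added per spectrum.
#' @param signal_intensity Intensity of every ladder peak.
#' @param noise_intensity Range (length 2) of noise peak intensities; must
#'   stay below `signal_intensity` so planted ladders remain optimal.
#' @param n_decoys Decoys generated per true peptide.
#' @param seed Random seed; identical seeds give identical datasets.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(protein = "AVTDPVLSGNATSMPGSTLKEIFDRHNQWYVEAMGLSTPK",
                           peptide_length = 12, step = 4,
                           n_noise = 0, signal_intensity = 100,
                           noise_intensity = c(1, 10),
                           n_decoys = 3, seed = 1) {
  stopifnot(peptide_length >= 8, step >= 1,
            nchar(protein) >= peptide_length,
            n_noise >= 0, n_decoys >= 0,
            max(noise_intensity) < signal_intensity)
  structure(list(protein = protein, peptide_length = peptide_length,
                 step = step, n_noise = n_noise,
                 signal_intensity = signal_intensity,
                 noise_intensity = noise_intensity,
                 n_decoys = n_decoys, seed = seed),
            class = "synthetic_spec")
}

# Decoy constructors. Each returns a single mutated copy of `pep` or NA if
# the kind is not applicable.
.decoy_il_swap <- function(pep, n_swaps) {
  chars <- strsplit(pep, "", fixed = TRUE)[[1L]]
  il <- which(chars %in% c("I", "L"))
  if (!length(il)) return(NA_character_)
  n_pick <- min(n_swaps, length(il))
  pick <- if (length(il) == 1L) il else sample(il, n_pick)
  chars[pick] <- ifelse(chars[pick] == "L", "I", "L")
  paste(chars, collapse = "")
}

.decoy_shuffle <- function(pep) {
  chars <- strsplit(pep, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  interior <- seq.int(2L, n - 1L)
  for (attempt in 1:50) {
    perm <- sample(interior)
    cand <- chars
    cand[interior] <- chars[perm]
    if (sum(cand != chars) >= 3L) return(paste(cand, collapse = ""))
  }
  NA_character_
}

.decoy_substitute <- function(pep, table, n_subs) {
  chars <- strsplit(pep, "", fixed = TRUE)[[1L]]
  pos <- sample(seq_along(chars), n_subs)
  for (g in pos) {
    far <- names(table)[abs(table - table[[chars[g]]]) > 10 &
                          names(table) != chars[g]]
    chars[g] <- sample(far, 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate a dataset with planted peptides and decoy candidates
#'
#' Generates, per peptide window of the source protein, one b-series and one
#' y-series theoretical spectrum (complete ladders including the
#' full-length species, so every k-mer of the peptide is covered by a tag)
#' plus optional noise peaks, and a per-spectrum candidate list holding the
#' true sequence at rank 1 followed by decoys. Identical seeds reproduce
#' identical datasets, and written files are byte-identical across reruns.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional directory; when given, `spectra.msalign` and
#'   `candidates.txt` (simple list format) are written into
#'   `dir/spectra/` and `dir/sequences/`.
#' @param table Residue mass table.
#' @return List with `spectra` (list of [deconv_spectrum()]), `candidates`
#'   (data frame `spectrum_id`, `sequence`), `truth` (same plus `is_true`
#'   and `kind`), `spec`, and (if `dir` was given) `paths`.
#' @export
simulate_dataset <- function(spec = synthetic_spec(), dir = NULL,
                             table = residue_mass_table()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n_prot <- nchar(spec$protein)
  starts <- seq(1L, n_prot - spec$peptide_length + 1L, by = spec$step)
  spectra <- list()
  truth <- list()
  for (w in seq_along(starts)) {
    pep <- substr(spec$protein, starts[w], starts[w] + spec$peptide_length - 1L)
    np <- nchar(pep)
    bid <- sprintf("pep%02d_b", w)
    yid <- sprintf("pep%02d_y", w)
    spb <- theoretical_spectrum(pep, "b", b_range = seq_len(np), id = bid,
                                intensity = spec$signal_intensity,
                                table = table)
    spy <- theoretical_spectrum(pep, "y", y_range = seq_len(np), id = yid,
                                intensity = spec$signal_intensity,
                                table = table)
    if (spec$n_noise > 0) {
      add_noise <- function(sp) {
        nm <- stats::runif(spec$n_noise, 60, sp$precursor_mass - 1)
        ni <- stats::runif(spec$n_noise, spec$noise_intensity[1L],
                           spec$noise_intensity[2L])
        .with_peaks(sp, c(sp$peaks$mass, nm), c(sp$peaks$intensity, ni))
      }
      spb <- add_noise(spb)
      spy <- add_noise(spy)
    }
    spectra <- c(spectra, list(spb, spy))

    cand <- data.frame(spectrum_id = bid, sequence = pep,
                       is_true = TRUE, kind = "true")
    kinds <- rep(c("il_swap", "shuffle", "substitute"),
                 length.out = spec$n_decoys)
    for (kind in kinds) {
      dec <- switch(kind,
                    il_swap = .decoy_il_swap(pep, sample(1:2, 1L)),
                    shuffle = .decoy_shuffle(pep),
                    substitute = .decoy_substitute(pep, table,
                                                   sample(1:2, 1L)))
      if (is.na(dec) || dec == pep || dec %in% cand$sequence) next
      cand <- rbind(cand, data.frame(spectrum_id = bid, sequence = dec,
                                     is_true = FALSE, kind = kind))
    }
    truth[[w]] <- cand
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  out <- list(spectra = spectra,
              candidates = truth[c("spectrum_id", "sequence")],
              truth = truth, spec = spec)
  if (!is.null(dir)) {
    spectra_dir <- file.path(dir, "spectra")
    seq_dir <- file.path(dir, "sequences")
    dir.create(spectra_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(seq_dir, recursive = TRUE, showWarnings = FALSE)
    write_msalign(spectra, file.path(spectra_dir, "spectra.msalign"))
    write_candidates(out$candidates, file.path(seq_dir, "candidates.txt"))
    out$paths <- c(spectra = file.path(spectra_dir, "spectra.msalign"),
                   sequences = file.path(seq_dir, "candidates.txt"))
  }
  out
}
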