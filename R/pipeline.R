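# Pipeline orchestration mirroring the standalone validation tool: a
# spectra directory and a sequences directory in, per-file .valid.txt /
# .scores.txt out.

#' Pipeline run configuration
#'
#' Bundles and checks the tunable parameters of the validation pipeline.
#' Defaults: `k = 3`, tag tolerance `eps = 4` mDa, validation matching
#' tolerance 0.02 Da, middle-tag-score threshold `h = 1`, window bound
#' `L = 25`, peak reflection on, water-loss elimination off.
#'
#' @param k Tag length (>= 1).
#' @param eps Tag-generation tolerance in Da (> 0).
#' @param tol Validation mass matching tolerance in Da (> 0).
#' @param h Middle-tag-score threshold (>= 0).
#' @param L Window bound on flanking substrings (>= k).
#' @param reflect Reflect peaks against the precursor mass?
#' @param water_loss Remove water-loss peaks?
#' @param merge_tol Peak merge tolerance in Da (`NULL` to skip merging).
#' @param fixed_mods Fixed modifications, see [residue_mass_table()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(k = 3, eps = 0.004, tol = 0.02, h = 1, L = 25,
                       reflect = TRUE, water_loss = FALSE,
                       merge_tol = eps, fixed_mods = c(C = 57.02146)) {
  stopifnot(k >= 1, eps > 0, tol > 0, h >= 0, L >= k,
            is.logical(reflect), is.logical(water_loss),
            is.null(merge_tol) || merge_tol > 0)
  structure(list(k = as.integer(k), eps = eps, tol = tol, h = h, L = L,
                 reflect = reflect, water_loss = water_loss,
                 merge_tol = merge_tol,
                 table = residue_mass_table(fixed_mods)),
            class = "run_config")
}

# Read every parseable spectra file in a directory (.msalign/.txt parsed as
# msalign blocks, .tsv as a single plain peak list). Per-file failures are
# collected; the run continues while at least one file parses.
.read_spectra_dir <- function(spectra_dir) {
  files <- list.files(spectra_dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) {
    stop("no spectra files found in ", spectra_dir, call. = FALSE)
  }
  spectra <- list()
  failures <- character()
  for (f in files) {
    res <- tryCatch({
      if (grepl("\\.tsv$", f, ignore.case = TRUE)) {
        list(read_peaks_tsv(f))
      } else {
        read_msalign(f)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("skipping ", f, ": ", conditionMessage(res), call. = FALSE)
      failures <- c(failures, f)
    } else {
      spectra <- c(spectra, res)
    }
  }
  if (!length(spectra)) {
    stop("all spectra files in ", spectra_dir, " failed to parse",
         call. = FALSE)
  }
  .check_unique_ids(spectra)
  spectra
}

# Preprocess + tag generation for a directory of spectra.
.tags_from_dir <- function(spectra_dir, config, verbose = FALSE) {
  spectra <- .read_spectra_dir(spectra_dir)
  spectra <- lapply(spectra, preprocess_spectrum, reflect = config$reflect,
                    water_loss = config$water_loss,
                    merge_tol = config$merge_tol, water_tol = config$tol)
  generate_tags(spectra, k = config$k, eps = config$eps,
                table = config$table, verbose = verbose)
}

#' Run the end-to-end validation pipeline
#'
#' Reads every spectra file from `spectra_dir`, preprocesses the spectra
#' and generates the tag set, then validates each candidate file in
#' `seq_dir` and writes, next to it in `out_dir`, the retained sequences
#' (`<name>.valid.txt`) and their tag/k-mer score rows
#' (`<name>.scores.txt`). Identical inputs and configuration yield
#' byte-identical outputs.
#'
#' @param spectra_dir Directory of deconvoluted spectra files.
#' @param seq_dir Directory of candidate sequence files.
#' @param out_dir Output directory (default `seq_dir`).
#' @param config A [run_config()].
#' @param verbose Log stage counts with `message()`?
#' @return Invisibly, a list with the tag index and, per sequence file, the
#'   validation summary (stage counts).
#' @export
run_validation <- function(spectra_dir, seq_dir, out_dir = seq_dir,
                           config = run_config(), verbose = TRUE) {
  if (!dir.exists(spectra_dir)) {
    stop("spectra directory not found: ", spectra_dir, call. = FALSE)
  }
  if (!dir.exists(seq_dir)) {
    stop("sequences directory not found: ", seq_dir, call. = FALSE)
  }
  seq_files <- list.files(seq_dir, pattern = "\\.txt$", full.names = TRUE)
  seq_files <- seq_files[!grepl("\\.(valid|scores)\\.txt$", seq_files)]
  if (!length(seq_files)) {
    stop("no candidate .txt files found in ", seq_dir, call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  index <- .tags_from_dir(spectra_dir, config, verbose = verbose)
  if (verbose) {
    message(sprintf("generated %d %d-tags", nrow(index), config$k))
  }

  summaries <- list()
  n_failed <- 0L
  for (f in seq_files) {
    res <- tryCatch({
      cand <- read_candidates(f)
      val <- validate_candidates(cand, index, k = config$k, L = config$L,
                                 tol = config$tol, h = config$h,
                                 table = config$table)
      base <- tools::file_path_sans_ext(basename(f))
      write_validation_outputs(
        val,
        file.path(out_dir, paste0(base, ".valid.txt")),
        file.path(out_dir, paste0(base, ".scores.txt")))
      if (verbose) {
        s <- val$summary
        message(sprintf(
          paste0("%s: %d candidates (%d unscorable); length>%d: %d, ",
                 "all-positive %d, retained upon filtration %d; ",
                 "length-%d: %d, middle score >= %g: %d; final %d"),
          basename(f), s[["total"]], s[["unscorable"]], 2 * config$k + 1,
          s[["long_total"]], s[["all_positive"]], s[["align_retained"]],
          2 * config$k + 1, s[["middle_total"]], config$h,
          s[["middle_pass"]], s[["final"]]))
      }
      val$summary
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("validation failed for ", f, ": ", conditionMessage(res),
              call. = FALSE)
      n_failed <- n_failed + 1L
    } else {
      summaries[[basename(f)]] <- res
    }
  }
  if (n_failed == length(seq_files)) {
    stop("validation failed for every candidate file in ", seq_dir,
         call. = FALSE)
  }
  invisible(list(index = index, summaries = summaries))
}

#' Generate and export the tag table of a spectra directory
#'
#' @param spectra_dir Directory of deconvoluted spectra files.
#' @param out_file Optional TSV output path (columns `spectrum_id`, `tag`,
#'   `offset`).
#' @param config A [run_config()].
#' @return The [tag_index()], invisibly if `out_file` is given.
#' @export
run_tags <- function(spectra_dir, out_file = NULL, config = run_config()) {
  if (!dir.exists(spectra_dir)) {
    stop("spectra directory not found: ", spectra_dir, call. = FALSE)
  }
  index <- .tags_from_dir(spectra_dir, config)
  if (is.null(out_file)) return(index)
  utils::write.table(
    data.frame(spectrum_id = index$spectrum_id, tag = index$tag,
               offset = sprintf("%.6f", index$offset)),
    out_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(index)
}

#' Tag convolution of two strings against a spectra directory
#'
#' Generates tags from `spectra_dir` and prints/returns the string-level
#' tag convolution `T(s1, s2)`, sorted by decreasing multiplicity.
#'
#' @param spectra_dir Directory of deconvoluted spectra files.
#' @param s1,s2 Amino-acid strings of length >= k.
#' @param config A [run_config()].
#' @return The [mass_convolution()], with rows ordered by decreasing
#'   multiplicity.
#' @export
run_convolution <- function(spectra_dir, s1, s2, config = run_config()) {
  if (nchar(s1) < config$k || nchar(s2) < config$k) {
    stop("both strings must have length >= k = ", config$k, call. = FALSE)
  }
  index <- .tags_from_dir(spectra_dir, config)
  conv <- string_convolution(index, s1, s2, k = config$k, tol = config$tol,
                             table = config$table)
  conv[order(-conv$mult, conv$diff), , drop = FALSE]
}
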