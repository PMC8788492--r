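# Candidate sequence IO: the simple list format (a '>spectrum id' line
# followed by one candidate per line) and a tolerant reader for
# PepNovo+-style result listings, plus the .valid.txt / .scores.txt output
# writers.

#' Read candidate sequences
#'
#' Two formats are supported. The simple list format has a `>spectrum_id`
#' line followed by one candidate sequence per line. PepNovo+-style
#' listings have `>> ...` spectrum header lines (the last whitespace token
#' is taken as the spectrum id) followed by ranked rows whose final
#' tab/space-separated field is the sequence; `#` comment lines are
#' skipped. With `format = "auto"` the format is chosen from the first
#' non-blank line.
#'
#' @param path Path to the candidate file.
#' @param format One of "auto", "simple", "pepnovo".
#' @return Data frame with columns `spectrum_id` and `sequence`, in file
#'   order (the order is meaningful: it breaks ties during elimination).
#' @export
read_candidates <- function(path, format = c("auto", "simple", "pepnovo")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  nonblank <- trimws(lines[nzchar(trimws(lines))])
  if (format == "auto") {
    if (!length(nonblank)) {
      return(data.frame(spectrum_id = character(), sequence = character()))
    }
    format <- if (startsWith(nonblank[1L], ">>")) "pepnovo"
      else if (startsWith(nonblank[1L], ">")) "simple"
      else stop(path, ": cannot determine candidate format ",
                "(expected a '>' or '>>' header line)", call. = FALSE)
  }
  sid <- NA_character_
  out_id <- character()
  out_seq <- character()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (format == "pepnovo" && startsWith(line, ">>")) {
      toks <- strsplit(trimws(sub("^>>", "", line)), "[\t ]+")[[1L]]
      if (!length(toks)) {
        stop(sprintf("%s:%d: empty spectrum header", path, ln), call. = FALSE)
      }
      sid <- toks[length(toks)]
      next
    }
    if (format == "simple" && startsWith(line, ">")) {
      sid <- trimws(sub("^>", "", line))
      next
    }
    if (is.na(sid)) {
      stop(sprintf("%s:%d: candidate before any spectrum header", path, ln),
           call. = FALSE)
    }
    seqs <- if (format == "simple") {
      line
    } else {
      fields <- strsplit(line, "[\t ]+")[[1L]]
      last <- fields[length(fields)]
      if (!grepl("^[A-Z]+$", last)) next  # tolerate non-sequence rows
      last
    }
    out_id <- c(out_id, sid)
    out_seq <- c(out_seq, seqs)
  }
  data.frame(spectrum_id = out_id, sequence = out_seq)
}

#' Write candidate sequences in the simple list format
#'
#' @param candidates Data frame with columns `spectrum_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  out <- character()
  for (sid in unique(candidates$spectrum_id)) {
    out <- c(out, paste0(">", sid),
             candidates$sequence[candidates$spectrum_id == sid])
  }
  writeLines(out, path)
  invisible(path)
}

# Format a theta vector for the scores file: '-' at undefined positions.
.format_theta <- function(theta) {
  paste(ifelse(is.na(theta), "-",
               format(theta, trim = TRUE, scientific = FALSE)),
        collapse = ",")
}

#' Write validation outputs
#'
#' For a validated candidate set, writes the two per-input-file outputs:
#' `*.valid.txt` lists, per spectrum with at least one retained candidate,
#' the retained sequences (simple list format); `*.scores.txt` lists, per
#' retained sequence, a tab-separated row with the sequence, its
#' comma-separated tag scores (`-` at the undefined first/last k positions)
#' and its comma-separated k-mer scores.
#'
#' @param validation A [validate_candidates()] result.
#' @param valid_path,scores_path Output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_validation_outputs <- function(validation, valid_path, scores_path) {
  ret <- validation$retained
  ids <- vapply(ret, `[[`, character(1), "spectrum_id")
  valid <- character()
  scores <- character()
  for (sid in unique(ids)) {
    valid <- c(valid, paste0(">", sid))
    scores <- c(scores, paste0(">", sid))
    for (x in ret[ids == sid]) {
      valid <- c(valid, x$sequence)
      scores <- c(scores, paste(x$sequence, .format_theta(x$theta),
                                paste(x$kappa, collapse = ","), sep = "\t"))
    }
  }
  writeLines(valid, valid_path)
  writeLines(scores, scores_path)
  invisible(c(valid_path, scores_path))
}
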