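# Per-residue scoring of a candidate sequence: the tag score theta(a_g) is
# the multiplicity of Mass(a_g) in the string convolution of the flanking
# substrings, and the binary k-mer score kappa is raised for every residue
# covered by a k-mer pair that contributed that mass.

#' Tag score of one position of a candidate string
#'
#' Computes `theta(a_g)`: the multiplicity of the residue mass of `a_g` in
#' `T(s_l, s_r)`, where `s_l` and `s_r` are the substrings of `s`
#' immediately left and right of position `g`, truncated to at most `L`
#' residues each. Also returns the k-mer pairs whose tag pairs contributed
#' that mass, with their positions in `s` coordinates (reversed-half k-mers
#' are mapped back to forward coordinates), for k-mer score updating.
#'
#' @param s Candidate amino-acid string.
#' @param g Position, with `k < g <= nchar(s) - k`.
#' @param index A [tag_index()].
#' @param k Tag length; defaults to the index's.
#' @param L Window bound on the flanking substring lengths (>= k).
#' @param tol Mass matching / grouping tolerance in Da.
#' @param table Residue mass table.
#' @return List with elements `theta` (integer multiplicity, 0 if the mass
#'   is absent), `target` (the residue mass matched) and `contributors`
#'   (data frame with one row per contributing tag pair: `w1_start`,
#'   `w1_end`, `w2_start`, `w2_end`, `half`, `diff`).
#' @export
tag_score <- function(s, g, index, k = attr(index, "k"), L = 25,
                      tol = 0.02, table = residue_mass_table()) {
  n <- nchar(s)
  if (!(g > k && g <= n - k)) {
    stop(sprintf("tag score undefined at position %d (need %d < g <= %d)",
                 g, k, n - k), call. = FALSE)
  }
  stopifnot(L >= k)
  lo <- max(1L, g - L)
  hi <- min(n, g + L)
  sl <- substr(s, lo, g - 1L)
  sr <- substr(s, g + 1L, hi)
  p <- nchar(sl)
  q <- nchar(sr)
  target <- string_mass(substr(s, g, g), table)

  pairs <- .string_conv_pairs(index, sl, sr, k, table)
  empty <- data.frame(w1_start = integer(), w1_end = integer(),
                      w2_start = integer(), w2_end = integer(),
                      half = character(), diff = numeric())
  if (!nrow(pairs)) {
    return(list(theta = 0L, target = target, contributors = empty))
  }

  # map k-mer start positions into s coordinates
  is_fwd <- pairs$half == "fwd"
  w1_start <- ifelse(is_fwd, lo + pairs$i - 1L, g + (q - pairs$i - k + 2L))
  w2_start <- ifelse(is_fwd, g + pairs$j, (lo - 1L) + (p - pairs$j - k + 2L))

  grp <- .group_diffs(pairs$diff, rep(1, nrow(pairs)), tol)
  hits <- which(abs(grp$diff - target) <= tol)
  if (!length(hits)) {
    return(list(theta = 0L, target = target, contributors = empty))
  }
  sel <- hits[which.min(abs(grp$diff[hits] - target))]
  members <- grp$order[grp$group == sel]
  list(theta = grp$mult[sel], target = target,
       contributors = data.frame(
         w1_start = w1_start[members], w1_end = w1_start[members] + k - 1L,
         w2_start = w2_start[members], w2_end = w2_start[members] + k - 1L,
         half = pairs$half[members], diff = pairs$diff[members]))
}

#' Score a candidate string
#'
#' Computes the tag score `theta` at every defined position
#' (`k < g <= n - k`) and the binary k-mer score `kappa` at every position:
#' `kappa` starts at zero and is raised to one for each residue covered by a
#' k-mer pair that contributed the matched residue mass during any tag-score
#' computation. Strings shorter than `2k + 1` (no defined tag-score
#' position) and strings containing residues without a defined mass are
#' marked unscorable.
#'
#' @inheritParams tag_score
#' @param spectrum_id Optional source spectrum id carried along.
#' @return Object of class `scored_candidate`: list with `sequence`,
#'   `spectrum_id`, `n`, `k`, `theta` (length-n numeric, `NA` at undefined
#'   positions), `kappa` (length-n 0/1 integer), `theta_sum` and `scorable`.
#' @export
score_string <- function(s, index, k = attr(index, "k"), L = 25, tol = 0.02,
                         table = residue_mass_table(), spectrum_id = NA_character_) {
  n <- nchar(s)
  out <- list(sequence = s, spectrum_id = spectrum_id, n = n, k = as.integer(k),
              theta = rep(NA_real_, n), kappa = integer(n),
              theta_sum = NA_real_, scorable = FALSE)
  class(out) <- "scored_candidate"
  if (n < 2 * k + 1) return(out)
  ok <- tryCatch({ string_mass(s, table); TRUE },
                 error = function(e) FALSE)
  if (!ok) return(out)
  kappa <- integer(n)
  for (g in seq.int(k + 1L, n - k)) {
    ts <- tag_score(s, g, index, k = k, L = L, tol = tol, table = table)
    out$theta[g] <- ts$theta
    if (nrow(ts$contributors)) {
      for (r in seq_len(nrow(ts$contributors))) {
        kappa[ts$contributors$w1_start[r]:ts$contributors$w1_end[r]] <- 1L
        kappa[ts$contributors$w2_start[r]:ts$contributors$w2_end[r]] <- 1L
      }
    }
  }
  out$kappa <- kappa
  out$theta_sum <- sum(out$theta, na.rm = TRUE)
  out$scorable <- TRUE
  out
}

#' @export
print.scored_candidate <- function(x, ...) {
  cat(sprintf("<scored_candidate> %s (n=%d, k=%d)%s\n", x$sequence, x$n, x$k,
              if (!x$scorable) " [unscorable]" else ""))
  if (x$scorable) {
    th <- ifelse(is.na(x$theta), "-", format(x$theta))
    cat("  tag score:   ", paste(th, collapse = " "), "\n")
    cat("  k-mer score: ", paste(x$kappa, collapse = " "), "\n")
    cat("  sum of tag scores:", x$theta_sum, "\n")
  }
  invisible(x)
}
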