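# The three-stage filtering cascade applied to scored candidates: (1) keep
# candidates whose scores are all positive (possible only for length
# > 2k+1); (2) within each spectrum, eliminate near-duplicates by ungapped
# Hamming alignment in decreasing tag-score-sum order; (3) keep
# length-(2k+1) candidates whose single middle tag score reaches the
# threshold h.

#' All-positive score filter
#'
#' Keeps scored candidates of length greater than `2k + 1` whose defined tag
#' scores are all positive and whose k-mer scores are all one. Candidates of
#' length exactly `2k + 1` can never qualify (their middle k-mer score is
#' necessarily zero) and are handled by [middle_score_filter()] instead.
#'
#' @param scored List of [score_string()] results.
#' @return The qualifying subset, in input order.
#' @export
positive_score_filter <- function(scored) {
  keep <- vapply(scored, function(x) {
    x$scorable && x$n > 2 * x$k + 1 &&
      all(x$theta[!is.na(x$theta)] > 0) && all(x$kappa == 1L)
  }, logical(1))
  scored[keep]
}

# Best ungapped alignment Hamming distance between a retained string s and a
# later candidate sp, under the cascade's alignment conditions:
#  (a) if nchar(sp) <= nchar(s), sp slides over every length-|sp| substring
#      of s;
#  (b) if nchar(sp) == nchar(s) + 1, s is aligned against the prefix and the
#      suffix of sp of length |s|;
#  (c) no insertions or deletions.
# Returns Inf when no alignment is admissible.
.best_hamming <- function(s, sp) {
  a <- strsplit(s, "", fixed = TRUE)[[1L]]
  b <- strsplit(sp, "", fixed = TRUE)[[1L]]
  n <- length(a)
  m <- length(b)
  if (m <= n) {
    best <- Inf
    for (start in 0:(n - m)) {
      best <- min(best, sum(a[start + seq_len(m)] != b))
    }
    best
  } else if (m == n + 1L) {
    min(sum(a != b[seq_len(n)]), sum(a != b[1L + seq_len(n)]))
  } else {
    Inf
  }
}

#' Hamming-alignment elimination of redundant candidates
#'
#' Within one spectrum's candidates (already through the all-positive
#' filter), sorts by decreasing sum of tag scores (stable: ties keep input
#' order) and iteratively removes, for each surviving string `s`, every
#' later string `s'` with `nchar(s') <= nchar(s) + 1` whose best ungapped
#' alignment against `s` has Hamming distance at most 2.
#'
#' @param scored List of [score_string()] results for one spectrum.
#' @return The surviving subset; always contains the highest-scoring input.
#' @export
hamming_elimination <- function(scored) {
  if (length(scored) <= 1L) return(scored)
  o <- order(-vapply(scored, `[[`, numeric(1), "theta_sum"))
  scored <- scored[o]
  alive <- rep(TRUE, length(scored))
  for (i in seq_along(scored)) {
    if (!alive[i]) next
    s <- scored[[i]]$sequence
    for (j in seq_along(scored)) {
      if (j <= i || !alive[j]) next
      sp <- scored[[j]]$sequence
      if (nchar(sp) <= nchar(s) + 1L && .best_hamming(s, sp) <= 2) {
        alive[j] <- FALSE
      }
    }
  }
  scored[alive]
}

#' Middle-tag-score filter for length-(2k+1) candidates
#'
#' A string of length exactly `2k + 1` has a single defined tag score, at
#' its middle position `k + 1`. Candidates whose middle tag score is at
#' least `h` are kept; the rest are eliminated.
#'
#' @param scored List of [score_string()] results, each of length `2k + 1`.
#' @param h Non-negative threshold on the middle tag score.
#' @return The qualifying subset, in input order.
#' @export
middle_score_filter <- function(scored, h) {
  stopifnot(h >= 0)
  keep <- vapply(scored, function(x) {
    stopifnot(x$n == 2 * x$k + 1)
    x$scorable && !is.na(x$theta[x$k + 1L]) && x$theta[x$k + 1L] >= h
  }, logical(1))
  scored[keep]
}

#' Validate candidate de novo sequences against a tag set
#'
#' Runs the full validation cascade. Every candidate is scored with
#' [score_string()]; candidates longer than `2k + 1` go through the
#' all-positive filter and then per-spectrum Hamming elimination, candidates
#' of length exactly `2k + 1` go through the middle-tag-score filter, and
#' shorter or unscorable candidates are dropped (counted in the summary).
#'
#' @param candidates Data frame with columns `spectrum_id` and `sequence`;
#'   row order defines the tie-breaking input order.
#' @param index A [tag_index()].
#' @param k Tag length; defaults to the index's.
#' @param L Window bound for [tag_score()].
#' @param tol Mass matching tolerance in Da.
#' @param h Middle-tag-score threshold.
#' @param table Residue mass table.
#' @return List with `retained` (list of `scored_candidate`s, grouped by
#'   spectrum in order of first appearance), `results` (data frame with one
#'   row per input candidate: `spectrum_id`, `sequence`, `theta_sum`,
#'   `status`), and `summary` (named integer vector of stage counts:
#'   `total`, `unscorable`, `long_total`, `all_positive`, `all_zero`,
#'   `align_retained`, `align_eliminated`, `middle_total`, `middle_pass`,
#'   `middle_fail`, `final`).
#' @export
validate_candidates <- function(candidates, index, k = attr(index, "k"),
                                L = 25, tol = 0.02, h = 1,
                                table = residue_mass_table()) {
  stopifnot(is.data.frame(candidates),
            all(c("spectrum_id", "sequence") %in% names(candidates)))
  n_in <- nrow(candidates)
  scored <- vector("list", n_in)
  for (r in seq_len(n_in)) {
    scored[[r]] <- score_string(candidates$sequence[r], index, k = k, L = L,
                                tol = tol, table = table,
                                spectrum_id = candidates$spectrum_id[r])
    scored[[r]]$input_order <- r
  }

  is_scorable <- vapply(scored, `[[`, logical(1), "scorable")
  nvec <- vapply(scored, `[[`, integer(1), "n")
  is_long <- is_scorable & nvec > 2 * k + 1
  is_mid <- is_scorable & nvec == 2 * k + 1
  all_zero <- vapply(scored, function(x) {
    x$scorable && all(x$theta[!is.na(x$theta)] == 0) && all(x$kappa == 0L)
  }, logical(1))

  retained <- list()
  status <- rep("dropped_unscorable", n_in)
  n_pos <- 0L
  n_align_kept <- 0L
  n_mid_pass <- 0L
  for (sid in unique(candidates$spectrum_id)) {
    in_sp <- candidates$spectrum_id == sid
    long_sc <- scored[in_sp & is_long]
    mid_sc <- scored[in_sp & is_mid]
    status[in_sp & is_long] <- "failed_positive_filter"
    status[in_sp & is_mid] <- "failed_middle_filter"

    pos <- positive_score_filter(long_sc)
    n_pos <- n_pos + length(pos)
    for (x in pos) status[x$input_order] <- "eliminated_by_alignment"
    surv <- hamming_elimination(pos)
    n_align_kept <- n_align_kept + length(surv)
    for (x in surv) status[x$input_order] <- "retained"

    mid <- middle_score_filter(mid_sc, h)
    n_mid_pass <- n_mid_pass + length(mid)
    for (x in mid) status[x$input_order] <- "retained"

    keep <- c(surv, mid)
    if (length(keep)) {
      keep <- keep[order(vapply(keep, `[[`, integer(1), "input_order"))]
      retained <- c(retained, keep)
    }
  }

  list(
    retained = retained,
    results = data.frame(
      spectrum_id = candidates$spectrum_id,
      sequence = candidates$sequence,
      theta_sum = vapply(scored, `[[`, numeric(1), "theta_sum"),
      status = status),
    summary = c(
      total = n_in,
      unscorable = sum(!is_scorable),
      long_total = sum(is_long),
      all_positive = n_pos,
      all_zero = sum(all_zero),
      align_retained = n_align_kept,
      align_eliminated = n_pos - n_align_kept,
      middle_total = sum(is_mid),
      middle_pass = n_mid_pass,
      middle_fail = sum(is_mid) - n_mid_pass,
      final = n_align_kept + n_mid_pass
    ),
    scored = scored
  )
}
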