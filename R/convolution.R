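# The tag-convolution algebra: k-mer convolution tau, the shift and merge
# operators, string-level convolution T(s1, s2), and spectral convolution as
# the 0-tag special case.

#' Construct a convolution object
#'
#' A convolution is a multiset of (offset-difference, multiplicity) pairs
#' together with the grouping tolerance under which nearby differences were
#' binned.
#'
#' @param diff Numeric vector of offset differences (Da).
#' @param mult Integer vector of multiplicities (>= 1), same length.
#' @param tol Grouping tolerance in Da.
#' @return Object of class `mass_convolution`, a data frame with columns
#'   `diff` and `mult` sorted by `diff`, with attribute `tol`.
#' @export
mass_convolution <- function(diff = numeric(), mult = integer(), tol = 0.02) {
  stopifnot(length(diff) == length(mult), tol > 0)
  mult <- as.integer(mult)
  if (length(mult) && any(mult < 1L)) {
    stop("multiplicities must be >= 1", call. = FALSE)
  }
  o <- order(diff)
  structure(data.frame(diff = diff[o], mult = mult[o]),
            tol = tol, class = c("mass_convolution", "data.frame"))
}

#' @export
print.mass_convolution <- function(x, ...) {
  cat(sprintf("<mass_convolution> %d difference(s), total multiplicity %d, tol=%g Da\n",
              nrow(x), sum(x$mult), attr(x, "tol")))
  if (nrow(x)) print.data.frame(x[order(-x$mult, x$diff), ], row.names = FALSE)
  invisible(x)
}

# Single-linkage grouping of weighted differences: sorted values chain into
# one bin while consecutive gaps are <= tol; each bin is reported at its
# multiplicity-weighted mean with the summed multiplicity. Returns the group
# assignment of the (sorted) input as well, for contributor tracking.
.group_diffs <- function(d, w, tol) {
  if (!length(d)) {
    return(list(diff = numeric(), mult = integer(),
                order = integer(), group = integer()))
  }
  o <- order(d)
  ds <- d[o]
  ws <- w[o]
  grp <- cumsum(c(1L, as.integer(diff(ds) > tol)))
  wsum <- as.numeric(tapply(ws, grp, sum))
  list(diff = as.numeric(tapply(ds * ws, grp, sum)) / wsum,
       mult = as.integer(wsum),
       order = o, group = grp)
}

#' k-mer tag convolution
#'
#' For two k-mers `w1` and `w2`, examines every pair `(t1, t2)` of tags from
#' the index labelled `w1` and `w2` respectively, computes the offset
#' difference `o(t2) - o(t1)`, and groups the differences within `tol`,
#' reporting each with its multiplicity (number of contributing tag pairs).
#' If either k-mer is absent from the tag-string set the result is empty.
#'
#' @param index A [tag_index()].
#' @param w1,w2 k-mer strings of equal length.
#' @param tol Grouping tolerance in Da (default 0.02, the validation
#'   matching tolerance).
#' @return A [mass_convolution()].
#' @export
kmer_convolution <- function(index, w1, w2, tol = 0.02) {
  stopifnot(inherits(index, "tag_index"), nchar(w1) == nchar(w2))
  o1 <- tags_for(index, w1)
  o2 <- tags_for(index, w2)
  if (!length(o1) || !length(o2)) return(mass_convolution(tol = tol))
  d <- as.numeric(outer(o2, o1, "-"))
  g <- .group_diffs(d, rep(1, length(d)), tol)
  mass_convolution(g$diff, g$mult, tol)
}

#' Shift a convolution
#'
#' Translates every offset difference by `delta`; multiplicities are
#' unchanged. `conv_shift(conv_shift(x, a), -a)` recovers `x`.
#'
#' @param conv A [mass_convolution()].
#' @param delta Shift in Da.
#' @return The shifted convolution.
#' @export
conv_shift <- function(conv, delta) {
  stopifnot(inherits(conv, "mass_convolution"))
  conv$diff <- conv$diff + delta
  conv
}

#' Merge two convolutions
#'
#' Takes the union of the two difference sets; differences matching within
#' `tol` are combined with summed multiplicity (reported at the
#' multiplicity-weighted mean difference), unmatched ones inherit theirs.
#' Total multiplicity is conserved exactly.
#'
#' @param x,y [mass_convolution()] objects.
#' @param tol Grouping tolerance in Da; defaults to `x`'s.
#' @return The merged convolution.
#' @export
conv_merge <- function(x, y, tol = attr(x, "tol")) {
  stopifnot(inherits(x, "mass_convolution"), inherits(y, "mass_convolution"))
  g <- .group_diffs(c(x$diff, y$diff), c(x$mult, y$mult), tol)
  mass_convolution(g$diff, g$mult, tol)
}

# One row per contributing tag pair for every k-mer pair of one directional
# half of a string convolution: w1 ranges over k-mers of x, w2 over k-mers
# of y, and each tag-pair difference o(t2) - o(t1) is shifted by
# delta = -Mass(x[i..p]) - Mass(y[1..j-1]).
.half_pairs <- function(index, x, y, k, table) {
  p <- nchar(x)
  q <- nchar(y)
  rows <- list()
  for (i in seq_len(p - k + 1L)) {
    w1 <- substr(x, i, i + k - 1L)
    o1 <- tags_for(index, w1)
    if (!length(o1)) next
    delta_i <- -string_mass(substr(x, i, p), table)
    for (j in seq_len(q - k + 1L)) {
      w2 <- substr(y, j, j + k - 1L)
      o2 <- tags_for(index, w2)
      if (!length(o2)) next
      delta <- delta_i - string_mass(substr(y, 1L, j - 1L), table)
      rows[[length(rows) + 1L]] <- data.frame(
        diff = as.numeric(outer(o2, o1, "-")) + delta,
        i = i, j = j, w1 = w1, w2 = w2)
    }
  }
  if (!length(rows)) {
    return(data.frame(diff = numeric(), i = integer(), j = integer(),
                      w1 = character(), w2 = character()))
  }
  do.call(rbind, rows)
}

# Raw tag-pair contributions to T(s1, s2): the forward half over (s1, s2)
# plus the reversed half over (rev(s2), rev(s1)).
.string_conv_pairs <- function(index, s1, s2, k, table) {
  fwd <- .half_pairs(index, s1, s2, k, table)
  rev <- .half_pairs(index, reverse_string(s2), reverse_string(s1), k, table)
  fwd$half <- rep("fwd", nrow(fwd))
  rev$half <- rep("rev", nrow(rev))
  rbind(fwd, rev)
}

#' String-level tag convolution T(s1, s2)
#'
#' Extends k-mer convolution to arbitrary strings: for every pair of k-mers
#' `w1 = a_i..a_(i+k-1)` of `s1` and `w2 = b_j..b_(j+k-1)` of `s2`, the k-mer
#' convolution of `(w1, w2)` is shifted by
#' `delta = -Mass(a_i..a_p) - Mass(b_1..b_(j-1))` and all shifted sets are
#' merged; the same is done with the reversed copies (`rev(s2)`, `rev(s1)`)
#' in place of (`s1`, `s2`), and both halves are merged. The entries of the
#' result are weighted estimates of the mass of the sequence gap between
#' `s1` and `s2`; by construction `T(s1, s2) = T(rev(s2), rev(s1))`.
#'
#' @param index A [tag_index()].
#' @param s1,s2 Amino-acid strings, each of length >= k.
#' @param k Tag length; defaults to the index's.
#' @param tol Grouping tolerance in Da.
#' @param table Residue mass table.
#' @return A [mass_convolution()].
#' @export
string_convolution <- function(index, s1, s2, k = attr(index, "k"),
                               tol = 0.02, table = residue_mass_table()) {
  stopifnot(inherits(index, "tag_index"))
  if (nchar(s1) < k || nchar(s2) < k) {
    stop("both strings must have length >= k = ", k, call. = FALSE)
  }
  pairs <- .string_conv_pairs(index, s1, s2, k, table)
  g <- .group_diffs(pairs$diff, rep(1, nrow(pairs)), tol)
  mass_convolution(g$diff, g$mult, tol)
}

#' Spectral convolution of two spectra
#'
#' The classical spectral convolution -- all pairwise peak-mass differences
#' `m2 - m1` with multiplicities -- computed as the 0-tag special case of
#' tag convolution: each peak of either spectrum becomes a tag labelled with
#' an artificial per-spectrum string, and the k-mer convolution of the two
#' labels is returned. The multiplicity of the zero difference is the shared
#' peaks count.
#'
#' @param s1,s2 [deconv_spectrum()] objects.
#' @param tol Grouping tolerance in Da.
#' @return A [mass_convolution()].
#' @export
spectral_convolution <- function(s1, s2, tol = 0.02) {
  stopifnot(inherits(s1, "deconv_spectrum"), inherits(s2, "deconv_spectrum"))
  m1 <- s1$peaks$mass
  m2 <- s2$peaks$mass
  tags <- data.frame(
    tag = c(rep("z1*", length(m1)), rep("z2*", length(m2))),
    offset = c(m1, m2),
    spectrum_id = c(rep("s1", length(m1)), rep("s2", length(m2))))
  idx <- tag_index(tags, k = 3L)
  kmer_convolution(idx, "z1*", "z2*", tol)
}
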