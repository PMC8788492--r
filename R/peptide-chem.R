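# Monoisotopic residue masses (Da) from standard atomic masses. I and L are
# isobaric by construction; K and Q differ by ~0.036 Da and stay distinct at
# the default tag tolerance.
.STANDARD_RESIDUE_MASSES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, I = 113.08406, L = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.WATER <- 18.010565

#' Residue mass table with fixed modifications
#'
#' Builds the table of monoisotopic amino-acid residue masses used throughout
#' the package, optionally shifted by fixed (global) modifications. The
#' default applies carbamidomethylation of cysteine (C+57.02146 Da), the
#' standard fixed modification for iodoacetamide-alkylated samples.
#'
#' @param fixed_mods Named numeric vector of mass deltas in Da, one entry per
#'   modified residue letter, e.g. `c(C = 57.02146)`. Use `NULL` or an empty
#'   vector for unmodified masses. A list of single named values is also
#'   accepted.
#' @return Named numeric vector mapping residue letters to residue masses
#'   (Da), of class `residue_mass_table`.
#' @examples
#' tab <- residue_mass_table()
#' tab["C"] # 103.00919 + 57.02146
#' residue_mass_table(NULL)["C"]
#' @export
residue_mass_table <- function(fixed_mods = c(C = 57.02146)) {
  tab <- .STANDARD_RESIDUE_MASSES
  if (is.list(fixed_mods)) fixed_mods <- unlist(fixed_mods)
  if (length(fixed_mods)) {
    if (!is.numeric(fixed_mods) || is.null(names(fixed_mods)) ||
        any(!nzchar(names(fixed_mods)))) {
      stop("`fixed_mods` must be a named numeric vector of mass deltas in Da",
           call. = FALSE)
    }
    unknown <- setdiff(names(fixed_mods), names(tab))
    if (length(unknown)) {
      stop("fixed modification targets unknown residue(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    tab[names(fixed_mods)] <- tab[names(fixed_mods)] + fixed_mods
  }
  structure(tab, class = c("residue_mass_table", class(tab)))
}

#' Residue-sum mass of an amino-acid string
#'
#' Sums residue masses; no water term is added, so the result matches offset
#' differences within a single fragment-ion ladder. The empty string has mass
#' zero.
#'
#' @param s Character vector of amino-acid strings.
#' @param table Residue mass table, see [residue_mass_table()].
#' @return Numeric vector of masses in Da.
#' @examples
#' string_mass("N") # 114.04293
#' string_mass("GG") == 2 * string_mass("G")
#' @export
string_mass <- function(s, table = residue_mass_table()) {
  vapply(s, function(si) {
    if (is.na(si)) return(NA_real_)
    if (!nzchar(si)) return(0)
    chars <- strsplit(si, "", fixed = TRUE)[[1L]]
    m <- unname(table[chars])
    if (anyNA(m)) {
      bad <- which(is.na(m))[1L]
      stop(sprintf("unknown residue '%s' at position %d of \"%s\"",
                   chars[bad], bad, si), call. = FALSE)
    }
    sum(m)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Reverse an amino-acid string
#'
#' @param s Character vector.
#' @return `s` with the characters of each element in reverse order.
#' @examples
#' reverse_string("DPV") # "VPD"
#' @export
reverse_string <- function(s) {
  vapply(s, function(si) {
    if (is.na(si)) return(NA_character_)
    paste(rev(strsplit(si, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Lookup key under which isobaric I/L are identified: de novo engines may
# write either letter, but tags carry the canonical L.
.il_key <- function(w) gsub("I", "L", w, fixed = TRUE)

# Residues usable as spectrum-graph edge labels: residues sharing one exact
# mass collapse to a single canonical letter (L for the I/L pair).
.graph_residues <- function(table) {
  letters <- names(table)
  ord <- c(setdiff(letters, "I"), intersect("I", letters))
  tab <- table[ord]
  tab[!duplicated(unname(tab))]
}
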