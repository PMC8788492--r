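# Spectrum graph and k-tag extraction. Vertices are peaks scored by their
# intensities; a directed edge u -> v labelled with residue a exists when
# |Mass(v) - Mass(u) - mass(a)| < 2*eps. One optimal (maximum
# intensity-sum) path is extracted per weakly connected component and all
# k-length edge windows along it become sequence tags.

#' Build the spectrum graph of a deconvoluted spectrum
#'
#' @param spectrum A [deconv_spectrum()].
#' @param table Residue mass table; isobaric residues (I/L) are collapsed to
#'   a single edge label (L).
#' @param eps Tag-generation tolerance in Da; edges require the peak-mass
#'   difference to match a residue mass within `2 * eps`. Default 4 mDa.
#' @return An object of class `spectrum_graph`: a list with the peak table,
#'   an edge data frame (`from`, `to`, `residue`, `error`), the spectrum id
#'   and `eps`. Edges always point from lighter to heavier peaks, so the
#'   graph is acyclic.
#' @export
build_spectrum_graph <- function(spectrum, table = residue_mass_table(),
                                 eps = 0.004) {
  stopifnot(inherits(spectrum, "deconv_spectrum"), eps > 0)
  m <- spectrum$peaks$mass
  res <- .graph_residues(table)
  edges <- list()
  if (length(m) >= 2L) {
    for (a in names(res)) {
      target <- res[[a]]
      lo <- findInterval(m + target - 2 * eps, m) + 1L
      hi <- findInterval(m + target + 2 * eps, m)
      for (i in which(lo <= hi)) {
        js <- seq.int(lo[i], hi[i])
        err <- m[js] - m[i] - target
        ok <- abs(err) < 2 * eps & js != i
        if (any(ok)) {
          edges[[length(edges) + 1L]] <-
            data.frame(from = i, to = js[ok], residue = a, error = err[ok])
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = integer(), to = integer(), residue = character(),
               error = numeric())
  edges <- edges[order(edges$from, edges$to, edges$residue), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(spectrum_id = spectrum$id, peaks = spectrum$peaks,
                 edges = edges, eps = eps),
            class = "spectrum_graph")
}

#' @export
print.spectrum_graph <- function(x, ...) {
  cat(sprintf("<spectrum_graph> id=%s: %d vertices, %d edges (eps=%g Da)\n",
              x$spectrum_id, nrow(x$peaks), nrow(x$edges), x$eps))
  invisible(x)
}

# Comparator for path candidates: higher score, then lighter start peak,
# then lexicographically smaller label string. Deterministic.
.path_better <- function(a, b) {
  if (a$score != b$score) return(a$score > b$score)
  if (a$startm != b$startm) return(a$startm < b$startm)
  a$labs < b$labs
}

#' Optimal path per connected component of a spectrum graph
#'
#' Computes, for every weakly connected component, the directed path
#' maximizing the sum of vertex scores (peak intensities), by dynamic
#' programming over the mass-sorted vertices. Ties are broken
#' deterministically by the lighter start peak, then the lexicographically
#' smaller edge-label string. Where parallel edges connect the same peak
#' pair, the label with the smaller absolute mass error is used.
#'
#' @param graph A [build_spectrum_graph()] result.
#' @return List with one element per component (ordered by lightest member
#'   peak), each a list with `vertices` (peak indices along the path),
#'   `masses`, `intensities`, `labels` (edge residue letters, one fewer than
#'   vertices), `score` and `spectrum_id`.
#' @export
optimal_paths <- function(graph) {
  stopifnot(inherits(graph, "spectrum_graph"))
  n <- nrow(graph$peaks)
  if (n == 0L) return(list())
  m <- graph$peaks$mass
  int <- graph$peaks$intensity
  E <- graph$edges
  if (nrow(E)) {
    # collapse parallel edges: smaller |error| wins, then letter order
    E <- E[order(E$from, E$to, abs(E$error), E$residue), , drop = FALSE]
    E <- E[!duplicated(E[c("from", "to")]), , drop = FALSE]
  }
  comp <- if (nrow(E)) {
    g <- igraph::graph_from_data_frame(
      E[c("from", "to")], directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    igraph::components(g)$membership
  } else {
    seq_len(n)
  }

  score <- int
  startm <- m
  labs <- rep("", n)
  pred <- rep(NA_integer_, n)
  inc <- if (nrow(E)) split(seq_len(nrow(E)), E$to) else list()
  for (v in order(m, seq_len(n))) {
    ein <- inc[[as.character(v)]]
    best <- list(score = int[v], startm = m[v], labs = "")
    best_u <- NA_integer_
    for (e in ein) {
      u <- E$from[e]
      cand <- list(score = score[u] + int[v], startm = startm[u],
                   labs = paste0(labs[u], E$residue[e]))
      if (.path_better(cand, best)) {
        best <- cand
        best_u <- u
      }
    }
    score[v] <- best$score
    startm[v] <- best$startm
    labs[v] <- best$labs
    pred[v] <- best_u
  }

  comps <- unname(split(seq_len(n), comp))
  comps <- comps[order(vapply(comps, function(vs) min(m[vs]), numeric(1)))]
  lapply(comps, function(vs) {
    end <- vs[1L]
    for (v in vs[-1L]) {
      cand <- list(score = score[v], startm = startm[v], labs = labs[v])
      cur <- list(score = score[end], startm = startm[end], labs = labs[end])
      if (.path_better(cand, cur)) end <- v
    }
    path <- end
    while (!is.na(pred[path[1L]])) path <- c(pred[path[1L]], path)
    list(vertices = path, masses = m[path], intensities = int[path],
         labels = strsplit(labs[end], "", fixed = TRUE)[[1L]],
         score = score[end], spectrum_id = graph$spectrum_id)
  })
}

#' Extract all k-tags along a path
#'
#' Every window of `k` consecutive edges along the path yields one sequence
#' tag; its string is the concatenated edge labels and its offset the mass
#' of the window's first peak. A path with fewer than `k` edges yields no
#' tags.
#'
#' @param path One element of an [optimal_paths()] result.
#' @param k Tag length (>= 1).
#' @param spectrum_id Source spectrum id (defaults to the path's).
#' @return Data frame with columns `tag`, `offset`, `spectrum_id`.
#' @export
extract_k_tags <- function(path, k, spectrum_id = path$spectrum_id) {
  stopifnot(k >= 1)
  e <- length(path$labels)
  if (e < k) {
    return(data.frame(tag = character(), offset = numeric(),
                      spectrum_id = character()))
  }
  starts <- seq_len(e - k + 1L)
  data.frame(
    tag = vapply(starts, function(i)
      paste(path$labels[i:(i + k - 1L)], collapse = ""), character(1)),
    offset = path$masses[starts],
    spectrum_id = spectrum_id
  )
}

#' Generate the tag set of a spectrum dataset
#'
#' Runs the full tag-generation pipeline over a list of (preprocessed)
#' spectra: spectrum graph, optimal path per connected component, k-tag
#' extraction. Tags with the same string and offset from distinct spectra
#' are kept as distinct members of the tag set.
#'
#' @param spectra List of [deconv_spectrum()] objects with unique ids.
#' @param k Tag length, default 3.
#' @param eps Tag tolerance in Da, default 0.004.
#' @param table Residue mass table.
#' @param verbose Log per-spectrum tag counts with `message()`?
#' @return A [tag_index()] holding all generated tags.
#' @export
generate_tags <- function(spectra, k = 3, eps = 0.004,
                          table = residue_mass_table(), verbose = FALSE) {
  if (inherits(spectra, "deconv_spectrum")) spectra <- list(spectra)
  .check_unique_ids(spectra)
  tags <- lapply(spectra, function(sp) {
    paths <- optimal_paths(build_spectrum_graph(sp, table, eps))
    tg <- do.call(rbind, c(
      lapply(paths, extract_k_tags, k = k),
      list(data.frame(tag = character(), offset = numeric(),
                      spectrum_id = character()))))
    if (verbose) {
      message(sprintf("spectrum %s: %d peaks, %d components, %d %d-tags",
                      sp$id, nrow(sp$peaks), length(paths), nrow(tg), k))
    }
    tg
  })
  empty <- data.frame(tag = character(), offset = numeric(),
                      spectrum_id = character())
  tag_index(do.call(rbind, c(tags, list(empty))), k = k)
}

#' Tag index
#'
#' The tag set T keyed for k-mer lookup. Lookup keys identify the isobaric
#' residues I and L, so that candidate strings written with either letter
#' retrieve the same tags; stored tag strings are kept as generated.
#'
#' @param tags Data frame with columns `tag`, `offset`, `spectrum_id`.
#' @param k Tag length; all tag strings must have `nchar == k`.
#' @return Object of class `tag_index` (a data frame with attribute `k`).
#' @export
tag_index <- function(tags, k) {
  stopifnot(is.data.frame(tags),
            all(c("tag", "offset", "spectrum_id") %in% names(tags)))
  if (nrow(tags) && any(nchar(tags$tag) != k)) {
    stop("all tag strings must have length k = ", k, call. = FALSE)
  }
  tags <- tags[c("tag", "offset", "spectrum_id")]
  tags$key <- .il_key(tags$tag)
  rownames(tags) <- NULL
  structure(tags, k = as.integer(k),
            class = c("tag_index", "data.frame"))
}

#' Look up the offsets of all tags labelled with a k-mer
#'
#' @param index A [tag_index()].
#' @param w k-mer string (I/L treated as identical).
#' @return Numeric vector of offsets (empty if `w` is not in the tag-string
#'   set K).
#' @export
tags_for <- function(index, w) {
  stopifnot(inherits(index, "tag_index"))
  index$offset[index$key == .il_key(w)]
}

#' Tag-string set K of a tag index
#'
#' @param index A [tag_index()].
#' @return Character vector of distinct lookup keys.
#' @export
tag_strings <- function(index) {
  unique(index$key)
}

#' @export
print.tag_index <- function(x, ...) {
  cat(sprintf("<tag_index> %d %d-tags from %d spectra (%d distinct strings)\n",
              nrow(x), attr(x, "k"), length(unique(x$spectrum_id)),
              length(unique(x$key))))
  if (nrow(x)) print.data.frame(utils::head(x, 10L))
  invisible(x)
}
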