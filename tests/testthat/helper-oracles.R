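# Shared fixtures, random-instance generators and independent brute-force
# oracles used across the test files.

WATER <- 18.010565

toy_fixture <- function() {
  toy <- toy_dataset()
  toy$index <- generate_tags(toy$spectra, k = 3, eps = 0.004)
  toy
}

random_spectrum <- function(n, id = "rnd", mass_range = c(100, 2000),
                            precursor = NA_real_) {
  deconv_spectrum(id, sort(runif(n, mass_range[1], mass_range[2])),
                  runif(n, 1, 100), precursor_mass = precursor)
}

# Tag index of random k-mers over a small alphabet (so string collisions,
# hence multiplicities > 1, actually occur).
random_tag_index <- function(n_tags, k = 3, alphabet = c("A", "G", "S", "P", "V")) {
  strings <- vapply(seq_len(n_tags), function(i)
    paste(sample(alphabet, k, replace = TRUE), collapse = ""), character(1))
  tag_index(data.frame(tag = strings,
                       offset = runif(n_tags, 0, 3000),
                       spectrum_id = sample(sprintf("sp%d", 1:4), n_tags,
                                            replace = TRUE)),
            k = k)
}

random_string <- function(len, alphabet = c("A", "G", "S", "P", "V")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Independent single-linkage grouping used to check convolution binning:
# written as an explicit loop, unlike the vectorised implementation.
oracle_group <- function(d, w, tol) {
  o <- order(d)
  d <- d[o]
  w <- w[o]
  out_d <- numeric()
  out_m <- numeric()
  cur_d <- d[1]
  cur_w <- w[1]
  if (length(d) > 1) {
    for (i in 2:length(d)) {
      if (d[i] - d[i - 1] > tol) {
        out_d <- c(out_d, sum(cur_d * cur_w) / sum(cur_w))
        out_m <- c(out_m, sum(cur_w))
        cur_d <- d[i]
        cur_w <- w[i]
      } else {
        cur_d <- c(cur_d, d[i])
        cur_w <- c(cur_w, w[i])
      }
    }
  }
  out_d <- c(out_d, sum(cur_d * cur_w) / sum(cur_w))
  out_m <- c(out_m, sum(cur_w))
  data.frame(diff = out_d, mult = as.integer(out_m))
}

# Brute-force k-mer convolution: enumerate the Cartesian product of tag
# offsets directly from the index data frame.
oracle_kmer_convolution <- function(index, w1, w2, tol) {
  key <- gsub("I", "L", index$tag, fixed = TRUE)
  o1 <- index$offset[key == gsub("I", "L", w1, fixed = TRUE)]
  o2 <- index$offset[key == gsub("I", "L", w2, fixed = TRUE)]
  if (!length(o1) || !length(o2)) {
    return(data.frame(diff = numeric(), mult = integer()))
  }
  d <- as.numeric(sapply(o1, function(a) o2 - a))
  oracle_group(d, rep(1, length(d)), tol)
}

# Exhaustive best-path score per weakly connected component: depth-first
# enumeration of every directed path in the spectrum graph.
oracle_best_path_scores <- function(graph) {
  n <- nrow(graph$peaks)
  int <- graph$peaks$intensity
  E <- unique(graph$edges[c("from", "to")])
  adj <- split(E$to, factor(E$from, levels = seq_len(n)))
  best <- rep(-Inf, n) # best over paths *starting* at each vertex
  walk <- function(v) {
    if (is.finite(best[v])) return(best[v])
    succ <- adj[[v]]
    score <- int[v]
    if (length(succ)) {
      score <- int[v] + max(0, max(vapply(succ, walk, numeric(1))))
    }
    best[v] <<- score
    score
  }
  for (v in seq_len(n)) walk(v)
  # component membership via repeated expansion over undirected adjacency
  und <- rbind(E, data.frame(from = E$to, to = E$from))
  comp <- seq_len(n)
  repeat {
    new <- comp
    for (r in seq_len(nrow(und))) {
      m <- min(comp[und$from[r]], comp[und$to[r]])
      new[und$from[r]] <- min(new[und$from[r]], m)
      new[und$to[r]] <- min(new[und$to[r]], m)
    }
    if (identical(new, comp)) break
    comp <- new
  }
  tapply(best, comp, max)
}

# Independent Hamming-elimination checker operating on plain sequences
# sorted by score, using substring() rather than character vectors.
oracle_hamming_survivors <- function(seqs, scores) {
  hd <- function(a, b) {
    sum(vapply(seq_len(nchar(a)), function(i)
      substring(a, i, i) != substring(b, i, i), logical(1)))
  }
  best_aln <- function(s, sp) {
    ns <- nchar(s)
    np <- nchar(sp)
    if (np <= ns) {
      min(vapply(0:(ns - np), function(off)
        hd(substring(s, off + 1, off + np), sp), numeric(1)))
    } else if (np == ns + 1) {
      min(hd(s, substring(sp, 1, ns)), hd(s, substring(sp, 2, np)))
    } else {
      Inf
    }
  }
  o <- order(-scores)
  seqs <- seqs[o]
  alive <- rep(TRUE, length(seqs))
  for (i in seq_along(seqs)) {
    if (!alive[i]) next
    for (j in seq_along(seqs)) {
      if (j <= i || !alive[j]) next
      if (nchar(seqs[j]) <= nchar(seqs[i]) + 1 &&
          best_aln(seqs[i], seqs[j]) <= 2) {
        alive[j] <- FALSE
      }
    }
  }
  sort(seqs[alive])
}

# Minimal stand-in for a scored candidate, for filter-only tests.
fake_scored <- function(sequence, theta_sum) {
  structure(list(sequence = sequence, theta_sum = theta_sum,
                 n = nchar(sequence), k = 3L, scorable = TRUE),
            class = "scored_candidate")
}
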