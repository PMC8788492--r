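---
title: "Bottom-up tag convolution: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bottom-up tag convolution: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagconv)
```

## The model

`tagconv` validates candidate de novo peptide sequences by checking whether
the mass structure of the spectra they were derived from independently
supports each residue. The chain of objects is:

1. **Deconvoluted spectra.** Input peak lists are neutral monoisotopic
   masses with intensities (msalign dialect or plain TSV). Deconvolution
   itself is upstream and out of scope.
2. **Spectrum graph.** Peaks become vertices scored by intensity; a
   directed edge u→v labelled with residue *a* exists when
   `Mass(v) > Mass(u)` and `|Mass(v) − Mass(u) − mass(a)| < 2ε`. The
   doubled tolerance reflects that consecutive fragment ions share most of
   their absolute mass error, so their *difference* is far more accurate
   than either mass. Edges always increase mass, so the graph is a DAG.
3. **k-tags.** One maximum intensity-sum path is computed per weakly
   connected component, and every window of k consecutive edges yields a
   tag: string = edge labels, offset = mass of the window's first peak.
   Tags with equal string and offset from different spectra are distinct.
4. **Tag convolution.** For k-mers w₁, w₂, `kmer_convolution()` collects
   all offset differences o(t₂) − o(t₁) over tag pairs labelled (w₁, w₂),
   binned within a grouping tolerance. `string_convolution()` extends this
   to strings by shifting each k-mer pair's convolution by
   δ = −Mass(suffix of s₁ from w₁) − Mass(prefix of s₂ before w₂) and
   merging, over both (s₁, s₂) and the reversed copies (s̄₂, s̄₁) — the
   latter capture y-type ladders, whose tag strings read the sequence
   backwards. By construction `T(s₁,s₂) = T(s̄₂,s̄₁)`, which the test suite
   checks as a property.
5. **Scores.** θ(a_g) is the multiplicity of Mass(a_g) in the convolution
   of the flanks of position g (windowed to L residues); κ is a binary
   per-residue flag raised when the residue belongs to any k-mer pair that
   contributed the matched mass.
6. **Cascade.** All-positive selection (θ all > 0 and κ all 1), then
   per-spectrum Hamming-alignment elimination (sorted by decreasing Σθ;
   later strings at ungapped distance ≤ 2 with the stated length
   conditions are removed), then the middle-tag-score threshold h for
   strings of length exactly 2k + 1.

### Assumptions

* Offsets of tags from the same ion series of the same underlying sequence
  differ by residue-sum masses only; this is why `string_mass()` carries
  no water term. Pairs that mix b- and y-derived tags differ by ±H₂O and
  simply fail to match a residue mass.
* k-mers are assumed (not enforced) to be near-unique in the sample up to
  reversal; repeated k-mers add spurious convolution entries, which the
  all-positive filter tolerates because only the matched residue mass is
  read off.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `k` | 3 | residues | tag length; short tags cover weak regions at the cost of duplicated strings |
| `eps` | 0.004 | Da | tag-generation tolerance; edge rule uses `2 * eps` |
| `tol` | 0.02 | Da | convolution grouping and residue-mass matching tolerance |
| `h` | 1 | counts | middle-tag-score threshold for length-(2k+1) strings; raise on tag-rich datasets |
| `L` | 25 | residues | flank window bound for θ |
| `reflect` | on | — | add mirrored peaks at precursor − mass before tag generation |
| `water_loss` | off | — | drop peaks 18.0106 Da below a stronger peak |
| `fixed_mods` | C+57.02146 | Da | global residue-mass shifts (carbamidomethyl-C) |

`L` is deliberately generous: it has no natural value in the method itself,
and 25 residues exceeds nearly all tryptic peptides, so in practice (and
in the worked toy) the full flanks are used; it exists to keep distant,
error-accumulating k-mer pairs out of θ for unusually long candidates.

## Numerical choices

* **Residue masses** are standard monoisotopic values to five decimals;
  I and L are isobaric. Spectrum-graph edges collapse exact-duplicate
  masses to one canonical label (L), and tag lookups normalise I→L, so
  candidates keep their letters while convolution and scoring effectively
  operate on masses. K and Q (Δ ≈ 0.036 Da) remain distinct at ε = 4 mDa.
* **Binning** of convolution differences is single-linkage on the sorted
  values: a gap > tol starts a new bin; a bin is reported at its
  multiplicity-weighted mean. This makes `conv_merge()` exactly
  conservative in total multiplicity and keeps reported differences
  pairwise separated by more than tol.
* **θ matching**: the convolution entry nearest the residue mass within
  tol is read; contributing pairs are the members of that bin, which keeps
  θ and the κ updates consistent with each other.
* **Ties** in the optimal-path DP are broken by (higher score, lighter
  start peak, lexicographically smaller label string); parallel edges keep
  the label with the smaller absolute mass error. Candidate elimination
  sorts are stable, so equal-score candidates keep file order — a de novo
  engine's rank order — making every pipeline output byte-reproducible.
* **Degenerate inputs**: empty spectra give empty graphs and no tags;
  k-mers absent from the tag set give empty convolutions; strings shorter
  than 2k+1 or containing letters without a mass are marked unscorable and
  dropped with a count rather than erroring the run.

## The synthetic generator

`simulate_dataset()` defines the study conditions used by the end-to-end
tests. A 40-residue source protein is cut into overlapping 12-mers
(step 4); each peptide emits **two** spectra — one complete b-series and
one complete y-series ladder, both including the full-length species (the
dehydrated and intact precursor masses, routinely present in deconvoluted
bottom-up data) — at uniform intensity 100, with optional sub-signal noise
peaks (default none). Candidate lists carry the true peptide at rank 1
plus decoys: isobaric I/L swaps (score-identical to the truth, removable
only by Hamming elimination), shuffled interiors and 1–2 substitutions
with a per-position mass change above 10 Da (both of which fail the
all-positive filter).

Two deliberate choices deserve justification:

* *Both series, separate spectra.* With only one ion series, the k-mers at
  a peptide's termini are never tagged and a true candidate's boundary θ
  would be zero, making 100% recovery impossible; with both series in one
  spectrum, the two ladders can fuse into one graph component of which
  only one optimal path survives. One series per spectrum gives complete
  k-mer coverage with clean components. For the same reason, pipeline runs
  on simulated data disable peak reflection — reflection exists to
  reconstruct the missing series on real data.
* *Uniform intensities.* The optimal-path objective then reduces to the
  longest path, so planted ladders are provably optimal and noise peaks
  (kept below the signal floor) can only append to, never divert, a path.

What the simulator does **not** emulate: realistic fragmentation and
intensity models, deconvolution errors (±1 Da misassignments), isotopic
envelope artefacts, chimeric spectra, missed peaks inside ladders.
Passing the recovery test therefore shows the *procedure* is implemented
correctly under ideal evidence, not that real datasets will reach any
particular retention rate; on real data the interesting regime is exactly
the one where tags are incomplete.

Problem sizes throughout the test suite (a 40-residue protein, 8 peptides,
16 spectra, ~150 tags, 32 candidates; property suites of 25–500 random
instances; exhaustive path search up to 10 vertices) were chosen as the
smallest at which every behaviour of interest — multiplicities above one,
component splits, all three decoy fates — actually occurs.

## The toy worked example

```{r toy}
toy <- toy_dataset()
idx <- generate_tags(toy$spectra, k = 3, eps = 0.004)
score_string(toy$protein, idx, k = 3, L = 25, tol = 0.02)
```

The four spectra plant partial ladders chosen so that each sits in its own
graph component (verified by a fixture self-check in the tests): b3..b7
(yielding tags DPV and PVL), b12..b15 with y5..y8 (SMP and STA), y9..y12
(GSL) and y12..y15 (VPD). The scores above are the package's reference
output; the tag score 4 at N-10 decomposes into one count from each of the
pairs (DPV, SMP), (PVL, SMP), (STA, VPD) and (STA, GSL).

## Known limitations

* One optimal path per component: parallel high-quality ladders in the
  same component contribute only one tag series.
* The all-positive filter is stringent by design; on sparse tag sets most
  correct candidates fail it and only the length-(2k+1) route (with small
  h) retains them.
* Scoring cost grows with |s_l|·|s_r| k-mer pairs per position times the
  tag pairs per k-mer; for very large tag sets an inverted index keyed by
  k-mer keeps lookups linear, but no further indexing (e.g. offset
  sorting) is attempted.
* Variable/positional modifications are not modelled; fixed modifications
  shift the residue table globally.
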