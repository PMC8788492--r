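# tagconv

Validation of de novo peptide sequences with bottom-up tag convolution.

## The problem

De novo sequencing engines interpret tandem mass (MS/MS) spectra without a
database, which makes them indispensable for unknown genomes, splice
variants and antibodies — and also makes it hard to tell a correct
interpretation from its many plausible-looking alternatives. `tagconv`
addresses this for high-resolution bottom-up data: it re-examines the same
deconvoluted spectra the candidates came from, extracts short peptide
sequence tags from them, and asks whether the mass relationships among
those tags independently support each candidate residue.

It is aimed at proteomics researchers and tool builders who already have
deconvoluted peak lists (e.g. MS-Deconv `msalign` output) and candidate
sequences (e.g. PepNovo+ results) and want a fast, database-free validation
step.

## The method

A *k-tag* is a ladder of k+1 spectrum peaks separated by amino-acid residue
masses; its *string* is the k residue letters and its *offset* the mass of
the leftmost peak. Tags are extracted by building a spectrum graph (peaks
as intensity-scored vertices; an edge u→v labelled with residue *a* when
|Mass(v) − Mass(u) − mass(a)| < 2ε, with ε = 4 mDa), taking the maximum
intensity-sum path of each connected component, and reading off all k-edge
windows.

For two k-mers w₁, w₂, the *tag convolution* τ(w₁, w₂) is the multiset of
offset differences o(t₂) − o(t₁) over all tag pairs labelled w₁ and w₂,
each with its multiplicity. With a *shift* operator
τ_δ(w₁,w₂) = {(d + δ, m)} and a multiplicity-summing *merge* ∘, the
convolution extends to whole strings: for every k-mer pair from s₁ and s₂,
shift by δ = −Mass(aᵢ…a_p) − Mass(b₁…b_{j−1}) and merge, do the same for
the reversed copies (s̄₂, s̄₁), and merge both halves into T(s₁, s₂). The
entries of T(s₁, s₂) are weighted estimates of the mass of whatever
separates s₁ from s₂ in the underlying sequence. Classical spectral
convolution (and its shared peaks count) is the 0-tag special case.

Candidate validation scores every residue a_g of a candidate s:

* **tag score** θ(a_g) — the multiplicity of Mass(a_g) in T(s_l, s_r),
  where s_l and s_r are the flanks of a_g truncated to L residues
  (defined for k < g ≤ n − k);
* **k-mer score** κ(a_h) ∈ {0, 1} — raised to 1 whenever a_h belongs to a
  k-mer pair that contributed the matched mass.

Candidates then pass a three-stage cascade: (1) keep strings whose scores
are all positive (all θ > 0 and all κ = 1; only possible for length
> 2k+1); (2) per spectrum, sort by decreasing Σθ and eliminate every later
string within ungapped Hamming distance ≤ 2 (no indels; a one-residue-longer
string is matched on its prefix or suffix); (3) strings of length exactly
2k+1 are kept iff their single middle tag score is ≥ h.

## Worked example

The toy protein `AVTDPVLSGNATSMPGST` observed through four theoretical
spectra that plant six 3-tags:

```r
library(tagconv)
toy <- toy_dataset()
idx <- generate_tags(toy$spectra, k = 3, eps = 0.004)
idx
#> <tag_index> 6 3-tags from 4 spectra (6 distinct strings)
#>   tag    offset spectrum_id key
#> 1 DPV  271.1532        toy1 DPV
#> 2 PVL  386.1801        toy1 PVL
#> 3 STA  491.2050        toy2 STA
#> 4 SMP 1125.5666        toy2 SMP
#> 5 GSL  864.3647        toy3 GSL
#> 6 VPD 1121.5023        toy4 VPD
```

`DPV`, `PVL`, `SMP` come from b-ion ladders (offsets are prefix masses);
`STA`, `GSL`, `VPD` from y-ion ladders (offsets are suffix masses + H₂O),
so their strings read the protein backwards. Scoring the protein against
these tags:

```r
score_string(toy$protein, idx, k = 3, L = 25, tol = 0.02)
#> <scored_candidate> AVTDPVLSGNATSMPGST (n=18, k=3)
#>   tag score:    - - -  0  0  0  2  3  3  4  2  2  0  0  0 - - -
#>   k-mer score:  0 0 0 1 1 1 1 1 1 0 1 1 1 1 1 0 0 0
#>   sum of tag scores: 16
```

The tag score of N-10 is 4: the pairs (DPV, SMP), (PVL, SMP), (STA, VPD)
and (STA, GSL) each contribute the mass of asparagine (114.043 Da) once to
the string convolution of the flanks:

```r
string_convolution(idx, "AVTDPVLSG", "ATSMPGST")
#> <mass_convolution> 1 difference(s), total multiplicity 4, tol=0.02 Da
#>      diff mult
#>  114.0429    4
```

N-10 itself is covered by no tag, so its k-mer score stays 0 — which is
why a correct string of length 2k+1 can never have all-positive scores and
is filtered by the middle-tag-score threshold instead.

For whole directories (spectra in, `<name>.valid.txt` / `<name>.scores.txt`
out) use `run_validation()`, or the CLI at `inst/cli/tagconv.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "tagconv.R", package = "tagconv"))')" \
  validate --spectra spectra/ --sequences sequences/ --out out/
```

`simulate_dataset()` generates seeded synthetic datasets (theoretical b/y
ladders for overlapping peptides of a source protein, with planted true
candidates and decoy sequences) for end-to-end testing without any
downloads.

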