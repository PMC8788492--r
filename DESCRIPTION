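Package: tagconv
Title: Bottom-Up Tag Convolution for Validating De Novo Peptide Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Generates peptide sequence tags from deconvoluted tandem mass
    spectra via optimal paths in spectrum graphs, computes tag convolution --
    a generalization of spectral convolution defined over tag offset
    differences -- and uses it to assign per-residue tag and k-mer scores to
    candidate de novo peptide sequences, which are then filtered by an
    all-positive-score selection, a Hamming-alignment elimination and a
    middle-tag-score threshold. Includes a reader and writer for
    msalign-style deconvoluted peak lists, peak preprocessing (reflection,
    merging, water-loss removal), a theoretical b-/y-ion spectrum simulator
    with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
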