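Package: ehmmalign
Title: Ensemble Profile HMM Alignment of Fragmentary Sequences into a
    Backbone Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Aligns query sequences -- in particular short, fragmentary
    sequences -- into an existing backbone multiple sequence alignment.
    The backbone is represented by an ensemble of profile hidden Markov
    models built on subsets of the backbone sequences obtained by
    centroid-edge decomposition of the backbone tree.  For each query the
    ensemble is fused into a single merged HMM whose topology is the
    union of the ensemble's transition edges and whose numeric parameters
    are adjusted-bitscore-weighted averages; entry and exit edges enable
    glocal alignment of fragments, and the final alignment is assembled
    by transitivity.  Includes sum-of-pairs alignment error scoring
    (SPFN/SPFP) and a small indel-aware sequence simulator plus a
    fragmentation protocol for generating test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
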