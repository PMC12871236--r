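Package: qrnadesign
Title: RNA Inverse Folding by Deep Q-Learning with Structure and SHAPE Rewards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs RNA sequences that fold into a prescribed secondary
    structure, including pseudoknotted targets, by autoregressive deep
    Q-learning. Provides a pseudoknot-aware dot-bracket parser, a pluggable
    reward environment (a deterministic Nussinov folding oracle with a
    structure-derived SHAPE oracle, or any user-supplied predictor), a
    structure-conditioned encoder/decoder action-value network with key-value
    cached stepwise decoding, twice-shifted action-value training with reward
    reweighting and position-dependent discounting, greedy/beam/random
    inference with a combinatorial rescue repair step, and screening metrics
    (base-pair Jaccard, Eterna Classic Score, Crossed Pair Quality Score,
    OpenKnot score). A fixtures module generates designable hairpin,
    pseudoknot, and fold-derived targets so the whole pipeline runs at desk
    scale with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
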