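Package: manaim
Title: Agent-Based Bit-String Simulation of Cytotoxic T-Cell Memory and
    Interferon-Driven Attrition
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A stochastic, lattice-based (Celada-Seiden style) simulator of
    the CD8+ cytotoxic T-cell response to viral infection.  Receptors and
    viral peptides are binary strings; binding is governed by a Hamming-match
    affinity potential with a hard cut-off.  The package implements a full
    prime/challenge protocol over a panel of viruses at graded antigenic
    distance, reproduces the memory-anti-naive (MaN) dominance of
    cross-reactive memory clones over higher-affinity naive responses, and
    models its mitigation by type-I interferon driven attrition of aged,
    low-affinity cytotoxic cells.  Derived response metrics (per-match-class
    counts, total affinity, time-to-clear, efficacy, compression) are
    first-class outputs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
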