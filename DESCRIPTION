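Package: evofuse
Title: Combining Protein Language Model Embeddings with Evolutionary Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether per-residue protein language model
    (pLM) embeddings benefit from explicit evolutionary information. Implements
    five per-residue prediction workflows (raw embeddings, MSA-averaged
    embeddings, MSA-consensus prediction, PSSM concatenation, and split-branch
    PSSM fusion) around a small 1-D convolutional predictor, together with
    HSSP-curve (HVAL/PIDE) redundancy-reduction data splitting with leakage
    verification, PSSM construction from multiple sequence alignments, a full
    per-residue and per-segment evaluation suite (Q3, Q10, F1, Spearman, MCC,
    segment Q_ok) with random baselines, and a synthetic protein-family
    simulator that makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
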