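Package: UmamiForge
Title: Umami Peptide Discovery from Nucleotide Sequences with a
    Unanimity Deep Ensemble
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end in-silico discovery of candidate umami peptides
    from assembled nucleotide sequences. Extracts open reading frames by
    six-frame translation between stop codons, simulates combined
    trypsin/chymotrypsin proteolysis with configurable missed cleavages,
    removes redundancy by greedy longest-first clustering at a sequence
    identity threshold, classifies peptides with an ensemble of four
    small sequence models (convolutional, bidirectional LSTM, attention
    pooling, transformer encoder) combined by a unanimity vote, explains
    predictions with exact or sampled position-wise Shapley values, and
    annotates candidates with molecular weight, isoelectric point, GRAVY
    and net charge at a chosen pH.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Classification, Proteomics, SequenceMatching, Software
RoxygenNote: 7.3.3
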