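Package: protgraph
Title: Panproteome Graphs: Build, Index and Align to Protein MSA Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a panproteome from a collection of protein multiple
    sequence alignments (MSAs): each MSA is converted into a directed acyclic
    sequence graph whose paths spell the original (degapped) sequences, all
    MSAs are indexed by k-mer or (w,k)-minimizer seeds with normalized-count
    ordering, and amino-acid or DNA queries are locally aligned to the
    best-matching graphs using a partial-order extension of Smith-Waterman.
    DNA queries may be aligned frameshift-aware, consuming codons against
    amino-acid nodes with penalized single-nucleotide jumps. Graphs are
    exchanged as GFA1 with path records and alignments as GAF.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
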