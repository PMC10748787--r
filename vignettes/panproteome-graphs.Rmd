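---
title: "Panproteome graphs: construction, indexing and alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Panproteome graphs: construction, indexing and alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protgraph)
```

## The model

Bacterial genomes are too diverse for a single linear reference: a query
carrying a non-reference allele may fail to align at all. `protgraph`
represents the protein-coding content of a species or clade as a
*panproteome*: a collection of small directed acyclic sequence graphs, one
per protein (or protein cluster), each built from that protein's multiple
sequence alignment. Working in amino-acid space keeps distantly related
sequences alignable — synonymous DNA changes vanish, and a substitution
matrix scores biochemical similarity rather than edit distance.

### From MSA to DAG

An MSA is a matrix $M \in (A \cup \{-\})^{n \times m}$ over the amino-acid
alphabet $A$ plus the gap character. The builder scans columns left to
right; every (column, distinct non-gap character) pair becomes a node, and
an edge joins the nodes of two residues that are consecutive in some row
*after skipping gaps* — a residue followed by a run of gaps connects
forward to the row's next residue. Because edges always point to a strictly
later column the graph is acyclic, and each row is recorded as a named path
whose spelled labels reproduce the degapped row exactly (the round-trip
property, asserted on random fixtures). Construction touches each cell once,
so cost is linear in $n \times m$. Internally columns are 0-based; the
`column_of` field keeps each node's source column for provenance.

Linear stretches are then *compacted*: adjacent nodes $u \to v$ merge when
$u$ has out-degree one, $v$ has in-degree one, and the **identical set of
paths** traverses both. The path-set condition is essential: merging a
stretch that some sequence only partially traverses would make that
sequence inexpressible as a node path. For the MSA `{MTQT, --QT, MT--}` the
four single-residue nodes form a chain, but only `M+T` and `Q+T` may merge
— sequence 3 lives entirely in the first merged node and sequence 2 in the
second. Compaction is idempotent and never increases node, edge or
path-step counts. Graphs are exchanged as GFA1 (S/L/P lines; `0M` overlaps,
`+` orientations), with one P-line per original sequence.

### Seeding

Queries are routed to candidate graphs by a global seed index. Seeds are
either all consecutive $k$-mers of each degapped row ($m-k+1$ of them) or
$(w,k)$-minimizers: the lexicographically smallest $k$-mer in every window
of $w$ consecutive $k$-mers, computed with a monotone-deque sliding-window
minimum in linear time, with a consecutive window re-selecting the same
occurrence emitted once. Each seed maps to the list of MSAs containing it,
ordered by the seed's *normalized count* — occurrences in the MSA divided
by the MSA's row count — so that an MSA where the seed is common relative
to its depth ranks first. A per-seed cutoff (`seed_limit`) truncates the
list to curb promiscuous seeds; `0` keeps everything. Ties in normalized
count break by ascending MSA id so indexes are bit-reproducible.

### Alignment

Each candidate DAG is topologically sorted and its labels concatenated into
a target string $N$. The local DP generalizes Smith–Waterman: for a cell
$(i, j)$ the "previous column" is the set $P_{in}$ of predecessor columns —
$j-1$ inside a node, the last columns of all parent nodes at a node's first
column — and

$$H_{i,j} = \max_{p \in P_{in}} \max \{\, H_{i-1,p} + \mathrm{sub}(N_p, Q_i),\;
H_{i-1,j} + \Delta,\; H_{i,p} + \Delta,\; 0 \,\}$$

with a linear gap penalty $\Delta$ and a substitution matrix
(BLOSUM62 by default). The floor at 0 makes the alignment local; traceback
starts at the best cell and follows score provenance across node
boundaries, yielding the node path, intervals, CIGAR and identity.

DNA queries can be aligned directly and *frameshift-aware*: DP rows are
nucleotides, and each row is treated as a potential third codon position.
The substitution move consumes the codon ending at row $i$
($H_{i-3,p} + \mathrm{sub}(\mathrm{trans}(N[i-2,i]), \cdot)$), a codon may be
consumed against a target gap ($H_{i-3,j} + \Delta$) and a target residue
against a query gap ($H_{i,p} + \Delta$), and two penalized jumps
$H_{i-4,p} + \sigma$ and $H_{i-2,p} + \sigma$ consume four or two
nucleotides against one residue — a single-nucleotide insertion or deletion
that shifts the reading frame. Only these jumps change the frame modulo 3,
so a planted single-nucleotide indel must appear as exactly one σ-jump on
the traceback whenever σ is cheaper than the alternatives (with the
defaults, one jump at −4 always beats a jump-plus-gap detour at −7). The σ
jumps carry no substitution term, so a jump replaces that codon's diagonal
score. Both strands are attempted; rows with $i < 3$ admit no codon and
out-of-range indices are treated as unavailable moves. Stop codons do not
terminate the DP — frames are unreliable, which is the point of this mode —
they simply score as `*` under the matrix.

For seeding, DNA queries are translated in all six frames (standard code,
partial codons dropped, `N`-containing codons as `X`, stops as `*`) and the
hits pooled per graph before ranking by total hit count.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 5 | seed length (residues) |
| `w` | 3 (CLI) / 1 | minimizer window, in k-mers; `w = 1` = plain k-mers |
| `seed_limit` | 0 | max MSAs stored per seed; 0 = unlimited |
| `sub_matrix` | BLOSUM62 | any BLOSUM/PAM matrix shipped with Biostrings |
| `gap_penalty` Δ | −3 | per gap column, linear |
| `frameshift_penalty` σ | −4 | per single-nucleotide jump |
| `min_identity` | 0 | report-all; raise to filter weak alignments |
| `min_len_frac` | 0 | minimum query fraction covered |
| `align_limit` | 5 | candidate graphs aligned per query; 0 = all |
| `unknown_penalty` | −4 | score for residue pairs absent from the matrix |

Δ and σ have no canonical published values for this scoring scheme; the
defaults were fixed once so that a frameshift jump (σ) is slightly worse
than a mismatch but much better than the σ+Δ detour, and they are
recorded in every log line and overridable everywhere. `min_identity` of
0.5 together with `min_len_frac` of 0.5 is a sensible reporting filter for
real screens; the package default reports everything so downstream filters
see the full picture.

## Numerical and determinism choices

* **Identity** is identical columns over *all* alignment columns including
  gap columns — the stricter of the common conventions. Frameshift-jump
  columns count as non-matching.
* **Traceback ties**: substitution > target gap > query gap > frameshift
  jumps; among predecessor columns with equal score the smallest column
  wins; among co-optimal cells the largest query position, then the largest
  target column. All outputs are therefore byte-stable.
* **Node ids** are consecutive integers in construction order (a valid
  topological order), renumbered after compaction; GFA segment names are
  their decimal strings.
* Equal-score comparisons in the traceback are exact: every score is an
  integer combination of matrix entries and penalties held in doubles.
* The two DP kernels are column-vectorized: the max over predecessor
  columns is one vector, and the within-column gap chain
  $H_i = \max(m_i, H_{i-\delta} + \Delta)$ is a cummax prefix scan.
  Provenance is recomputed only along the traceback, so no move matrices
  are stored.
* Degenerate inputs: all-gap MSA rows are rejected (their path would be
  empty); all-gap columns produce no nodes; sequences shorter than $k$
  yield no seeds, and in minimizer mode a sequence shorter than $k+w-1$ but
  at least $k$ long contributes its single smallest $k$-mer. `X` and `*`
  are ordinary alphabet symbols throughout.

## What the synthetic generator does and does not emulate

`make_family()` mutates a random ancestor *in alignment coordinates*:
per-column substitutions, per-row deletion events, and insertion events
realized as extra columns gapped in every other row. This yields valid,
gap-bearing MSAs with no external aligner and exact ground truth. Queries
are degapped rows; DNA queries are fixed-codon back-translations with
planted single-nucleotide indels spaced more than $3k$ nucleotides apart so
seeding survives. `make_panproteome()` assigns families pairwise disjoint
residue alphabets, so families share no $k$-mer and the expected
wrong-alignment fraction is exactly zero — which the end-to-end test
verifies.

What this does *not* emulate: realistic phylogenetic correlation between
rows, codon-usage variation, sequencing error beyond planted indels, and
families that genuinely share homologous stretches. Passing tests therefore
demonstrate algorithmic correctness (recurrences, traceback, ranking,
round-trips), not recall on real, seed-sharing proteomes, where
`seed_limit`, `k` and the identity filter trade sensitivity against
runtime.

## Problem sizes in the shipped tests

The suite runs at desk scale, chosen so the whole suite completes in well
under a minute while still exercising every path: 1000 random DAGs of at
most 12 nodes against the brute-force best-path-spelling oracle; 200
back-translated queries with 0/1/2 planted indels; 1000 random strings for
the minimizer deque against the naive window minimum; families of 3–5 rows
and 40–60 residues for the end-to-end pipeline.

## Known limitations

* Linear gaps only — no affine model — and no banding, X-drop or
  bit-parallel acceleration; the full table is computed, so very long
  queries against very sparse (wide) MSAs are the slow case.
* One graph per protein: variation *between* families (fusion, domain
  shuffling) is invisible.
* GFA dialect is deliberately narrow (integer segment names, `0M`
  overlaps); GFA2/rGFA are out of scope.
* The `threads` argument is accepted for interface stability but alignment
  currently runs sequentially; ordering of output records would be
  identical either way.
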