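# protgraph

Build, index and align to **panproteome graphs** in R.

Bacterial populations are too diverse for one linear reference genome:
queries carrying non-reference alleles align poorly or not at all, and at
larger phylogenetic distances DNA identity collapses long before protein
identity does. `protgraph` represents the protein-coding content of a
species or clade as a *panproteome* — a collection of small directed
acyclic sequence graphs, one per protein (or protein cluster), each built
from that protein's multiple sequence alignment (MSA) — and aligns
amino-acid or DNA queries back to the best-matching graphs.

The package covers the full pipeline:

* **MSA → DAG.** Each (column, distinct residue) pair of the alignment
  matrix $M \in (A\cup\{-\})^{n\times m}$ becomes a labelled node; edges
  connect residues consecutive in some row after skipping gaps; every row
  is a named path spelling the degapped sequence. Linear stretches are
  compacted only where the identical set of paths traverses them, so P-line
  fidelity is preserved. Graphs are read and written as GFA1.
* **Seed index.** All $k$-mers, or $(w,k)$-minimizers found with a
  monotone-deque sliding-window minimum, of every degapped row map each
  seed to the MSAs containing it, ordered by the seed's *normalized count*
  (occurrences ÷ rows of that MSA) and optionally truncated to the top
  `seed_limit` entries.
* **Graph-aware local alignment.** A partial-order extension of
  Smith–Waterman with a substitution matrix (BLOSUM62 by default) and a
  linear gap penalty $\Delta$: at a node's first column the recurrence
  maximizes over the last columns $p \in P_{in}$ of all parent nodes,
  $$H_{i,j} = \max_{p\in P_{in}}\max\{H_{i-1,p}+\mathrm{sub}(N_p,Q_i),\;
  H_{i-1,j}+\Delta,\; H_{i,p}+\Delta,\; 0\}.$$
  DNA queries may be aligned *frameshift-aware*: each nucleotide row is a
  potential third codon position, and two extra diagonal jumps consuming 4
  or 2 nucleotides at penalty $\sigma$ model single-nucleotide insertions
  and deletions that shift the reading frame. Alignments are emitted as GAF
  with score, identity, frame, frameshift-count and CIGAR tags.
* **Synthetic fixtures.** Deterministic family/query generators (mutations
  applied in alignment coordinates; fixed-codon back-translation with
  planted indels) for testing and benchmarking without external tools.

## Worked example

The packaged three-sequence MSA (`-MEPTPEQ`, `---T--MA`, `MSETQSTQ`)
exercises gap bridging and compaction:

```r
library(protgraph)
x <- example_msa()
g <- compact_graph(build_graph_from_msa(x))
write_gfa(g, "example.gfa")
```

The GFA shows the merged `PTPE` stretch and one path per input row — note
row 2's path jumps from its `T` node straight to `MA`, bridging its gaps:

```
S	1	MS
S	2	M
S	3	E
S	4	PTPE
S	5	T
S	6	QST
S	7	MA
S	8	Q
...
P	r1	2+,3+,4+,8+	*
P	r2	5+,7+	*
P	r3	1+,3+,5+,6+,8+	*
```

Aligning a near-copy of row 3 (one substitution at the end):

```r
align_protein("MSETQSTA", g, align_config(), query_name = "q1")
#> alignment of 'q1' to graph 'example': score 33, identity 1, nodes 1>3>5>6
```

The local optimum spans the first seven residues (the trailing `A` vs `Q`
mismatch is dropped by the local floor), giving identity 1 over the aligned
block and BLOSUM62 self-score 33. As a GAF record:

```
q1	8	0	7	+	>1>3>5>6	7	0	7	7	7	255	AS:i:33	id:f:1	gi:Z:example	fr:Z:none	fs:i:0	bt:A:1	cg:Z:7=
```

A DNA query back-translated from row 3 with one extra nucleotide planted
mid-sequence aligns through the frameshift with exactly one penalized jump:

```r
dna <- back_translate("MSETQSTQ")
mut <- plant_indels(dna, 1, spacing = 6)$dna
align_dna_frameshift(mut, g, align_config())
#> alignment of 'query' to graph 'example': score 29, identity 0.875, nodes 1>3>5>6>8, 1 frameshift(s)
```

End-to-end, the same steps run from the shell via the installed script
(`exec/protgraph` under the package library):

```sh
protgraph build_gfa   --in-dir msas/ --out-dir gfas/
protgraph build_index --in-dir msas/ --seeding minimizer -k 5 -w 3 --seed-limit 0 -o index.bin
protgraph align       --in-dir gfas/ --index index.bin -q queries.fa --type dna -o out.gaf
```

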