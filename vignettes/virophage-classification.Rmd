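---
title: "Identifying and classifying virophage genomes with virotax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and classifying virophage genomes with virotax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Virophages are small dsDNA viruses that parasitise the replication
machinery of giant viruses during co-infection of a protist host. Their
genomes (typically 15–45 kb) are extraordinarily diverse: apart from a
four-gene morphogenesis module — major capsid protein (MCP), penton,
FtsK-HerA packaging ATPase and an Adenain-like protease (PRO) — most of
their gene content is unique to individual genomes. Any workable
taxonomy therefore has to rest on that conserved module, and on explicit
numeric demarcation rules that a program (not only an expert) can apply.
`virotax` implements such a rule set end to end: marker detection with
profile HMMs, class- and family-level assignment with bit-score cutoffs,
genome quality control, and dereplication/grouping by nucleotide and
amino-acid identity. A closely related lineage, the polinton-like
viruses (PLVs), encodes an analogous but non-homologous capsid module;
the pipeline flags those separately through a PLV-specific ATPase
profile rather than forcing them into the class.

## Classification model

### Class demarcation

Predicted proteins are searched against the marker profiles with
`hmmsearch`. A hit requires a **full-sequence** bit score ≥ 40 and
E ≤ 0.01; per-domain scores are not used, because the demarcation
thresholds are calibrated on full-sequence scores. Per genome and
marker, only the best hit is kept (ties break by lower E-value, then
profile name). A genome is assigned to the class when its best MCP hit
reaches **50 bits**. The MCP-only rule is deliberate: the three other
markers confirm the assignment and measure completeness (the
`n_markers_detected` column), but they do not gate it, so partial
genomes missing an ATPase or PRO gene are still recognised. Genomes with
at least three of the four markers but no qualifying MCP are flagged
(`candidate_flag`) for manual review rather than silently dropped. The
PLV flag is only reported for genomes *not* assigned to the class; for
class members the raw PLV hit, if any, remains visible in the marker
table.

True marker proteins typically score in the hundreds of bits against
their profiles, while unrelated proteins fall well below 10, so the
40/50-bit thresholds sit in a wide empty margin rather than on a knife
edge.

### Family assignment

Within the class, a genome is assigned to one of seven family-level
groups by the best BLASTP hit of its highest-scoring MCP protein against
a labeled reference MCP database. The cutoff for family *F* is the
highest bit score obtained by any query from outside *F* against a
subject in *F*, with self-hits omitted — i.e. exactly the score level at
which in-group and out-group sequences become indistinguishable. For
that reason the comparison is **strictly greater**: a query scoring
exactly the cutoff is left `unclassified_within_class`. A family that
receives no out-of-group hit at all gets a configurable floor
(default 50 bits) so that assignment can never ride on an arbitrarily
weak best hit. When a genome encodes several MCPs, the highest-scoring
one carries the assignment. Whether cutoffs should be derived per family
or per reference sequence is genuinely ambiguous; per family is used,
being the more conservative (higher) cutoff.

### Genome quality control

*Terminal repeats.* The detector returns the longest exact prefix that
equals a suffix (direct, DTR) or the reverse complement of a suffix
(inverted, ITR), at least 10 nt, capped at 5 kb and at half the sequence
length so the two copies cannot overlap. Matches are exact by design —
the repeats that evidence a complete circularly-permuted genome are
identical copies. When both kinds tie at the maximal length, the direct
repeat wins (it is the actionable one). Only DTRs are trimmed: the 3'
copy is removed, and if an ORF would span the resulting junction of the
now circular genome unit, the sequence is rotated by the smallest shift
that places the junction in an intergenic gap, so downstream gene
calling never truncates a gene across the ends.

*Integrated elements.* Contigs are screened for intergenic regions
≥ 1 kb — the typical footprint of eukaryotic host sequence annotated
with a prokaryote-style gene caller — and for GC shifts. The original
procedure relied on expert inspection of GC profiles; the automated
stand-in computes non-overlapping 100-nt GC windows and reports a
boundary wherever the mean GC over 2 kb on one side differs from the
other side by ≥ 0.05 (both parameters configurable). Runs of adjacent
qualifying window edges are collapsed to the edge of maximal difference,
so a clean host/element junction yields one boundary. With reference
virophage proteins supplied, segments whose genes have no BLASTP hit at
≥ 30 bits are flagged host-like.

*Completeness.* Categories are assigned by first match in a fixed
precedence order: isolate reference → integrated with host flanks
≥ 2 kb on both sides → DTR → ITR → external completeness estimate ≥ 90 %
→ linear ≥ 25 kb → partial. The precedence makes the categories disjoint
and every genome receives exactly one. The 25-kb floor reflects the
median length of complete virophage genomes; the external estimate is an
optional input column — this package does not compute it.

## Dereplication and grouping

### vOTUs

Genomes are dereplicated at the standard dsDNA-virus cutoff: 95 % ANI
over ≥ 85 % aligned fraction (AF) of the shorter sequence. Clustering is
greedy longest-first: genomes sorted by decreasing length (ties:
lexicographic id) either join the first existing representative they
match or found a new cluster, so representatives are always the longest
member. Membership is tested against representatives only — the
standard protocol for this cutoff — not by complete linkage. Isolate or
reference genomes can be designated preferred representatives
(`overrides`), mirroring the practice of representing a vOTU by its
best-curated genome rather than its longest contig.

ANI itself comes from local nucleotide alignments (BLASTN, word size
11): ANI is the alignment-length-weighted mean identity and AF the
merged aligned length on the shorter genome divided by its length. The
backend is pluggable: `ani_from_coords()` ingests a whole-genome
aligner's coordinate output in "show-coords" layout, for
bit-compatibility with pipelines built on such aligners.

### Genome-wide AAI groups

For every genome pair, protein best hits with ≥ 50 % coverage of both
query and subject at E ≤ 1e-5 define the shared gene set; AAI is their
mean percent identity across both search directions. Each pair also gets
a *normalised cumulative bit score*: the mean of the two directional
bit-score sums divided by the smaller of the two genomes' self-hit score
sums. The normalisation denominator is not uniquely defined in the
literature this protocol descends from; the smaller self-sum was chosen
because it makes the quantity symmetric and bounded by 1 (a genome
against itself scores exactly 1), and the raw sums are retained on each
edge so alternative normalisations can be recomputed. Edges below 0.05
are discarded and the remaining AAI-weighted graph is clustered with
Markov clustering at inflation 1.1 — low inflation yields the coarse,
family-scale granularity wanted here.

### The Markov clustering implementation

MCL is implemented in-package as the textbook dense process: self-loops
at each node's maximum incident weight, column-stochastic normalisation,
then repeated expansion (matrix squaring), inflation (elementwise power
+ renormalisation) and pruning of entries below 1e-6 (followed by
renormalisation), until the maximum entry change falls below 1e-8 or 200
iterations. Clusters are read from attractor rows (positive diagonal);
each node goes to the attractor with the largest flow into it, ties
breaking to the lexicographically smallest attractor, which also merges
symmetric attractor systems into one cluster. Only the inflation
parameter is fixed by the protocol; expansion power, pruning threshold
and convergence tolerance are this package's numerical choices and are
exposed as arguments.

One numerical detail deserves a note: after each iteration the flow
matrix is quantized to 12 decimals. On graphs with exact symmetries, a
node can be *mathematically* tied between two attractors; without
quantization, sub-1e-15 differences in floating-point summation order
get amplified exponentially by inflation until one side wins — so the
output would depend on the linear-algebra backend. Quantization keeps
the process invariant under graph automorphisms (noise cannot outgrow
the quantum between iterations), letting true ties survive to the
extraction step where the deterministic lexicographic rule resolves
them. Real-valued AAI weights essentially never tie, so this only
matters for degenerate (e.g. binary-weighted) inputs — but those are
exactly the inputs used to validate the implementation against an
independent reference.

## Profile building

Marker reference proteins are compared all-vs-all with BLASTP, the
bit-score graph is clustered with the same MCL implementation at
inflation 5 (high inflation: fine, subfamily-scale granularity), and
every cluster with ≥ 10 members is aligned with MAFFT and compiled into
a profile with `hmmbuild`. The ≥ 10 floor keeps profiles from being
built on a handful of sequences that cannot support a position-specific
model. The edge weight for the pre-MCL graph is the best bit score seen
in either direction for a pair — the exact weighting is not prescribed
by the protocol and is configurable in spirit: any monotone similarity
gives the same clusters when families are well separated.

## Gene calling

The built-in six-frame caller enumerates maximal stop-to-stop ORFs
≥ 50 aa under translation table 11, treating contig ends as stops; Ns
translate to X and do not split an ORF. It is a deterministic fallback,
*not* a re-creation of a trained gene finder: it has no start-codon
model, no GC-frame scoring, and will merge a gene with upstream in-frame
sequence up to the previous stop. Analyses that must reproduce an
external caller's gene models should ingest them via
`load_external_gene_calls()`, which parses the common
`id # start # end # strand` protein-header dialect. All coordinates in
the package are 1-based and inclusive; the ingestion function is the
only place a convention conversion happens.

## The synthetic data generator

The generator (`fixture_spec()` / `generate_fixture_set()`) emulates the
study conditions the pipeline is designed for: by default seven
family-level groups of ten genomes each, genome lengths drawn from
15–45 kb, viral elements at GC 0.40 against host flanks at GC 0.60,
within-family marker identity 0.7 and cross-family ancestor identity
forced ≤ 0.35, plus two PLV-like genomes, one markerless decoy and three
planted near-duplicate groups at 98 % ANI for dereplication truth.
Marker proteins are random ancestors diversified by point substitution;
the per-descendant substitution rate is solved from the target pairwise
identity ((1−r)² + r²/19 = t). Genes are back-translated with uniform
codon choice and embedded between in-frame stop codons, so the fallback
caller recovers exactly the planted protein; intergenic GC is solved
analytically so whole-element GC lands on target. Host flanks and
junction pads are built from sequence interleaved with a stop cassette
(`TTAATTAATTAA`, which stops all six frames and is its own reverse
complement), guaranteeing the ≥ 1 kb intergenic junction gap that the
integration screen keys on.

What the generator does **not** emulate: realistic phylogenetic
evolution (no indels, no rate heterogeneity, no codon bias), real
virophage sequence motifs (synthetic markers are not homologous to any
published profile set), gene-content variation within families, or
sequencing artefacts. Consequently, passing the recovery tests shows
that the pipeline's machinery — search, thresholds, clustering,
bookkeeping — is correct under clean conditions with known truth; it
does not measure sensitivity on real, noisy, partially assembled data.
Conversely, the synthetic families are *harder* than real data in one
respect: they are so divergent from each other that out-of-group BLAST
hits rarely exist, so family cutoffs usually fall back to the 50-bit
floor rather than being data-derived.

## Validation strategy and problem sizes

Every non-trivial primitive is checked against an independent oracle at
small scale: the ORF caller against a character-level six-frame
enumeration (sequences up to 2 kb), the terminal-repeat detector against
an exhaustive prefix/suffix scan (up to 2 kb, planted and random),
family cutoffs against per-family exhaustive searches (3 families × 10
references), pairwise AAI against global pairwise alignments, and the
MCL implementation against pinned partitions from an independently
written dense implementation for **all** 1099 binary graphs on ≤ 5
nodes. End-to-end recovery runs on the default fixture set (79 genomes);
threshold boundary behaviour (50-bit class call, 0.60 coverage filter,
10-nt repeat floor, 25-kb completeness floor) is asserted exactly at the
flip points. These sizes were chosen so the full suite exercises every
code path in a few minutes on one CPU.

## Known limitations

* The published marker profile set and reference MCP database are not
  bundled; the package builds equivalent-shaped resources from any
  reference proteins, and treats published profile files (HMMER3
  format) as drop-in inputs.
* The completeness estimate of category `checkv_high` is an external
  input; no AAI-based completeness model is included.
* The integration screen automates a procedure that was originally
  expert inspection; its GC-shift rule (0.05 over 2-kb flanks) is a
  reproducible default, not a learned boundary detector, and both
  parameters should be revisited for unusual host/element GC contrasts.
* Phylogeny-based placement is out of scope; the batch report carries a
  `phylogeny_label` column for externally supplied placements.
* `hmmsearch`, BLAST+ and MAFFT must be installed; the package fails
  with a clear message when an executable is missing.
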