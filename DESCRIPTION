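Package: virotax
Title: Identification, Taxonomic Assignment and Dereplication of Virophage Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to detect the four conserved virophage morphogenesis genes
    (major capsid protein, penton, FtsK-HerA ATPase, maturation protease) in
    nucleotide contigs using profile hidden Markov models, assign genomes to
    the Maveriviricetes class and to seven family-level groups by best-hit
    protein comparison with per-family bit-score cutoffs, flag polinton-like
    viruses, perform genome quality control (terminal-repeat detection and
    trimming, integrated-element screening, completeness categories), and
    dereplicate or group genomes by average nucleotide identity and
    genome-wide amino-acid identity with Markov clustering. Profile searches
    and pairwise alignments are delegated to HMMER, BLAST+ and MAFFT, which
    must be available on the system path. A synthetic-fixture generator with
    known truth tables supports hermetic testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0)
SystemRequirements: HMMER (>= 3.1), BLAST+ (>= 2.10), MAFFT
Config/testthat/edition: 3
RoxygenNote: 7.3.3
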