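# virotax

Identification, taxonomic assignment and dereplication of **virophage**
genomes from assembled contigs.

Virophages are small dsDNA viruses (genomes typically 15–45 kb) that
replicate only during co-infection of a protist host with a giant virus.
They form the class *Maveriviricetes* and are recognisable by a conserved
morphogenesis gene module: a double jelly-roll major capsid protein (MCP),
a penton (minor capsid) protein, an FtsK-HerA-family packaging ATPase and
an Adenain-like maturation protease (PRO). Related polinton-like viruses
(PLVs) carry an analogous but non-homologous module and must be kept
apart. `virotax` implements the profile-HMM and best-hit classification
workflow used to delineate this taxonomy, for R users and for the shell.

## What it does

* **Marker detection** — searches predicted proteins against marker
  profile HMMs with `hmmsearch` (full-sequence score ≥ 40 bits,
  E ≤ 0.01), reduces hits to the best hit per genome per marker, and
  applies the class demarcation rule: a genome enters *Maveriviricetes*
  when at least one MCP profile scores ≥ 50 bits. Genomes with three of
  the four markers but no qualifying MCP are flagged as candidates;
  non-members hitting the PLV-specific ATPase profile at ≥ 50 bits are
  flagged as possible PLVs.
* **Family assignment** — class members are assigned to one of seven
  family-level groups (*Ruviroviridae*, *Maviroviridae*,
  *Sputniviroviridae*, *Dishuiviroviridae*, *Omnilimnoviroviridae*,
  *Gulliviroviridae*, *Burtonviroviridae*) by the best BLASTP hit of
  their MCP against a labeled reference database. The per-family
  bit-score cutoff is the highest score any out-of-group sequence
  achieves against that family (self-hits omitted); assignment requires
  strictly exceeding it.
* **Genome QC** — exact direct/inverted terminal-repeat detection
  (≥ 10 nt), DTR trimming with junction-aware rotation, screening for
  integrated elements (intergenic regions ≥ 1 kb, GC shifts in 100-nt
  windows), and completeness categories: isolate reference → integrated
  with ≥ 2 kb host flanks → DTR → ITR → external estimate ≥ 90 % →
  linear ≥ 25 kb → partial.
* **Dereplication and grouping** — greedy longest-first vOTU clustering
  at 95 % ANI over 85 % of the shorter sequence, and genome-wide AAI
  (gwAAI) groups from a filtered AAI graph (protein best hits at 50 %
  query/subject coverage, E ≤ 1e-5; edges kept at normalised cumulative
  bit score ≥ 0.05) clustered with an in-house Markov clustering (MCL)
  implementation at inflation 1.1.
* **Profile building** — rebuilds marker profile HMMs from reference
  proteins: all-vs-all BLASTP, Markov clustering at inflation 5, one
  MAFFT alignment + `hmmbuild` profile per cluster of ≥ 10 sequences.
* **Synthetic fixtures** — a generator for family-structured genomes
  with planted markers, terminal repeats, host flanks, near-duplicates
  and truth tables, so the full pipeline is testable hermetically.

External searches run through HMMER (`hmmsearch`/`hmmbuild`), BLAST+
(`blastp`/`blastn`/`makeblastdb`) and MAFFT, which must be on `PATH`.

## Worked example

Everything below is runnable without any downloads: the fixture
generator plays the role of a sequenced dataset, and the marker profiles
are built from its reference proteins.

```r
library(virotax)

spec <- fixture_spec(seed = 11, n_families = 3, genomes_per_family = 10,
                     genome_length_range = c(15000L, 22000L),
                     duplicate_groups = 0, n_plv = 1, n_decoys = 1)
fx <- generate_fixture_set(spec)

profiles <- build_marker_profiles(fx$marker_refs, tempfile(fileext = ".hmm"))
profiles
#> <profile_set> 13 profiles (3 MCP, 3 Penton, 3 ATPase, 3 PRO, 1 PLV)

cutoffs <- derive_cutoffs(fx$ref_db)
head(cutoffs, 3)
#>              family cutoff provenance
#> 1     Maviroviridae     50      floor
#> 2     Ruviroviridae     50      floor
#> 3 Sputniviroviridae     50      floor

report <- classify_batch(fx$genomes[c("fam01_g02", "fam02_g07",
                                      "plv_g01", "decoy_g01")],
                         profiles, db = fx$ref_db, cutoffs = cutoffs)
report[, c("genome_id", "in_maveriviricetes", "family", "mcp_score",
           "n_markers_detected", "possible_plv")]
#>   genome_id in_maveriviricetes        family mcp_score n_markers_detected possible_plv
#> 1 fam01_g02               TRUE Ruviroviridae    1573.5                  4        FALSE
#> 2 fam02_g07               TRUE Maviroviridae    1096.9                  4        FALSE
#> 3   plv_g01              FALSE          <NA>        NA                  0         TRUE
#> 4 decoy_g01              FALSE          <NA>        NA                  0        FALSE
```

Reading the output: both family genomes carry all four morphogenesis
markers, their MCP scores (≈1100–1600 bits) are far above the 50-bit
class threshold, and their best reference hits clear the per-family
cutoffs — here the fallback 50-bit floor, because the synthetic families
are too divergent to produce any out-of-group BLAST hit. The PLV-like
genome has no virophage marker but hits the PLV ATPase profile, and the
markerless decoy is left unassigned.

The same workflow is available from the shell:

```sh
inst/scripts/virotax simulate --outdir fixtures/ --seed 11
inst/scripts/virotax classify --input genomes.fna --profiles markers.hmm \
    --ref-db ref_mcp.faa --labels ref_mcp_labels.tsv --out report
inst/scripts/virotax qc --input genomes.fna --outdir qc/
inst/scripts/virotax cluster-votu --input genomes.fna --out votus.tsv
```

## Package layout

| Path | Contents |
| --- | --- |
| `R/genome_io.R` | FASTA I/O, six-frame ORF fallback caller, external gene-call ingestion |
| `R/genome_qc.R` | terminal repeats, DTR trimming, integration screen, completeness |
| `R/marker_detection.R` | profile sets, marker search, class demarcation, profile building |
| `R/taxonomy.R` | reference databases, family cutoffs, best-hit assignment, batch classification |
| `R/clustering.R` | ANI/vOTU dereplication, AAI graph, Markov clustering |
| `R/fixtures.R` | synthetic data generator with truth tables |
| `R/cli.R`, `inst/scripts/virotax` | pipeline commands and the CLI |

See `vignettes/virophage-classification.Rmd` for the methods, parameter
rationale and limitations.
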