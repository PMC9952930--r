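test_that("marker families hit the identity targets and stay apart", {
  spec <- fixture_spec(seed = 301, n_families = 3, genomes_per_family = 6,
                       marker_identity = 0.9)
  mk <- generate_marker_families(spec)
  # mean pairwise within-family identity near the target
  idents <- unlist(lapply(mk$families, function(fam) {
    sapply(fam, function(seqs) {
      pairs <- combn(length(seqs), 2)
      mean(apply(pairs, 2, function(p) {
        virotax:::positional_identity(seqs[p[1]], seqs[p[2]])
      }))
    })
  }))
  expect_lt(abs(mean(idents) - 0.9), 0.03)
  # ancestors of different families stay below the divergence ceiling
  for (m in names(mk$ancestors)) {
    anc <- mk$ancestors[[m]]
    for (i in seq_along(anc)) for (j in seq_len(i - 1)) {
      expect_lte(virotax:::positional_identity(anc[[i]], anc[[j]]), 0.35)
    }
  }
  # determinism: the same spec yields identical sequences
  mk2 <- generate_marker_families(spec)
  expect_identical(mk$families, mk2$families)

  # single family: no cross-family constraint to satisfy
  one <- generate_marker_families(fixture_spec(seed = 302, n_families = 1,
                                               genomes_per_family = 3))
  expect_length(one$families, 1)
})

test_that("generated genomes honour DTR, GC and marker-coordinate truth", {
  spec <- fixture_spec(seed = 311, n_families = 1, genomes_per_family = 1,
                       genome_length_range = c(16000L, 16000L),
                       dtr_length = 20L)
  mk <- generate_marker_families(spec)
  markers <- vapply(virotax:::VIROPHAGE_MARKERS,
                    function(m) mk$families[[1]][[m]][1], character(1))
  res <- generate_genome("t1", markers, spec, seed = 312)
  s <- res$genome$sequence
  expect_equal(substr(s, 1, 20), substr(s, nchar(s) - 19, nchar(s)))
  expect_equal(res$dtr_length, 20L)

  # genome GC on target when no flanks are present
  spec2 <- fixture_spec(seed = 313, gc_element = 0.40)
  res2 <- generate_genome("t2", markers, spec2, seed = 314)
  expect_lt(abs(virotax:::gc_content(res2$genome$sequence) - 0.40), 0.02)

  # planted marker coordinates reproduce the marker proteins via the caller
  calls <- call_orfs(res2$genome)
  for (i in seq_len(nrow(res2$markers))) {
    row <- res2$markers[i, ]
    hit <- calls[calls$start == row$start & calls$end == row$end &
                   calls$strand == row$strand, ]
    expect_equal(nrow(hit), 1, info = row$marker)
    expect_equal(hit$protein, unname(markers[row$marker]))
  }
})

test_that("host flanks create detectable junctions with intergenic gaps", {
  spec <- fixture_spec(seed = 321, n_families = 1, genomes_per_family = 1,
                       genome_length_range = c(24000L, 24000L),
                       gc_element = 0.35, gc_host = 0.60,
                       host_flank_length = 5000L)
  mk <- generate_marker_families(spec)
  markers <- vapply(virotax:::VIROPHAGE_MARKERS,
                    function(m) mk$families[[1]][[m]][1], character(1))
  res <- generate_genome("h1", markers, spec, seed = 322)
  n <- nchar(res$genome$sequence)
  calls <- call_orfs(res$genome)
  scr <- screen_integration(res$genome, calls)
  # a >= 1 kb intergenic gap at each element/host junction
  gaps <- scr$long_intergenic_regions
  expect_true(any(gaps$start <= 5000 - 500 & gaps$end >= 5000))
  expect_true(any(gaps$start <= n - 5000 & gaps$end >= n - 5000 + 500))
  # GC boundaries within 500 nt of the true junctions
  expect_true(any(abs(scr$candidate_boundaries - 5000) <= 500))
  expect_true(any(abs(scr$candidate_boundaries - (n - 5000)) <= 500))
})

test_that("fixture sets are reproducible on disk with verified checksums", {
  spec <- fixture_spec(seed = 331, n_families = 2, genomes_per_family = 2,
                       genome_length_range = c(15000L, 16000L),
                       duplicate_groups = 0, n_plv = 0, n_decoys = 0)
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  m1 <- emit_fixture_set(spec, d1)
  m2 <- emit_fixture_set(spec, d2)
  # files exist and recorded checksums verify
  for (f in names(m1$files)) {
    path <- file.path(d1, f)
    expect_true(file.exists(path), info = f)
    expect_equal(unname(tools::md5sum(path)), m1$files[[f]], info = f)
  }
  # same seed, byte-identical outputs
  expect_equal(m1$files, m2$files)
  # reference/query split is disjoint and covers all genomes
  ref <- read_genomes(file.path(d1, "reference_genomes.fna"))
  qry <- read_genomes(file.path(d1, "query_genomes.fna"))
  all_g <- read_genomes(file.path(d1, "genomes.fna"))
  expect_length(intersect(names(ref), names(qry)), 0)
  expect_setequal(c(names(ref), names(qry)), names(all_g))
  unlink(c(d1, d2), recursive = TRUE)
})
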