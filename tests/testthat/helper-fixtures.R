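# Shared synthetic fixtures, built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small three-family set used by module tests.
small_spec <- function() {
  fixture_spec(seed = 101L, n_families = 3L, genomes_per_family = 6L,
               genome_length_range = c(15000L, 20000L),
               duplicate_groups = 1L, n_plv = 1L, n_decoys = 1L)
}

small_fixture <- function() cached("fx_small", generate_fixture_set(small_spec()))

small_profiles <- function() {
  cached("ps_small", {
    path <- file.path(tempdir(), "small_markers.hmm")
    build_marker_profiles(small_fixture()$marker_refs, path, min_group = 5L)
  })
}

# Study-condition fixture set (seven families of ten genomes, marker
# identity 0.7) used by the acceptance suite.
default_fixture <- function() {
  cached("fx_default", generate_fixture_set(fixture_spec()))
}

default_profiles <- function() {
  cached("ps_default", {
    path <- file.path(tempdir(), "default_markers.hmm")
    build_marker_profiles(default_fixture()$marker_refs, path)
  })
}

truth_label_of <- function(fx, genome_ids) {
  fx$truth_genomes$family_label[match(genome_ids, fx$truth_genomes$genome_id)]
}
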