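# Synthetic fixture generator: family-structured virophage-like genomes
# with planted marker genes, terminal repeats, host flanks, near-duplicate
# genomes and truth tables, so the whole pipeline can be exercised without
# any external data. Synthetic markers are random proteins diversified
# within each family; they are deliberately NOT homologous to any real
# virophage profile set.

MARKER_LENGTHS <- c(MCP = NA, Penton = 300L, ATPase = 400L, PRO = 220L)
# Per-family MCP lengths are drawn from this range (large-MCP families at
# the top end mirror the spread seen across real virophage groups).
MCP_LENGTH_RANGE <- c(500L, 940L)
PLV_ATPASE_LENGTH <- 400L

# All-frame stop cassette: contains a stop codon in every forward frame
# and is its own reverse complement, so it stops every reverse frame too.
# Interleaving it into a sequence caps stop-free runs in all six frames.
STOP_CASSETTE <- "TTAATTAATTAA"

#' Specification for a synthetic fixture set
#'
#' Defaults describe the standard study conditions the generator emulates:
#' seven family-level groups of ten genomes, within-family marker identity
#' 0.7, genome lengths 15-45 kb, low-GC viral elements (0.40) against
#' higher-GC host sequence (0.60), plus three planted near-duplicate
#' groups for dereplication tests, two polinton-like-virus genomes and one
#' markerless decoy.
#'
#' @param seed integer RNG seed; the same spec always yields byte-identical
#'   output.
#' @param n_families number of family-level groups.
#' @param genomes_per_family genomes generated per family.
#' @param marker_identity target mean pairwise amino-acid identity between
#'   descendants of one family's marker (fraction in (0,1)).
#' @param genome_length_range min/max genome length in nt.
#' @param gc_element GC fraction of the viral element.
#' @param gc_host GC fraction of host flanks.
#' @param dtr_length direct-terminal-repeat length in nt, or NULL for none.
#' @param host_flank_length host-flank length in nt on each side, or NULL.
#' @param n_decoys random genomes carrying no marker at all.
#' @param n_plv genomes carrying the PLV-specific ATPase instead of the
#'   virophage markers.
#' @param decoy_genes random non-marker genes embedded per genome.
#' @param duplicate_groups number of genomes that receive two planted
#'   near-duplicate copies (for vOTU truth).
#' @param duplicate_ani target ANI (percent) of planted duplicates.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 42L, n_families = 7L,
                         genomes_per_family = 10L,
                         marker_identity = 0.7,
                         genome_length_range = c(15000L, 45000L),
                         gc_element = 0.40, gc_host = 0.60,
                         dtr_length = NULL, host_flank_length = NULL,
                         n_decoys = 1L, n_plv = 2L, decoy_genes = 3L,
                         duplicate_groups = 3L, duplicate_ani = 98) {
  stopifnot(n_families >= 1, genomes_per_family >= 1,
            marker_identity > 0, marker_identity < 1,
            gc_element > 0, gc_element < 1, gc_host > 0, gc_host < 1,
            length(genome_length_range) == 2,
            genome_length_range[1] <= genome_length_range[2])
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 genomes_per_family = as.integer(genomes_per_family),
                 marker_identity = marker_identity,
                 genome_length_range = as.integer(genome_length_range),
                 gc_element = gc_element, gc_host = gc_host,
                 dtr_length = dtr_length,
                 host_flank_length = host_flank_length,
                 n_decoys = as.integer(n_decoys), n_plv = as.integer(n_plv),
                 decoy_genes = as.integer(decoy_genes),
                 duplicate_groups = as.integer(duplicate_groups),
                 duplicate_ani = duplicate_ani),
            class = "fixture_spec")
}

# Per-descendant substitution rate giving a target pairwise identity t
# between two independently mutated descendants: solve
# (1-r)^2 + r^2/19 = t (two sites agree if both kept, or both mutated to
# the same of 19 alternatives).
mutation_rate_for_identity <- function(t) {
  (1 - sqrt(1 - (20 / 19) * (1 - t))) * 19 / 20
}

mutate_protein <- function(seq, rate) {
  aa <- strsplit(seq, "")[[1]]
  hit <- runif(length(aa)) < rate
  hit[1] <- FALSE  # keep the leading methionine
  if (any(hit)) {
    aa[hit] <- vapply(aa[hit], function(x) {
      sample(setdiff(AA_ALPHABET, x), 1)
    }, character(1))
  }
  paste(aa, collapse = "")
}

#' Generate per-family marker protein sets
#'
#' Draws one ancestral protein per marker per family (rejecting ancestors
#' with more than 35 percent identity to any other family's ancestor of
#' the same marker) and mutates independent descendants, one per genome,
#' to the spec's within-family identity target. A separate PLV ATPase
#' family provides reference proteins for the PLV profile and descendant
#' proteins for PLV-like genomes.
#'
#' @param spec a [fixture_spec()].
#' @return list with `families` (family -> marker -> character vector of
#'   descendant proteins, one per genome), `ancestors`, and `plv`
#'   (references, descendants).
#' @export
generate_marker_families <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    rate <- mutation_rate_for_identity(spec$marker_identity)
    fams <- sprintf("fam%02d", seq_len(spec$n_families))
    ancestors <- list()
    for (marker in VIROPHAGE_MARKERS) {
      anc <- character(0)
      for (f in fams) {
        len <- if (marker == "MCP") {
          sample(MCP_LENGTH_RANGE[1]:MCP_LENGTH_RANGE[2], 1)
        } else MARKER_LENGTHS[[marker]]
        repeat {
          cand <- random_protein(len)
          if (all(vapply(anc, function(a) positional_identity(cand, a) <= 0.35,
                         logical(1)))) break
        }
        anc[f] <- cand
      }
      ancestors[[marker]] <- anc
    }
    families <- setNames(lapply(fams, function(f) {
      setNames(lapply(VIROPHAGE_MARKERS, function(marker) {
        vapply(seq_len(spec$genomes_per_family), function(i) {
          mutate_protein(ancestors[[marker]][[f]], rate)
        }, character(1))
      }), VIROPHAGE_MARKERS)
    }), fams)
    plv_anc <- random_protein(PLV_ATPASE_LENGTH)
    plv <- list(
      references = setNames(
        vapply(1:10, function(i) mutate_protein(plv_anc, rate), character(1)),
        sprintf("plvref%02d", 1:10)),
      descendants = if (spec$n_plv > 0) {
        vapply(seq_len(spec$n_plv), function(i) mutate_protein(plv_anc, rate),
               character(1))
      } else character(0))
    list(families = families, ancestors = ancestors, plv = plv)
  })
}

# Reverse genetic code: amino acid -> codons (translation table 11).
codons_by_aa <- function() {
  code <- Biostrings::getGeneticCode("11")
  split(names(code), unname(code))
}

back_translate <- function(protein, codon_table) {
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(x) {
    opts <- codon_table[[x]]
    if (is.null(opts)) opts <- codon_table[["X"]] %||% "NNN"
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

# Random DNA at a target GC with the all-frame stop cassette leading every
# block, so no six-frame ORF of >= ~45 codons can survive even across a
# junction with adjacent sequence (every truncated block still starts with
# a stop in all frames). Cassette AT content is compensated so the overall
# GC stays on target.
stop_dense_dna <- function(n, gc, period = 60L) {
  if (n <= 0) return("")
  cas_len <- nchar(STOP_CASSETTE)
  block_gc <- min(0.9, gc * (period + cas_len) / period)
  out <- character(0)
  made <- 0L
  while (made < n) {
    blk <- paste0(STOP_CASSETTE, random_dna(period, block_gc))
    out <- c(out, blk)
    made <- made + nchar(blk)
  }
  substr(paste(out, collapse = ""), 1L, n)
}

#' Generate one synthetic genome with known truth
#'
#' Marker (and decoy) proteins are back-translated with uniform codon
#' choice and embedded on random strands, each bracketed by in-frame stop
#' codons so the six-frame caller recovers the exact protein. Intergenic
#' spacers are tuned so the element hits the requested GC. Optionally a
#' direct terminal repeat is appended and/or host flanks (with stop-dense
#' junction-adjacent sequence guaranteeing a >= 1 kb intergenic gap at
#' each junction) are added.
#'
#' @param genome_id id for the emitted record.
#' @param markers named character vector (marker -> protein) to embed; may
#'   be empty for decoy genomes.
#' @param spec a [fixture_spec()].
#' @param seed RNG seed for this genome.
#' @return list: genome ([genome_record()]), markers (data frame
#'   genome_id/marker/start/end/strand), element (start/end in the emitted
#'   sequence), dtr_length, flank_length.
#' @export
generate_genome <- function(genome_id, markers, spec, seed) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(seed, {
    ct <- codons_by_aa()
    rng <- spec$genome_length_range
    target_len <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
    flank <- spec$host_flank_length %||% 0L
    dtr <- spec$dtr_length %||% 0L
    pad <- if (flank > 0) 500L else 0L
    core_len <- target_len - 2L * flank - dtr - 2L * pad
    gene_prot <- c(as.list(markers),
                   setNames(lapply(seq_len(spec$decoy_genes), function(i) {
                     random_protein(sample(150:350, 1))
                   }), sprintf("decoy%02d", seq_len(spec$decoy_genes))))
    if (length(gene_prot) == 0 && core_len < 200L) {
      stop("requested genome length infeasible", call. = FALSE)
    }
    cassettes <- lapply(gene_prot, function(p) {
      paste0("TAA", back_translate(p, ct), "TAA")
    })
    coding_nt <- sum(vapply(cassettes, nchar, integer(1)))
    spacer_total <- core_len - coding_nt
    if (spacer_total < 100L * (length(cassettes) + 1L)) {
      stop("requested genome length infeasible for gene content",
           call. = FALSE)
    }
    # spacer GC chosen so the element overall meets gc_element
    coding_gc <- gc_content(paste(unlist(cassettes), collapse = ""))
    sp_gc <- (spec$gc_element * core_len - coding_gc * coding_nt) /
      spacer_total
    sp_gc <- min(max(sp_gc, 0.1), 0.9)
    n_sp <- length(cassettes) + 1L
    w <- runif(n_sp) + 0.2
    sp_len <- floor(spacer_total * w / sum(w))
    sp_len[n_sp] <- spacer_total - sum(sp_len[-n_sp])
    parts <- character(0)
    marker_rows <- list()
    pos <- flank + pad
    for (i in seq_along(cassettes)) {
      sp <- random_dna(sp_len[i], sp_gc)
      parts <- c(parts, sp)
      pos <- pos + sp_len[i]
      strand <- sample(c("+", "-"), 1)
      cas <- if (strand == "+") cassettes[[i]] else revcomp(cassettes[[i]])
      gene_len <- nchar(cassettes[[i]]) - 6L
      gstart <- pos + 4L           # first codon after the leading TAA
      gend <- pos + 3L + gene_len  # last codon before the trailing TAA
      if (names(gene_prot)[i] %in% ALL_MARKERS) {
        marker_rows[[length(marker_rows) + 1L]] <- data.frame(
          genome_id = genome_id, marker = names(gene_prot)[i],
          start = gstart, end = gend, strand = strand,
          stringsAsFactors = FALSE)
      }
      parts <- c(parts, cas)
      pos <- pos + nchar(cas)
    }
    parts <- c(parts, random_dna(sp_len[n_sp], sp_gc))
    element <- paste(parts, collapse = "")
    if (pad > 0) {
      element <- paste0(stop_dense_dna(pad, spec$gc_element),
                        element,
                        stop_dense_dna(pad, spec$gc_element))
    }
    seq <- element
    if (flank > 0) {
      seq <- paste0(stop_dense_dna(flank, spec$gc_host), seq,
                    stop_dense_dna(flank, spec$gc_host))
    }
    if (dtr > 0) seq <- paste0(seq, substr(seq, 1L, dtr))
    mk <- if (length(marker_rows)) do.call(rbind, marker_rows) else
      data.frame(genome_id = character(), marker = character(),
                 start = integer(), end = integer(), strand = character(),
                 stringsAsFactors = FALSE)
    list(genome = genome_record(genome_id, seq, source = "synthetic"),
         markers = mk,
         element = c(start = flank + 1L,
                     end = flank + 2L * pad + nchar(paste(parts, collapse = ""))),
         dtr_length = dtr, flank_length = flank)
  })
}

mutate_dna <- function(seq, rate) {
  nt <- strsplit(seq, "")[[1]]
  hit <- runif(length(nt)) < rate
  if (any(hit)) {
    nt[hit] <- vapply(nt[hit], function(x) {
      sample(setdiff(DNA_BASES, x), 1)
    }, character(1))
  }
  paste(nt, collapse = "")
}

#' Generate a complete in-memory fixture set
#'
#' Produces the full study-condition dataset described by the spec:
#' family-structured virophage genomes, PLV-like genomes, markerless
#' decoys and planted near-duplicates, together with marker reference
#' sets (for profile building), a labeled reference MCP database built
#' from half of each family's genomes, and per-genome truth.
#'
#' @param spec a [fixture_spec()].
#' @return list: genomes (named list of [genome_record()]),
#'   truth_genomes (data frame: genome_id, kind, family, votu_group,
#'   is_reference), truth_markers (data frame of planted marker
#'   coordinates), marker_refs (marker -> named protein vector, for
#'   [build_marker_profiles()]), ref_db ([family_db()]), spec.
#' @export
generate_fixture_set <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  mk <- generate_marker_families(spec)
  fams <- names(mk$families)
  genomes <- list()
  truth_g <- list()
  truth_m <- list()
  seed_i <- spec$seed
  add_genome <- function(res, kind, family, votu, is_ref) {
    genomes[[res$genome$id]] <<- res$genome
    truth_g[[length(truth_g) + 1L]] <<- data.frame(
      genome_id = res$genome$id, kind = kind,
      family = family %||% NA_character_,
      votu_group = votu, is_reference = is_ref,
      length = nchar(res$genome$sequence), stringsAsFactors = FALSE)
    if (nrow(res$markers)) truth_m[[length(truth_m) + 1L]] <<- res$markers
  }
  votu_counter <- 0L
  for (f in fams) {
    for (i in seq_len(spec$genomes_per_family)) {
      gid <- sprintf("%s_g%02d", f, i)
      seed_i <- seed_i + 1L
      markers <- vapply(VIROPHAGE_MARKERS, function(m) {
        mk$families[[f]][[m]][i]
      }, character(1))
      res <- generate_genome(gid, markers, spec, seed_i)
      votu_counter <- votu_counter + 1L
      add_genome(res, "virophage", f, votu_counter,
                 is_ref = i <= spec$genomes_per_family %/% 2L)
    }
  }
  for (i in seq_len(spec$n_plv)) {
    gid <- sprintf("plv_g%02d", i)
    seed_i <- seed_i + 1L
    res <- generate_genome(gid, c(PLV = mk$plv$descendants[i]), spec, seed_i)
    votu_counter <- votu_counter + 1L
    add_genome(res, "plv", NULL, votu_counter, FALSE)
  }
  for (i in seq_len(spec$n_decoys)) {
    gid <- sprintf("decoy_g%02d", i)
    seed_i <- seed_i + 1L
    res <- generate_genome(gid, character(0), spec, seed_i)
    votu_counter <- votu_counter + 1L
    add_genome(res, "decoy", NULL, votu_counter, FALSE)
  }
  truth_g <- do.call(rbind, truth_g)
  # planted near-duplicates: two mutated copies of the first genome of the
  # first `duplicate_groups` families, sharing that genome's vOTU
  if (spec$duplicate_groups > 0) {
    rate <- 1 - spec$duplicate_ani / 100
    srcs <- sprintf("fam%02d_g01", seq_len(min(spec$duplicate_groups,
                                               spec$n_families)))
    for (s in srcs) {
      for (k in 1:2) {
        seed_i <- seed_i + 1L
        dup_id <- sprintf("%s_dup%d", s, k)
        dup_seq <- with_seed(seed_i, mutate_dna(genomes[[s]]$sequence, rate))
        genomes[[dup_id]] <- genome_record(dup_id, dup_seq,
                                           source = "synthetic duplicate")
        src_row <- truth_g[truth_g$genome_id == s, ]
        truth_g <- rbind(truth_g, data.frame(
          genome_id = dup_id, kind = "duplicate", family = src_row$family,
          votu_group = src_row$votu_group, is_reference = FALSE,
          length = nchar(dup_seq), stringsAsFactors = FALSE))
      }
    }
  }
  truth_m <- if (length(truth_m)) do.call(rbind, truth_m) else NULL
  # marker reference sets: all virophage genomes' marker proteins (so each
  # family contributes genomes_per_family sequences per marker), plus the
  # PLV reference set
  marker_refs <- setNames(lapply(VIROPHAGE_MARKERS, function(m) {
    unlist(lapply(fams, function(f) {
      setNames(mk$families[[f]][[m]],
               sprintf("%s_g%02d:%s", f, seq_len(spec$genomes_per_family), m))
    }))
  }), VIROPHAGE_MARKERS)
  marker_refs$PLV <- mk$plv$references
  # labeled reference MCP database from the reference half of each family
  ref_ids <- truth_g$genome_id[truth_g$kind == "virophage" &
                                 truth_g$is_reference]
  ref_prot <- setNames(vapply(ref_ids, function(g) {
    f <- truth_g$family[truth_g$genome_id == g]
    i <- as.integer(sub("^.*_g", "", g))
    mk$families[[f]][["MCP"]][i]
  }, character(1)), sprintf("%s:MCP", ref_ids))
  ref_fam <- setNames(truth_g$family[match(ref_ids, truth_g$genome_id)],
                      sprintf("%s:MCP", ref_ids))
  # synthetic labels reuse the seven proposed family names when they fit
  fam_labels <- setNames(
    c(VIROPHAGE_FAMILIES, sprintf("SynFamily%02d", seq_len(spec$n_families)))[
      seq_len(spec$n_families)], fams)
  truth_g$family_label <- ifelse(is.na(truth_g$family), NA_character_,
                                 fam_labels[truth_g$family])
  ref_fam <- fam_labels[ref_fam]
  names(ref_fam) <- names(ref_prot)
  list(genomes = genomes, truth_genomes = truth_g, truth_markers = truth_m,
       marker_refs = marker_refs,
       ref_db = family_db(ref_prot, ref_fam),
       family_labels = fam_labels, spec = spec)
}

#' Write a fixture set to disk
#'
#' Emits all genomes as FASTA, the reference MCP database (FASTA + label
#' TSV), per-marker reference proteins, truth tables, and a JSON manifest
#' with the seed and md5 checksums of every file.
#'
#' @param spec a [fixture_spec()].
#' @param outdir output directory (created if needed).
#' @return the manifest (list), invisibly; also written as manifest.json.
#' @export
emit_fixture_set <- function(spec = fixture_spec(), outdir) {
  fx <- generate_fixture_set(spec)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  p <- function(x) file.path(outdir, x)
  write_genomes(fx$genomes, p("genomes.fna"))
  files <- c(files, "genomes.fna")
  ref_ids <- fx$truth_genomes$genome_id[fx$truth_genomes$is_reference]
  qry_ids <- setdiff(names(fx$genomes), ref_ids)
  write_genomes(fx$genomes[ref_ids], p("reference_genomes.fna"))
  write_genomes(fx$genomes[qry_ids], p("query_genomes.fna"))
  files <- c(files, "reference_genomes.fna", "query_genomes.fna")
  write_fasta_vector(fx$ref_db$proteins, p("ref_mcp.faa"))
  utils::write.table(data.frame(id = names(fx$ref_db$family),
                                family = unname(fx$ref_db$family)),
                     p("ref_mcp_labels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  files <- c(files, "ref_mcp.faa", "ref_mcp_labels.tsv")
  for (m in names(fx$marker_refs)) {
    f <- sprintf("marker_refs_%s.faa", m)
    write_fasta_vector(fx$marker_refs[[m]], p(f))
    files <- c(files, f)
  }
  utils::write.table(fx$truth_genomes, p("truth_genomes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, "truth_genomes.tsv")
  if (!is.null(fx$truth_markers)) {
    utils::write.table(fx$truth_markers, p("truth_markers.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, "truth_markers.tsv")
  }
  sums <- tools::md5sum(file.path(outdir, files))
  manifest <- list(seed = spec$seed, spec = unclass(spec),
                   files = as.list(setNames(unname(sums), files)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Generate proteomes with planted genome-wide AAI group structure
#'
#' Each group has an ancestral proteome; member genomes carry mutated
#' copies of every ancestral gene, so within-group AAI matches the
#' identity target while cross-group AAI is background noise.
#'
#' @param n_groups number of groups (default 3).
#' @param genomes_per_group genomes per group (default 4).
#' @param n_genes genes per proteome (default 20).
#' @param gene_length residues per gene (default 250).
#' @param identity within-group target amino-acid identity (default 0.7).
#' @param seed RNG seed.
#' @return list: proteomes (genome id -> named protein vector), truth
#'   (named integer vector of group memberships).
#' @export
generate_aai_fixture <- function(n_groups = 3L, genomes_per_group = 4L,
                                 n_genes = 20L, gene_length = 250L,
                                 identity = 0.7, seed = 1L) {
  with_seed(seed, {
    rate <- mutation_rate_for_identity(identity)
    proteomes <- list()
    truth <- integer(0)
    for (g in seq_len(n_groups)) {
      anc <- vapply(seq_len(n_genes), function(i) random_protein(gene_length),
                    character(1))
      for (j in seq_len(genomes_per_group)) {
        gid <- sprintf("grp%02d_g%02d", g, j)
        proteomes[[gid]] <- setNames(
          vapply(anc, function(p) mutate_protein(p, rate), character(1)),
          sprintf("%s_%d", gid, seq_len(n_genes)))
        truth[gid] <- g
      }
    }
    list(proteomes = proteomes, truth = truth)
  })
}
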