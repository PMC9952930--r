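# Marker-gene detection: profile HMM searches for the four conserved
# virophage morphogenesis genes (MCP, penton, FtsK-HerA ATPase, maturation
# protease PRO) plus the PLV-specific ATPase profile, and class-level
# demarcation.

VIROPHAGE_MARKERS <- c("MCP", "Penton", "ATPase", "PRO")
ALL_MARKERS <- c(VIROPHAGE_MARKERS, "PLV")

#' Create a profile set from an HMMER3 file
#'
#' A profile set couples a (multi-)profile HMMER3 text file with a mapping
#' from profile name to marker. When `marker_of` is omitted the marker is
#' inferred from the profile-name prefix (e.g. `MCP_003` is an MCP
#' profile); profiles whose marker cannot be inferred are an error.
#'
#' @param hmm_path HMMER3 text file holding one or more profiles.
#' @param marker_of optional named character vector, profile name ->
#'   marker ("MCP", "Penton", "ATPase", "PRO", "PLV").
#' @return a `profile_set` (list: hmm_path, marker_of).
#' @export
profile_set <- function(hmm_path, marker_of = NULL) {
  if (!file.exists(hmm_path)) {
    stop(sprintf("profile file not found: %s", hmm_path), call. = FALSE)
  }
  names_in_file <- hmm_profile_names(hmm_path)
  if (is.null(marker_of)) {
    marker_of <- infer_marker(names_in_file)
    names(marker_of) <- names_in_file
  }
  missing <- setdiff(names_in_file, names(marker_of))
  if (length(missing) > 0) {
    stop(sprintf("no marker mapping for profile(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- !marker_of %in% ALL_MARKERS
  if (any(bad)) {
    stop(sprintf("unknown marker label(s): %s",
                 paste(unique(marker_of[bad]), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(hmm_path = hmm_path, marker_of = marker_of),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  tab <- table(factor(x$marker_of, levels = ALL_MARKERS))
  cat(sprintf("<profile_set> %d profiles (%s)\n", length(x$marker_of),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
  invisible(x)
}

hmm_profile_names <- function(hmm_path) {
  lines <- grep("^NAME ", readLines(hmm_path), value = TRUE)
  sub("^NAME +", "", lines)
}

infer_marker <- function(profile_names) {
  m <- sub("^(MCP|Penton|ATPase|PRO|PLV).*$", "\\1", profile_names)
  m[!m %in% ALL_MARKERS] <- NA_character_
  if (anyNA(m)) {
    stop(sprintf("cannot infer marker from profile name(s): %s",
                 paste(profile_names[is.na(m)], collapse = ", ")),
         call. = FALSE)
  }
  m
}

#' Search proteins against the marker profiles
#'
#' Runs hmmsearch and keeps hits passing both the full-sequence score floor
#' and the E-value ceiling. The score is the full-sequence bit score, not
#' the per-domain score. Profile coverage is the fraction of profile
#' columns spanned by the union of reported domain alignments.
#'
#' @param proteins named character vector of proteins, or a gene-call data
#'   frame (see [call_orfs()]).
#' @param profiles a [profile_set()].
#' @param min_score minimum full-sequence bit score (default 40).
#' @param max_evalue maximum full-sequence E-value (default 0.01).
#' @return data frame of marker hits: genome_id, marker, profile_id,
#'   protein_id, bit_score, e_value, profile_coverage.
#' @export
search_markers <- function(proteins, profiles, min_score = 40,
                           max_evalue = 0.01) {
  stopifnot(inherits(profiles, "profile_set"))
  genome_of <- NULL
  if (is.data.frame(proteins)) {
    genome_of <- setNames(proteins$genome_id, protein_ids(proteins))
    proteins <- proteins_of(proteins)
  }
  empty <- data.frame(genome_id = character(), marker = character(),
                      profile_id = character(), protein_id = character(),
                      bit_score = numeric(), e_value = numeric(),
                      profile_coverage = numeric(), stringsAsFactors = FALSE)
  if (length(proteins) == 0) return(empty)
  dom <- hmmsearch_domtbl(proteins, profiles$hmm_path)
  if (nrow(dom) == 0) return(empty)
  key <- paste(dom$target, dom$query, sep = "\r")
  rows <- lapply(split(dom, key), function(d) {
    cov <- merged_interval_length(d$hmm_from, d$hmm_to) / d$qlen[1]
    data.frame(protein_id = d$target[1], profile_id = d$query[1],
               bit_score = d$full_score[1], e_value = d$full_evalue[1],
               profile_coverage = cov, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  hits <- hits[hits$bit_score >= min_score & hits$e_value <= max_evalue, ,
               drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  hits$marker <- unname(profiles$marker_of[hits$profile_id])
  hits$genome_id <- if (!is.null(genome_of)) {
    unname(genome_of[hits$protein_id])
  } else {
    sub("_[0-9]+$", "", hits$protein_id)
  }
  hits <- hits[order(hits$genome_id, hits$marker, -hits$bit_score,
                     hits$e_value, hits$profile_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("genome_id", "marker", "profile_id", "protein_id", "bit_score",
           "e_value", "profile_coverage")]
}

#' Reduce marker hits to the best hit per genome per marker
#'
#' Ties on bit score are broken by lower E-value, then lexicographic
#' profile id.
#'
#' @param hits marker-hit data frame from [search_markers()].
#' @return data frame with one row per (genome, marker); column
#'   `n_markers_detected` counts the distinct virophage markers (PLV
#'   excluded) detected for that genome.
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0) {
    out <- hits
    out$n_markers_detected <- integer()
    return(out)
  }
  ord <- order(hits$genome_id, hits$marker, -hits$bit_score, hits$e_value,
               hits$profile_id)
  hits <- hits[ord, , drop = FALSE]
  best <- hits[!duplicated(paste(hits$genome_id, hits$marker, sep = "\r")), ,
               drop = FALSE]
  counts <- tapply(best$marker, best$genome_id,
                   function(m) sum(unique(m) %in% VIROPHAGE_MARKERS))
  best$n_markers_detected <- as.integer(counts[best$genome_id])
  rownames(best) <- NULL
  best
}

#' Drop marker hits with insufficient profile coverage
#'
#' Used when exporting marker proteins for downstream alignment or
#' classification, to exclude partial gene predictions.
#'
#' @param hits marker-hit data frame.
#' @param min_cov minimum profile coverage (default 0.60).
#' @return filtered data frame.
#' @export
filter_by_profile_coverage <- function(hits, min_cov = 0.60) {
  hits[hits$profile_coverage >= min_cov, , drop = FALSE]
}

#' Class-level demarcation from a best-hit marker table
#'
#' A genome is assigned to the virophage class (*Maveriviricetes*) when its
#' best MCP hit reaches `mcp_min` bits. Genomes not assigned but with at
#' least three of the four virophage markers are flagged as candidates for
#' manual review. A qualifying hit to the PLV-specific ATPase profile marks
#' a genome as a possible polinton-like virus only when the genome is not
#' a class member (the classifier checks PLV for non-class sequences; the
#' raw hit is still visible in the table for class members).
#'
#' @param table best-hit table from [best_hits()].
#' @param genome_ids optional character vector of all genomes under
#'   consideration, so genomes with no hits at all are reported too.
#' @param mcp_min class bit-score threshold on MCP (default 50).
#' @param plv_min PLV bit-score threshold (default 50).
#' @return data frame: genome_id, in_maveriviricetes, candidate_flag,
#'   possible_plv, mcp_score, plv_score, n_markers_detected.
#' @export
assign_class <- function(table, genome_ids = NULL, mcp_min = 50,
                         plv_min = 50) {
  ids <- unique(c(genome_ids, table$genome_id))
  res <- lapply(ids, function(g) {
    t <- table[table$genome_id == g, , drop = FALSE]
    mcp <- t$bit_score[t$marker == "MCP"]
    plv <- t$bit_score[t$marker == "PLV"]
    n <- if (nrow(t)) t$n_markers_detected[1] else 0L
    in_class <- length(mcp) > 0 && max(mcp) >= mcp_min
    data.frame(genome_id = g,
               in_maveriviricetes = in_class,
               candidate_flag = !in_class && n >= 3L,
               possible_plv = !in_class && length(plv) > 0 &&
                 max(plv) >= plv_min,
               mcp_score = if (length(mcp)) max(mcp) else NA_real_,
               plv_score = if (length(plv)) max(plv) else NA_real_,
               n_markers_detected = as.integer(n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Build marker profile HMMs from reference proteins
#'
#' For each marker, reference proteins are compared all-vs-all with
#' BLASTP, the bit-score similarity graph is clustered with Markov
#' clustering (inflation 5 by default), and each cluster with at least
#' `min_group` members is aligned with MAFFT and turned into a profile
#' with hmmbuild. Profiles are named `<marker>_<k>` so the marker can be
#' recovered from the profile name.
#'
#' @param reference_proteins_by_marker named list (marker -> named
#'   character vector of proteins).
#' @param out_path destination for the combined HMMER3 file.
#' @param inflation Markov-clustering inflation (default 5).
#' @param min_group minimum cluster size that yields a profile
#'   (default 10).
#' @return a [profile_set()] for the written file; the number of clusters
#'   per marker is available via `attr(, "n_profiles")`.
#' @export
build_marker_profiles <- function(reference_proteins_by_marker, out_path,
                                  inflation = 5, min_group = 10L) {
  stopifnot(is.list(reference_proteins_by_marker),
            length(reference_proteins_by_marker) > 0)
  bad <- !names(reference_proteins_by_marker) %in% ALL_MARKERS
  if (any(bad)) {
    stop(sprintf("unknown marker label(s): %s",
                 paste(names(reference_proteins_by_marker)[bad],
                       collapse = ", ")), call. = FALSE)
  }
  tmp_files <- character()
  marker_of <- character()
  n_profiles <- setNames(integer(length(reference_proteins_by_marker)),
                         names(reference_proteins_by_marker))
  for (marker in names(reference_proteins_by_marker)) {
    seqs <- reference_proteins_by_marker[[marker]]
    clusters <- cluster_proteins_mcl(seqs, inflation = inflation)
    big <- clusters[vapply(clusters, length, integer(1)) >= min_group]
    if (length(big) == 0) {
      stop(sprintf("insufficient references for marker %s: no cluster with >= %d sequences",
                   marker, min_group), call. = FALSE)
    }
    # stable ordering: by decreasing size, ties by first member id
    ord <- order(-vapply(big, length, integer(1)),
                 vapply(big, function(m) sort(m)[1], character(1)))
    big <- big[ord]
    for (k in seq_along(big)) {
      name <- sprintf("%s_%03d", marker, k)
      aln <- mafft_align(seqs[big[[k]]])
      f <- tempfile(fileext = ".hmm")
      hmmbuild_profile(aln, name, f)
      tmp_files <- c(tmp_files, f)
      marker_of[name] <- marker
    }
    n_profiles[marker] <- length(big)
  }
  # concatenate the per-cluster profiles into one HMMER3 file
  out_con <- file(out_path, "w")
  for (f in tmp_files) writeLines(readLines(f), out_con)
  close(out_con)
  unlink(tmp_files)
  ps <- profile_set(out_path, marker_of = marker_of)
  attr(ps, "n_profiles") <- n_profiles
  ps
}

# All-vs-all BLASTP similarity graph over proteins, clustered with the
# in-house Markov clustering. Edge weight is the best bit score observed
# in either direction; self-hits are dropped (Markov clustering adds its
# own self-loops). Singletons (proteins with no edges) form their own
# clusters.
cluster_proteins_mcl <- function(seqs, inflation = 5) {
  stopifnot(!is.null(names(seqs)))
  if (length(seqs) == 1) return(list(names(seqs)))
  hits <- blast_search(seqs, seqs, program = "blastp", evalue = 1e-3)
  hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  if (nrow(hits) > 0) {
    a <- pmin(hits$qseqid, hits$sseqid)
    b <- pmax(hits$qseqid, hits$sseqid)
    w <- tapply(hits$bitscore, paste(a, b, sep = "\r"), max)
    pairs <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
    edges <- data.frame(from = pairs[, 1], to = pairs[, 2],
                        weight = as.numeric(w), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  part <- mcl_cluster(edges, inflation = inflation, nodes = names(seqs))
  part$clusters
}
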