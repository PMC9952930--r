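# Genome quality control: terminal repeats, integrated-element screening,
# completeness categories.

#' Detect the longest exact terminal repeat of a sequence
#'
#' Looks for the longest exact match between the 5' end and the 3' end of
#' the sequence: a prefix equal to a suffix (direct terminal repeat, DTR)
#' or a prefix equal to the reverse complement of a suffix (inverted
#' terminal repeat, ITR). Matches are exact (no mismatches). When a direct
#' and an inverted repeat exist at the same (maximal) length, the direct
#' repeat is returned. The search is capped at `max_len` and at half the
#' sequence length so the two copies never overlap.
#'
#' @param seq nucleotide string or [genome_record()].
#' @param min_len minimum repeat length in nt (default 10).
#' @param max_len maximum repeat length in nt (default 5000).
#' @return list with fields kind ("direct"/"inverted"), length, repeat_seq;
#'   or NULL when no terminal repeat of at least `min_len` exists.
#' @export
detect_terminal_repeats <- function(seq, min_len = 10L, max_len = 5000L) {
  if (inherits(seq, "genome_record")) seq <- seq$sequence
  stop_if_not_scalar_string(seq, "seq")
  n <- nchar(seq)
  if (n <= 2L * min_len) {
    stop("sequence too short for terminal-repeat search", call. = FALSE)
  }
  cap <- min(as.integer(max_len), n %/% 2L)
  rc <- revcomp(seq)
  for (k in seq(cap, as.integer(min_len))) {
    prefix <- substr(seq, 1L, k)
    if (prefix == substr(seq, n - k + 1L, n)) {
      return(list(kind = "direct", length = k, repeat_seq = prefix))
    }
    # prefix == revcomp(suffix)  <=>  prefix == prefix of revcomp(seq)
    if (prefix == substr(rc, 1L, k)) {
      return(list(kind = "inverted", length = k, repeat_seq = prefix))
    }
  }
  NULL
}

#' Trim the 3' copy of a direct terminal repeat
#'
#' Removes the duplicated 3' repeat copy so a single genome unit remains
#' and marks the genome `dtr_trimmed`. If an ORF would span the junction of
#' the now implicitly circular genome, the sequence is rotated by the
#' smallest shift that places the junction in an intergenic gap, so that
#' downstream gene calling does not truncate genes across the ends.
#'
#' @param genome a [genome_record()].
#' @param repeat_hit result of [detect_terminal_repeats()]; must be direct.
#' @param min_aa ORF length floor used for the junction check.
#' @return list with fields genome (trimmed record) and report (list:
#'   genome_id, original_length, trimmed_length, repeat, start_shift).
#' @export
trim_dtr <- function(genome, repeat_hit, min_aa = 50L) {
  stopifnot(inherits(genome, "genome_record"))
  if (is.null(repeat_hit)) stop("no repeat to trim", call. = FALSE)
  if (!identical(repeat_hit$kind, "direct")) {
    stop("ITRs are not trimmed", call. = FALSE)
  }
  n0 <- nchar(genome$sequence)
  k <- repeat_hit$length
  trimmed_seq <- substr(genome$sequence, 1L, n0 - k)
  n <- nchar(trimmed_seq)
  shift <- smallest_junction_shift(trimmed_seq, min_aa = min_aa)
  if (shift > 0L) {
    trimmed_seq <- paste0(substr(trimmed_seq, shift + 1L, n),
                          substr(trimmed_seq, 1L, shift))
  }
  out <- genome_record(genome$id, trimmed_seq, topology = "dtr_trimmed",
                       source = genome$source)
  list(genome = out,
       report = list(genome_id = genome$id, original_length = n0,
                     trimmed_length = n, repeat_ = repeat_hit,
                     start_shift = shift))
}

# Smallest rotation (0 if none needed) placing the circular junction of
# `seq` in a gap between circular ORFs. Circular ORFs are found by calling
# ORFs on the doubled sequence and keeping those that start within the
# first copy and are shorter than the genome. A shift s means the junction
# falls between original positions s and s+1.
smallest_junction_shift <- function(seq, min_aa = 50L) {
  n <- nchar(seq)
  doubled <- genome_record("doubled", paste0(seq, seq))
  calls <- call_orfs(doubled, min_aa = min_aa)
  calls <- calls[calls$start <= n & (calls$end - calls$start + 1L) < n, ,
                 drop = FALSE]
  if (nrow(calls) == 0) return(0L)
  # boundary s (between positions s and s+1, s in 0..n-1) is blocked if some
  # gene covers both s and s+1 (circularly)
  blocked <- rep(FALSE, n)  # index s+1 for boundary s
  for (i in seq_len(nrow(calls))) {
    a <- calls$start[i]; b <- calls$end[i]
    if (b <= n) {
      if (b > a) blocked[((a:(b - 1L)) %% n) + 1L] <- TRUE
    } else {
      pos <- a:(b - 1L)
      blocked[(pos %% n) + 1L] <- TRUE
    }
  }
  free <- which(!blocked) - 1L  # boundary positions, 0-based
  if (length(free) == 0) return(0L)
  if (0L %in% free) return(0L)
  min(free)
}

#' Non-overlapping GC profile of a sequence
#'
#' GC fraction in consecutive non-overlapping windows. A sequence shorter
#' than one window yields a single window covering the whole sequence;
#' otherwise a trailing remainder shorter than `window` is dropped.
#'
#' @param seq nucleotide string or [genome_record()].
#' @param window window size in nt (default 100).
#' @return numeric vector of GC fractions.
#' @export
gc_profile <- function(seq, window = 100L) {
  if (inherits(seq, "genome_record")) seq <- seq$sequence
  n <- nchar(seq)
  if (n <= window) return(gc_content(seq))
  starts <- seq(1L, n - window + 1L, by = window)
  vapply(starts, function(s) gc_content(substr(seq, s, s + window - 1L)),
         numeric(1))
}

#' Screen a genome for signatures of an integrated element
#'
#' Flags long intergenic regions (>= `min_intergenic` nt, a hallmark of
#' eukaryotic host sequence annotated with a prokaryotic gene caller),
#' computes a non-overlapping GC profile, and reports candidate
#' host/element boundaries where mean GC differs by at least `min_gc_diff`
#' between the `flank_nt` windows on either side. When reference virophage
#' proteins are supplied, segments between boundaries whose genes have no
#' BLASTP hit to the references (bit score >= `min_ref_bitscore`) are
#' flagged host-like.
#'
#' @param genome a [genome_record()].
#' @param gene_calls gene-call data frame for this genome.
#' @param reference_proteins optional named character vector of virophage
#'   reference proteins.
#' @param min_intergenic minimum intergenic length to report (default 1000).
#' @param window GC window in nt (default 100).
#' @param min_gc_diff minimum absolute GC difference at a boundary
#'   (default 0.05).
#' @param flank_nt span averaged on each side of a boundary (default 2000).
#' @param min_ref_bitscore BLASTP bit-score floor for calling a gene
#'   virophage-like (default 30).
#' @return list: genome_id, long_intergenic_regions (data frame start/end),
#'   gc_profile, candidate_boundaries (positions), host_like_segments
#'   (data frame start/end).
#' @export
screen_integration <- function(genome, gene_calls,
                               reference_proteins = NULL,
                               min_intergenic = 1000L, window = 100L,
                               min_gc_diff = 0.05, flank_nt = 2000L,
                               min_ref_bitscore = 30) {
  stopifnot(inherits(genome, "genome_record"))
  n <- nchar(genome$sequence)
  calls <- gene_calls[gene_calls$genome_id == genome$id, , drop = FALSE]

  gaps <- intergenic_gaps(calls, n)
  long_gaps <- gaps[(gaps$end - gaps$start + 1L) >= min_intergenic, ,
                    drop = FALSE]

  prof <- gc_profile(genome$sequence, window = window)
  boundaries <- gc_shift_boundaries(prof, window = window,
                                    min_gc_diff = min_gc_diff,
                                    flank_nt = flank_nt)

  host_like <- data.frame(start = integer(), end = integer())
  if (!is.null(reference_proteins) && length(boundaries) > 0 &&
      nrow(calls) > 0) {
    seg_edges <- c(1L, sort(boundaries), n)
    hits <- blast_search(proteins_of(calls), reference_proteins,
                         program = "blastp", evalue = 1e-3)
    hit_prot <- unique(hits$qseqid[hits$bitscore >= min_ref_bitscore])
    viro_like <- protein_ids(calls) %in% hit_prot
    segs <- list()
    for (i in seq_len(length(seg_edges) - 1L)) {
      s <- seg_edges[i]; e <- seg_edges[i + 1L]
      in_seg <- calls$start >= s & calls$end <= e
      if (!any(in_seg & viro_like)) {
        segs[[length(segs) + 1L]] <- data.frame(start = s, end = e)
      }
    }
    if (length(segs)) host_like <- do.call(rbind, segs)
  }

  list(genome_id = genome$id,
       long_intergenic_regions = long_gaps,
       gc_profile = prof,
       candidate_boundaries = boundaries,
       host_like_segments = host_like)
}

# Maximal regions of the genome not covered by any gene call, including
# leading/trailing uncovered ends.
intergenic_gaps <- function(calls, n) {
  if (nrow(calls) == 0) return(data.frame(start = 1L, end = as.integer(n)))
  ir <- IRanges::reduce(IRanges::IRanges(start = calls$start,
                                         end = calls$end))
  gaps <- IRanges::gaps(ir, start = 1L, end = n)
  data.frame(start = IRanges::start(gaps), end = IRanges::end(gaps))
}

# Candidate boundaries from a per-window GC profile: window edges where the
# mean GC over flank_nt on the left differs from flank_nt on the right by
# >= min_gc_diff (both flanks must be complete). Runs of adjacent
# qualifying edges are collapsed to the edge of maximal difference.
gc_shift_boundaries <- function(prof, window = 100L, min_gc_diff = 0.05,
                                flank_nt = 2000L) {
  if (length(prof) < 2) return(integer())
  k <- max(1L, as.integer(flank_nt %/% window))
  nw <- length(prof)
  if (nw < 2L * k) return(integer())
  diffs <- rep(NA_real_, nw - 1L)
  for (b in k:(nw - k)) {
    left <- mean(prof[(b - k + 1L):b], na.rm = TRUE)
    right <- mean(prof[(b + 1L):(b + k)], na.rm = TRUE)
    diffs[b] <- abs(right - left)
  }
  qual <- which(!is.na(diffs) & diffs >= min_gc_diff)
  if (length(qual) == 0) return(integer())
  runs <- split(qual, cumsum(c(1L, diff(qual) != 1L)))
  picks <- vapply(runs, function(idx) idx[which.max(diffs[idx])], integer(1))
  sort(unname(picks)) * window
}

#' Excise an element from a larger contig
#'
#' Returns the element-only record; the report keeps the original
#' coordinates so element positions can be mapped back to the source
#' contig.
#'
#' @param genome a [genome_record()].
#' @param boundaries integer vector c(start, end), 1-based inclusive.
#' @return list with fields genome and report (genome_id, original_length,
#'   trimmed_length, element_start, element_end).
#' @export
trim_host_region <- function(genome, boundaries) {
  stopifnot(inherits(genome, "genome_record"), length(boundaries) == 2)
  n <- nchar(genome$sequence)
  s <- as.integer(boundaries[1]); e <- as.integer(boundaries[2])
  if (s < 1 || e > n || s > e) {
    stop("boundaries outside sequence", call. = FALSE)
  }
  out <- genome_record(genome$id, substr(genome$sequence, s, e),
                       topology = genome$topology, source = genome$source)
  list(genome = out,
       report = list(genome_id = genome$id, original_length = n,
                     trimmed_length = e - s + 1L,
                     element_start = s, element_end = e))
}

COMPLETENESS_CATEGORIES <- c("isolate_reference", "integrated_flanked",
                             "dtr", "itr", "checkv_high", "large_linear",
                             "partial")

#' Assign a completeness category to a genome
#'
#' Categories, in precedence order (the first that applies wins):
#' isolate_reference; integrated_flanked (host-like flanks of at least
#' `min_flank` nt on both sides); dtr; itr; checkv_high (external
#' completeness estimate >= 90 percent); large_linear (at least
#' `min_large_linear` nt); partial. Every category except partial counts
#' as complete or near-complete.
#'
#' @param genome a [genome_record()].
#' @param repeat_hit result of [detect_terminal_repeats()] (or NULL).
#' @param integration result of [screen_integration()] (or NULL).
#' @param checkv_estimate optional completeness percent from an external
#'   estimator; not computed by this package.
#' @param is_isolate_reference logical.
#' @param min_large_linear length floor for the large-linear category
#'   (default 25000 nt).
#' @param min_flank host-flank floor for integrated_flanked (default 2000).
#' @return list: genome_id, category, complete_or_near, checkv_estimate.
#' @export
call_completeness <- function(genome, repeat_hit = NULL, integration = NULL,
                              checkv_estimate = NULL,
                              is_isolate_reference = FALSE,
                              min_large_linear = 25000L,
                              min_flank = 2000L) {
  stopifnot(inherits(genome, "genome_record"))
  n <- nchar(genome$sequence)
  category <- if (isTRUE(is_isolate_reference)) {
    "isolate_reference"
  } else if (has_both_host_flanks(integration, n, min_flank)) {
    "integrated_flanked"
  } else if (!is.null(repeat_hit) && identical(repeat_hit$kind, "direct") ||
             identical(genome$topology, "dtr_trimmed")) {
    "dtr"
  } else if (!is.null(repeat_hit) && identical(repeat_hit$kind, "inverted")) {
    "itr"
  } else if (!is.null(checkv_estimate) && !is.na(checkv_estimate) &&
             checkv_estimate >= 90) {
    "checkv_high"
  } else if (n >= min_large_linear) {
    "large_linear"
  } else {
    "partial"
  }
  list(genome_id = genome$id, category = category,
       complete_or_near = category != "partial",
       checkv_estimate = checkv_estimate %||% NA_real_)
}

has_both_host_flanks <- function(integration, n, min_flank) {
  if (is.null(integration)) return(FALSE)
  segs <- integration$host_like_segments
  if (is.null(segs) || nrow(segs) == 0) return(FALSE)
  len <- segs$end - segs$start + 1L
  left <- any(segs$start == 1L & len >= min_flank)
  right <- any(segs$end == n & len >= min_flank)
  left && right
}

#' Read an external completeness summary (TSV with a `completeness` column)
#'
#' Ingests the standard quality-summary table written by external
#' completeness estimators; only the contig id and completeness percent
#' are used.
#' @param path TSV file with columns contig_id, completeness.
#' @return named numeric vector of completeness percents.
#' @export
read_completeness_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("contig_id", "completeness") %in% names(df))) {
    stop("expected columns contig_id and completeness", call. = FALSE)
  }
  setNames(as.numeric(df$completeness), df$contig_id)
}
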