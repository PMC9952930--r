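# Independent oracles used to validate the implementation on small inputs.
# They deliberately re-derive results through different code paths
# (character-level scans, per-family searches, exhaustive enumeration).

# Exhaustive six-frame stop-to-stop ORF enumeration, character by
# character, translating through seqinr (not Biostrings).
oracle_orfs <- function(seq, min_aa = 50L) {
  n <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    template <- if (strand == "+") seq else virotax:::revcomp(seq)
    tv <- strsplit(tolower(template), "")[[1]]
    for (off in 0:2) {
      ncod <- (n - off) %/% 3
      if (ncod < 1) next
      aa <- seqinr::translate(tv[(off + 1):(off + 3 * ncod)], numcode = 11,
                              ambiguous = FALSE)
      aa[is.na(aa)] <- "X"
      run_start <- NULL
      for (i in seq_len(ncod + 1)) {
        stop_here <- i > ncod || aa[i] == "*"
        if (!stop_here && is.null(run_start)) run_start <- i
        if (stop_here && !is.null(run_start)) {
          len <- i - run_start
          if (len >= min_aa) {
            t_start <- off + 3L * (run_start - 1L) + 1L
            t_end <- off + 3L * (i - 1L)
            g <- if (strand == "+") c(t_start, t_end) else
              c(n - t_end + 1L, n - t_start + 1L)
            out[[length(out) + 1L]] <- data.frame(
              start = g[1], end = g[2], strand = strand,
              protein = paste(aa[run_start:(i - 1L)], collapse = ""),
              stringsAsFactors = FALSE)
          }
          run_start <- NULL
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), protein = character(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$end, df$strand), ]
  rownames(df) <- NULL
  df
}

# Exhaustive prefix/suffix comparison over every candidate length,
# character by character.
oracle_terminal_repeat <- function(seq, min_len = 10L, max_len = 5000L) {
  n <- nchar(seq)
  v <- strsplit(seq, "")[[1]]
  rc <- strsplit(virotax:::revcomp(seq), "")[[1]]
  best <- NULL
  for (k in seq.int(min_len, min(max_len, n %/% 2))) {
    if (all(v[1:k] == v[(n - k + 1):n])) {
      best <- list(kind = "direct", length = k,
                   repeat_seq = paste(v[1:k], collapse = ""))
    } else if (all(v[1:k] == rc[1:k])) {
      if (is.null(best) || best$length < k) {
        best <- list(kind = "inverted", length = k,
                     repeat_seq = paste(v[1:k], collapse = ""))
      }
    }
  }
  best
}

# Family cutoffs by per-family searches: for each family, BLAST all
# out-of-group references against a database of that family only.
oracle_cutoffs <- function(db, floor = 50) {
  fams <- sort(unique(db$family))
  vapply(fams, function(f) {
    inside <- db$proteins[names(db$family)[db$family == f]]
    outside <- db$proteins[names(db$family)[db$family != f]]
    hits <- virotax:::blast_search(outside, inside, program = "blastp",
                                   evalue = 1e-3,
                                   extra_args = c("-max_target_seqs",
                                                  "100000"))
    hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
    if (nrow(hits) == 0) floor else max(hits$bitscore)
  }, numeric(1))
}

# Minimal valid junction shift by brute-force rotation: rotate the
# sequence by every shift and accept the first whose circular gene set
# (ORFs on the doubled rotated sequence) has no gene across the ends.
oracle_junction_shift <- function(seq, min_aa = 50L) {
  n <- nchar(seq)
  for (s in 0:(n - 1L)) {
    rot <- if (s == 0) seq else
      paste0(substr(seq, s + 1L, n), substr(seq, 1L, s))
    doubled <- genome_record("rot", paste0(rot, rot))
    calls <- call_orfs(doubled, min_aa = min_aa)
    circ <- calls[calls$start <= n & (calls$end - calls$start + 1L) < n, ,
                  drop = FALSE]
    if (!any(circ$start <= n & circ$end > n)) return(s)
  }
  0L
}

canon_partition <- function(clusters) {
  paste(sapply(clusters, paste, collapse = ""), collapse = "|")
}

read_mcl_reference <- function() {
  read.table(test_path("mcl_reference_partitions.tsv"), header = TRUE,
             sep = "\t", stringsAsFactors = FALSE)
}
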