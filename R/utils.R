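#' @importFrom stats runif setNames aggregate
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the
#' previous RNG state so callers' random streams are unaffected.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

# 20 standard amino acids (no stops, no ambiguity codes)
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Reverse complement of a nucleotide string
#' @param seq character scalar (A/C/G/T/N, any case).
#' @return character scalar.
#' @keywords internal
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' GC fraction of a nucleotide string
#'
#' Ns and other ambiguity codes are excluded from the denominator; an
#' all-N (or empty) sequence returns NA.
#' @param seq character scalar.
#' @return numeric in [0, 1] or NA.
#' @keywords internal
gc_content <- function(seq) {
  counts <- table(strsplit(toupper(seq), "")[[1]])
  gc <- sum(counts[names(counts) %in% c("G", "C")])
  at <- sum(counts[names(counts) %in% c("A", "T")])
  if (gc + at == 0) return(NA_real_)
  gc / (gc + at)
}

#' Random DNA sequence at a target GC content
#' @param n length in nt.
#' @param gc target GC fraction.
#' @return character scalar.
#' @keywords internal
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Random protein sequence (uniform over the 20 standard residues)
#' @param n length in aa.
#' @param start_met prepend/force a leading methionine.
#' @return character scalar.
#' @keywords internal
random_protein <- function(n, start_met = TRUE) {
  aa <- sample(AA_ALPHABET, n, replace = TRUE)
  if (start_met) aa[1] <- "M"
  paste(aa, collapse = "")
}

#' Fraction of identical positions between two equal-length strings
#' @keywords internal
positional_identity <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  n <- min(length(va), length(vb))
  if (n == 0) return(0)
  mean(va[seq_len(n)] == vb[seq_len(n)])
}

#' Merge possibly-overlapping integer intervals and return total covered length
#' @param starts,ends integer vectors (1-based inclusive).
#' @return total number of positions covered by the union.
#' @keywords internal
merged_interval_length <- function(starts, ends) {
  if (length(starts) == 0) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(start = pmin(starts, ends),
                                         end = pmax(starts, ends)))
  sum(IRanges::width(ir))
}

stop_if_not_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("%s must be a single character string", what), call. = FALSE)
  }
}
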