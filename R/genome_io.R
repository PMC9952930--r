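# Sequence input/output and gene calling.
#
# Coordinate convention: 1-based, inclusive on both ends, everywhere in the
# package. Converters (external gene-call ingestion) are the only place an
# offset changes.

#' Construct a genome record
#'
#' @param id genome identifier (unique within a set).
#' @param sequence nucleotide string; lowercase is uppercased and any
#'   character outside A/C/G/T/N is replaced by N.
#' @param topology "linear" or "dtr_trimmed".
#' @param source free-text provenance.
#' @return a `genome_record` (list with fields id, sequence, topology, source).
#' @export
genome_record <- function(id, sequence, topology = c("linear", "dtr_trimmed"),
                          source = "") {
  stop_if_not_scalar_string(id, "id")
  stop_if_not_scalar_string(sequence, "sequence")
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  sequence <- gsub("[^ACGTN]", "N", sequence)
  if (nchar(sequence) < 1) stop("sequence length must be >= 1", call. = FALSE)
  structure(list(id = id, sequence = sequence, topology = topology,
                 source = source),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d nt, %s\n", x$id, nchar(x$sequence),
              x$topology))
  invisible(x)
}

#' Read nucleotide genomes from a FASTA file
#'
#' The header token before the first whitespace becomes the genome id.
#' Duplicate ids and empty files are errors.
#'
#' @param path FASTA file.
#' @return list of [genome_record()] objects, named by id.
#' @export
read_genomes <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("no sequences", call. = FALSE)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate sequence id: %s", dup[1]), call. = FALSE)
  }
  recs <- lapply(seq_along(set), function(i) {
    genome_record(ids[i], as.character(set[[i]]), source = path)
  })
  setNames(recs, ids)
}

#' Write genome records to a FASTA file
#' @param genomes list of genome records (or a single record).
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_genomes <- function(genomes, path) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  seqs <- setNames(vapply(genomes, `[[`, character(1), "sequence"),
                   vapply(genomes, `[[`, character(1), "id"))
  write_fasta_vector(seqs, path)
}

#' Six-frame open reading frame caller
#'
#' Finds all maximal stop-to-stop ORFs of at least `min_aa` translated
#' residues on all six frames and translates them under the given genetic
#' code. Contig ends act as stops: a reading frame truncated by the end of
#' the sequence yields an ORF that ends there. Ns translate to X and do not
#' split an ORF. This is a deliberately simple fallback, not a re-creation
#' of a trained gene finder; pipelines that must reproduce an external
#' caller's gene models should ingest them with
#' [load_external_gene_calls()].
#'
#' @param genome a [genome_record()].
#' @param min_aa minimum protein length in residues (default 50).
#' @param genetic_code NCBI translation table id (default 11).
#' @return data frame of gene calls: genome_id, gene_index, start, end,
#'   strand, protein. Coordinates are 1-based inclusive on the forward
#'   strand; `end - start + 1 == 3 * nchar(protein)`.
#' @export
call_orfs <- function(genome, min_aa = 50L, genetic_code = "11") {
  stopifnot(inherits(genome, "genome_record"))
  code <- Biostrings::getGeneticCode(as.character(genetic_code))
  n <- nchar(genome$sequence)
  fwd <- Biostrings::DNAString(genome$sequence)
  rev <- Biostrings::reverseComplement(fwd)
  rows <- list()
  for (strand in c("+", "-")) {
    template <- if (strand == "+") fwd else rev
    for (off in 0:2) {
      ncod <- (n - off) %/% 3
      if (ncod < 1) next
      sub <- Biostrings::subseq(template, off + 1L, off + 3L * ncod)
      aa <- as.character(Biostrings::translate(sub, genetic.code = code,
                                               if.fuzzy.codon = "X",
                                               no.init.codon = TRUE))
      # maximal stop-free runs of codons
      segs <- find_stop_free_runs(aa)
      for (k in seq_len(nrow(segs))) {
        len_aa <- segs$end[k] - segs$start[k] + 1L
        if (len_aa < min_aa) next
        # codon coordinates -> template nt coordinates
        t_start <- off + 3L * (segs$start[k] - 1L) + 1L
        t_end <- off + 3L * segs$end[k]
        if (strand == "+") {
          g_start <- t_start; g_end <- t_end
        } else {
          g_start <- n - t_end + 1L; g_end <- n - t_start + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = genome$id, start = g_start, end = g_end,
          strand = strand,
          protein = substr(aa, segs$start[k], segs$end[k]),
          stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(genome_id = character(), start = integer(), end = integer(),
               strand = character(), protein = character(),
               stringsAsFactors = FALSE)
  calls <- calls[order(calls$start, calls$end, calls$strand), , drop = FALSE]
  calls$gene_index <- seq_len(nrow(calls))
  rownames(calls) <- NULL
  calls[, c("genome_id", "gene_index", "start", "end", "strand", "protein")]
}

# Runs of non-stop characters in a translated frame, as codon indices.
find_stop_free_runs <- function(aa) {
  chars <- strsplit(aa, "")[[1]]
  is_stop <- chars == "*"
  r <- rle(is_stop)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Read gene calls from a protein FASTA with coordinate-bearing headers
#'
#' Supports the common gene-caller header dialect
#' `>id # start # end # strand [# attributes]` where strand is `1`/`-1`
#' (or `+`/`-`). Coordinates are taken as 1-based inclusive.
#'
#' @param path protein FASTA file.
#' @return data frame of gene calls (genome_id, gene_index, start, end,
#'   strand, protein). The genome id and gene index are recovered from the
#'   protein id by splitting at the final underscore.
#' @export
load_external_gene_calls <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("no sequences", call. = FALSE)
  parse_one <- function(header) {
    parts <- trimws(strsplit(header, "#", fixed = TRUE)[[1]])
    if (length(parts) < 4) {
      stop(sprintf("cannot parse gene coordinates from header: %s", header),
           call. = FALSE)
    }
    id <- strsplit(parts[1], "[ \t]")[[1]][1]
    start <- suppressWarnings(as.integer(parts[2]))
    end <- suppressWarnings(as.integer(parts[3]))
    strand_raw <- parts[4]
    strand <- switch(strand_raw, "1" = "+", "+1" = "+", "+" = "+",
                     "-1" = "-", "-" = "-", NA_character_)
    if (is.na(start) || is.na(end) || is.na(strand) || end < start) {
      stop(sprintf("cannot parse gene coordinates from header: %s", header),
           call. = FALSE)
    }
    list(id = id, start = start, end = end, strand = strand)
  }
  meta <- lapply(names(set), parse_one)
  ids <- vapply(meta, `[[`, character(1), "id")
  genome_id <- sub("_[0-9]+$", "", ids)
  gene_index <- suppressWarnings(as.integer(sub("^.*_", "", ids)))
  gene_index[is.na(gene_index)] <- seq_len(sum(is.na(gene_index)))
  proteins <- sub("\\*$", "", as.character(set))
  if (any(grepl("\\*", proteins))) {
    stop("internal stop character in protein sequence", call. = FALSE)
  }
  df <- data.frame(genome_id = genome_id, gene_index = gene_index,
                   start = vapply(meta, `[[`, numeric(1), "start"),
                   end = vapply(meta, `[[`, numeric(1), "end"),
                   strand = vapply(meta, `[[`, character(1), "strand"),
                   protein = unname(proteins), stringsAsFactors = FALSE)
  df[order(df$genome_id, df$start), , drop = FALSE]
}

#' Protein ids for a gene-call table
#'
#' Protein ids are `genome-id_gene-index`, matching the ids used in marker
#' search results and reference databases.
#' @param calls gene-call data frame.
#' @return character vector.
#' @export
protein_ids <- function(calls) {
  paste0(calls$genome_id, "_", calls$gene_index)
}

#' Extract a named protein vector from gene calls
#' @param calls gene-call data frame.
#' @return named character vector (names are protein ids).
#' @export
proteins_of <- function(calls) {
  setNames(calls$protein, protein_ids(calls))
}

#' Write gene-call proteins as FASTA in the coordinate-bearing dialect
#' @param calls gene-call data frame.
#' @param path output file.
#' @export
write_protein_fasta <- function(calls, path) {
  strand_num <- ifelse(calls$strand == "+", "1", "-1")
  headers <- sprintf("%s # %d # %d # %s", protein_ids(calls),
                     as.integer(calls$start), as.integer(calls$end),
                     strand_num)
  write_fasta_vector(setNames(calls$protein, headers), path)
}

#' Export gene calls as a tab-separated table
#' @param calls gene-call data frame.
#' @param path output TSV.
#' @export
write_gene_table <- function(calls, path) {
  out <- data.frame(genome_id = calls$genome_id,
                    gene_index = calls$gene_index,
                    start = calls$start, end = calls$end,
                    strand = calls$strand,
                    length_aa = nchar(calls$protein),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
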