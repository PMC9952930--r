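# Thin wrappers around the external search/alignment executables
# (HMMER, BLAST+, MAFFT). All results are parsed into plain data frames;
# every wrapper is deterministic for fixed inputs.

#' Locate an external executable or fail with a clear message
#' @param name executable name.
#' @return full path.
#' @keywords internal
find_tool <- function(name) {
  path <- Sys.which(name)
  if (!nzchar(path)) {
    stop(sprintf("required external tool '%s' not found on PATH", name),
         call. = FALSE)
  }
  unname(path)
}

run_tool <- function(exe, args, stdout = TRUE) {
  out <- suppressWarnings(system2(exe, args, stdout = stdout, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (is.logical(stdout) && !stdout) {
    status <- out  # system2 returns exit code when stdout = FALSE
    out <- character()
  }
  if (!identical(as.integer(status), 0L)) {
    stop(sprintf("%s failed (exit %s):\n%s", basename(exe), status,
                 paste(utils::tail(out, 20), collapse = "\n")), call. = FALSE)
  }
  invisible(out)
}

BLAST_FMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                     "gapopen", "qstart", "qend", "sstart", "send",
                     "evalue", "bitscore", "qlen", "slen")

empty_blast_table <- function() {
  df <- as.data.frame(setNames(rep(list(character()), length(BLAST_FMT6_COLS)),
                               BLAST_FMT6_COLS), stringsAsFactors = FALSE)
  num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
           "sstart", "send", "evalue", "bitscore", "qlen", "slen")
  for (cc in num) df[[cc]] <- numeric()
  df
}

parse_blast_fmt6 <- function(lines) {
  if (length(lines) == 0) return(empty_blast_table())
  df <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE,
                          col.names = BLAST_FMT6_COLS, quote = "")
  df$qseqid <- as.character(df$qseqid)
  df$sseqid <- as.character(df$sseqid)
  df
}

#' All-vs-all (or query-vs-db) BLAST search returning a tabular result
#'
#' @param query named character vector of sequences (names become ids).
#' @param subject named character vector for the database.
#' @param program "blastp" or "blastn".
#' @param evalue E-value ceiling passed to the search.
#' @param extra_args additional command-line arguments.
#' @return data frame in outfmt-6 layout plus qlen/slen columns.
#' @keywords internal
blast_search <- function(query, subject, program = c("blastp", "blastn"),
                         evalue = 1e-3, extra_args = character()) {
  program <- match.arg(program)
  if (length(query) == 0 || length(subject) == 0) return(empty_blast_table())
  dbtype <- if (program == "blastp") "prot" else "nucl"
  wd <- tempfile("blast")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE))
  qfa <- file.path(wd, "query.fa")
  sfa <- file.path(wd, "subject.fa")
  write_fasta_vector(query, qfa)
  write_fasta_vector(subject, sfa)
  run_tool(find_tool("makeblastdb"),
           c("-in", sfa, "-dbtype", dbtype, "-out", file.path(wd, "db")),
           stdout = TRUE)
  outfmt <- paste("6", paste(BLAST_FMT6_COLS, collapse = " "))
  out <- file.path(wd, "hits.tsv")
  args <- c("-query", qfa, "-db", file.path(wd, "db"),
            "-evalue", format(evalue, scientific = TRUE),
            "-outfmt", shQuote(outfmt), "-out", out, extra_args)
  run_tool(find_tool(program), args, stdout = TRUE)
  parse_blast_fmt6(readLines(out))
}

#' Write a named character vector as FASTA
#' @keywords internal
write_fasta_vector <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Multiple alignment of proteins with MAFFT
#' @param seqs named character vector of protein sequences.
#' @return named character vector of aligned sequences (with gaps).
#' @keywords internal
mafft_align <- function(seqs) {
  if (length(seqs) < 2) return(seqs)
  wd <- tempfile("mafft")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE))
  infa <- file.path(wd, "in.fa")
  outfa <- file.path(wd, "out.fa")
  write_fasta_vector(seqs, infa)
  out <- run_tool(find_tool("mafft"), c("--quiet", "--auto", infa))
  writeLines(out, outfa)
  aln <- Biostrings::readAAStringSet(outfa)
  setNames(toupper(as.character(aln)), names(aln))
}

#' Build a profile HMM from aligned sequences with hmmbuild
#' @param alignment named character vector of equal-length aligned proteins.
#' @param name profile name recorded in the HMM file.
#' @param out_path destination HMMER3 text file.
#' @return `out_path` invisibly.
#' @keywords internal
hmmbuild_profile <- function(alignment, name, out_path) {
  wd <- tempfile("hmmbuild")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE))
  sto <- file.path(wd, "aln.sto")
  write_stockholm(alignment, sto)
  run_tool(find_tool("hmmbuild"),
           c("--amino", "-n", name, out_path, sto))
  invisible(out_path)
}

write_stockholm <- function(alignment, path) {
  ids <- names(alignment)
  pad <- max(nchar(ids)) + 2L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  writeLines(sprintf("%-*s%s", pad, ids, alignment), con)
  writeLines("//", con)
  invisible(path)
}

HMMER_DOMTBL_COLS <- c("target", "tacc", "tlen", "query", "qacc", "qlen",
                       "full_evalue", "full_score", "full_bias",
                       "dom_n", "dom_of", "c_evalue", "i_evalue",
                       "dom_score", "dom_bias", "hmm_from", "hmm_to",
                       "ali_from", "ali_to", "env_from", "env_to", "acc")

#' Search proteins against profile HMMs with hmmsearch
#'
#' Runs hmmsearch with a permissive reporting threshold and returns the
#' per-domain table; thresholding is applied by the caller.
#'
#' @param proteins named character vector of protein sequences.
#' @param hmm_path path to an HMMER3 text file (may hold many profiles).
#' @return data frame with one row per reported domain.
#' @keywords internal
hmmsearch_domtbl <- function(proteins, hmm_path) {
  if (!file.exists(hmm_path)) {
    stop(sprintf("profile file not found: %s", hmm_path), call. = FALSE)
  }
  empty <- as.data.frame(setNames(rep(list(character()),
                                      length(HMMER_DOMTBL_COLS)),
                                  HMMER_DOMTBL_COLS),
                         stringsAsFactors = FALSE)
  if (length(proteins) == 0) return(empty)
  wd <- tempfile("hmmsearch")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE))
  fa <- file.path(wd, "prot.fa")
  tbl <- file.path(wd, "dom.tbl")
  write_fasta_vector(proteins, fa)
  run_tool(find_tool("hmmsearch"),
           c("--noali", "--domtblout", tbl, "-E", "10", hmm_path, fa))
  lines <- grep("^#", readLines(tbl), value = TRUE, invert = TRUE)
  if (length(lines) == 0) return(empty)
  # description field may contain spaces; take the first 22 fields only
  fields <- strsplit(trimws(lines), "[ \t]+")
  mat <- t(vapply(fields, function(f) f[seq_along(HMMER_DOMTBL_COLS)],
                  character(length(HMMER_DOMTBL_COLS))))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- HMMER_DOMTBL_COLS
  num <- setdiff(HMMER_DOMTBL_COLS, c("target", "tacc", "query", "qacc"))
  for (cc in num) df[[cc]] <- as.numeric(df[[cc]])
  df
}
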