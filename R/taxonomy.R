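# Family-level assignment within the virophage class: best BLASTP hit of
# the query MCP against a labeled reference MCP database, gated by
# per-family bit-score cutoffs derived from the highest out-of-group score.

#' The seven proposed family-level groups
#' @export
VIROPHAGE_FAMILIES <- c("Ruviroviridae", "Maviroviridae",
                        "Sputniviroviridae", "Dishuiviroviridae",
                        "Omnilimnoviroviridae", "Gulliviroviridae",
                        "Burtonviroviridae")

#' Build a labeled MCP reference database
#'
#' @param proteins named character vector of reference MCP sequences.
#' @param family named character vector (or vector aligned with
#'   `proteins`) giving each reference's family label.
#' @return a `family_db` (list: proteins, family).
#' @export
family_db <- function(proteins, family) {
  stopifnot(!is.null(names(proteins)))
  if (!is.null(names(family))) family <- family[names(proteins)]
  if (length(family) != length(proteins) || anyNA(family)) {
    stop("every reference needs exactly one family label", call. = FALSE)
  }
  structure(list(proteins = proteins,
                 family = setNames(as.character(family), names(proteins))),
            class = "family_db")
}

#' Read a reference database from FASTA + label TSV
#' @param fasta_path protein FASTA of reference MCPs.
#' @param labels_path two-column TSV (id, family), no header.
#' @return a [family_db()].
#' @export
read_family_db <- function(fasta_path, labels_path) {
  set <- Biostrings::readAAStringSet(fasta_path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1)
  prot <- setNames(as.character(set), ids)
  lab <- utils::read.table(labels_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("id", "family"))
  family_db(prot, setNames(lab$family, lab$id))
}

#' @export
print.family_db <- function(x, ...) {
  tab <- table(x$family)
  cat(sprintf("<family_db> %d reference MCPs in %d families\n",
              length(x$proteins), length(tab)))
  invisible(x)
}

#' Derive per-family bit-score cutoffs from out-of-group maxima
#'
#' All references are compared all-vs-all with BLASTP (self-hits omitted).
#' The cutoff of family F is the highest bit score obtained by any query
#' from outside F against a subject in F; a family receiving no
#' out-of-group hit gets the configured floor. Queries that score at or
#' below their family's cutoff cannot be distinguished from out-of-group
#' sequences, which is why assignment uses a strictly-greater comparison.
#'
#' @param db a [family_db()].
#' @param floor cutoff used when a family has no out-of-group hit
#'   (default 50 bits).
#' @param max_evalue BLASTP E-value ceiling (default 1e-3).
#' @return data frame: family, cutoff, provenance (query/subject pair that
#'   set the cutoff, or "floor").
#' @export
derive_cutoffs <- function(db, floor = 50, max_evalue = 1e-3) {
  stopifnot(inherits(db, "family_db"))
  fams <- sort(unique(db$family))
  if (length(fams) < 2) {
    stop("cannot derive out-of-group cutoffs from a single-family database",
         call. = FALSE)
  }
  hits <- blast_search(db$proteins, db$proteins, program = "blastp",
                       evalue = max_evalue,
                       extra_args = c("-max_target_seqs", "100000"))
  hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  hits$qfam <- db$family[hits$qseqid]
  hits$sfam <- db$family[hits$sseqid]
  cross <- hits[hits$qfam != hits$sfam, , drop = FALSE]
  rows <- lapply(fams, function(f) {
    h <- cross[cross$sfam == f, , drop = FALSE]
    if (nrow(h) == 0) {
      return(data.frame(family = f, cutoff = floor, provenance = "floor",
                        stringsAsFactors = FALSE))
    }
    i <- order(-h$bitscore, h$qseqid, h$sseqid)[1]
    data.frame(family = f, cutoff = h$bitscore[i],
               provenance = paste0(h$qseqid[i], "->", h$sseqid[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign a query MCP to a family by best reference hit
#'
#' The best hit is the reference with the highest bit score (ties: higher
#' percent identity, then lexicographic subject id); a reference with the
#' same id as the query is ignored (self-hit). The query is assigned to
#' the best hit's family only when the score strictly exceeds that
#' family's cutoff; otherwise it stays unclassified within the class.
#'
#' @param query_mcp named character vector of length 1 (the query MCP).
#' @param db a [family_db()].
#' @param cutoffs data frame from [derive_cutoffs()].
#' @param max_evalue BLASTP E-value ceiling (default 1e-3).
#' @return list: family ("unclassified_within_class" when not assigned),
#'   best_subject, best_score, passed_cutoff.
#' @export
assign_family <- function(query_mcp, db, cutoffs, max_evalue = 1e-3) {
  stopifnot(inherits(db, "family_db"))
  if (length(db$proteins) == 0) stop("empty reference database",
                                     call. = FALSE)
  stopifnot(length(query_mcp) == 1, !is.null(names(query_mcp)))
  hits <- blast_search(query_mcp, db$proteins, program = "blastp",
                       evalue = max_evalue,
                       extra_args = c("-max_target_seqs", "100000"))
  hits <- hits[hits$sseqid != names(query_mcp), , drop = FALSE]
  unassigned <- list(family = "unclassified_within_class",
                     best_subject = NA_character_,
                     best_score = NA_real_, passed_cutoff = FALSE)
  if (nrow(hits) == 0) return(unassigned)
  i <- order(-hits$bitscore, -hits$pident, hits$sseqid)[1]
  best <- hits[i, ]
  fam <- db$family[[best$sseqid]]
  cut <- cutoffs$cutoff[cutoffs$family == fam]
  passed <- length(cut) == 1 && best$bitscore > cut
  list(family = if (passed) fam else "unclassified_within_class",
       best_subject = best$sseqid, best_score = best$bitscore,
       passed_cutoff = passed)
}

#' Classify a batch of genomes end to end
#'
#' For every genome: gene calling (unless calls are supplied), marker
#' search, class demarcation, family assignment (on the genome's
#' highest-scoring MCP protein) for class members, PLV flagging for
#' non-members, and optionally a completeness call. A failure on one
#' genome marks its row "error" and never aborts the batch.
#'
#' @param genomes list of [genome_record()] objects.
#' @param profiles a [profile_set()].
#' @param db a [family_db()] (optional; without it family columns stay NA).
#' @param cutoffs data frame from [derive_cutoffs()] (required with `db`).
#' @param gene_calls optional externally produced gene-call data frame for
#'   all genomes; when absent ORFs are called with [call_orfs()].
#' @param checkv optional named numeric vector of external completeness
#'   percents.
#' @param marker_min_score bit-score floor for marker detection
#'   (default 40).
#' @param marker_max_evalue E-value ceiling for marker detection
#'   (default 0.01).
#' @param mcp_min class threshold on MCP score (default 50).
#' @param plv_min PLV threshold (default 50).
#' @param completeness run the completeness call per genome
#'   (default TRUE).
#' @return data frame, one row per input genome in input order:
#'   genome_id, length, in_maveriviricetes, family, best_subject,
#'   best_score, n_markers_detected, mcp_score, candidate_flag,
#'   possible_plv, plv_score, completeness_category, complete_or_near,
#'   phylogeny_label (always NA, reserved for externally supplied
#'   phylogenetic placements), status.
#' @export
classify_batch <- function(genomes, profiles, db = NULL, cutoffs = NULL,
                           gene_calls = NULL, checkv = NULL,
                           marker_min_score = 40, marker_max_evalue = 0.01,
                           mcp_min = 50, plv_min = 50,
                           completeness = TRUE) {
  ids <- vapply(genomes, function(g) {
    if (inherits(g, "genome_record")) g$id else NA_character_
  }, character(1))
  template <- data.frame(
    genome_id = NA_character_, length = NA_integer_,
    in_maveriviricetes = NA, family = NA_character_,
    best_subject = NA_character_, best_score = NA_real_,
    n_markers_detected = NA_integer_, mcp_score = NA_real_,
    candidate_flag = NA, possible_plv = NA, plv_score = NA_real_,
    completeness_category = NA_character_, complete_or_near = NA,
    phylogeny_label = NA_character_, status = "ok",
    stringsAsFactors = FALSE)
  if (length(genomes) == 0) return(template[0, , drop = FALSE])

  ok <- !is.na(ids)
  calls_all <- gene_calls
  if (is.null(calls_all)) {
    call_list <- lapply(genomes[ok], function(g) {
      tryCatch(call_orfs(g), error = function(e) NULL)
    })
    calls_all <- do.call(rbind, call_list)
  }
  hits <- if (!is.null(calls_all) && nrow(calls_all) > 0) {
    search_markers(calls_all, profiles, min_score = marker_min_score,
                   max_evalue = marker_max_evalue)
  } else {
    search_markers(character(), profiles)
  }
  table <- best_hits(hits)
  cls <- assign_class(table, genome_ids = ids[ok], mcp_min = mcp_min,
                      plv_min = plv_min)

  rows <- lapply(seq_along(genomes), function(i) {
    row <- template
    if (!ok[i]) {
      row$genome_id <- sprintf("input_%d", i)
      row$status <- "error: not a genome record"
      return(row)
    }
    g <- genomes[[i]]
    tryCatch({
      row$genome_id <- g$id
      row$length <- nchar(g$sequence)
      c1 <- cls[cls$genome_id == g$id, , drop = FALSE]
      row$in_maveriviricetes <- c1$in_maveriviricetes
      row$candidate_flag <- c1$candidate_flag
      row$possible_plv <- c1$possible_plv
      row$mcp_score <- c1$mcp_score
      row$plv_score <- c1$plv_score
      row$n_markers_detected <- c1$n_markers_detected
      if (isTRUE(c1$in_maveriviricetes) && !is.null(db)) {
        if (is.null(cutoffs)) stop("cutoffs required with a reference db")
        mcp_hits <- table[table$genome_id == g$id & table$marker == "MCP", ,
                          drop = FALSE]
        prot_id <- mcp_hits$protein_id[1]
        calls_g <- calls_all[calls_all$genome_id == g$id, , drop = FALSE]
        query <- proteins_of(calls_g)[prot_id]
        fa <- assign_family(query, db, cutoffs)
        row$family <- fa$family
        row$best_subject <- fa$best_subject
        row$best_score <- fa$best_score
      }
      if (completeness) {
        rep_hit <- tryCatch(detect_terminal_repeats(g),
                            error = function(e) NULL)
        est <- if (!is.null(checkv) && g$id %in% names(checkv))
          checkv[[g$id]] else NULL
        comp <- call_completeness(g, repeat_hit = rep_hit,
                                  checkv_estimate = est)
        row$completeness_category <- comp$category
        row$complete_or_near <- comp$complete_or_near
      }
      row
    }, error = function(e) {
      row$genome_id <- if (!is.na(ids[i])) ids[i] else sprintf("input_%d", i)
      row$status <- paste0("error: ", conditionMessage(e))
      row
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write family cutoffs as TSV
#' @param cutoffs data frame from [derive_cutoffs()].
#' @param path output file.
#' @export
write_cutoffs <- function(cutoffs, path) {
  utils::write.table(cutoffs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read family cutoffs from TSV
#' @param path TSV written by [write_cutoffs()].
#' @export
read_cutoffs <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
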