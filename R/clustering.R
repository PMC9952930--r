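# Genome dereplication and grouping: ANI-based vOTU clustering (95% ANI /
# 85% aligned fraction, greedy longest-first) and genome-wide AAI groups
# from a filtered AAI graph clustered with an in-house Markov clustering
# (MCL) implementation.

#' Markov clustering of a weighted undirected graph
#'
#' Dense implementation of the MCL process: self-loops are added at each
#' node's maximum incident edge weight, the matrix is made column
#' stochastic, and expansion (matrix squaring), inflation (elementwise
#' power and renormalisation) and pruning are iterated to convergence.
#' Clusters are read from attractor rows; a node attracted by several
#' attractors goes to the one with the largest flow (ties broken by
#' lexicographic attractor id, which also merges symmetric attractor
#' systems into a single cluster).
#'
#' @param edges data frame with columns from, to, weight (undirected).
#' @param inflation inflation exponent (default 1.1).
#' @param expansion expansion power (default 2).
#' @param max_iter iteration cap (default 200).
#' @param prune entries below this are zeroed each iteration
#'   (default 1e-6).
#' @param tol convergence tolerance on the max entry change
#'   (default 1e-8).
#' @param nodes optional character vector of node ids; isolated nodes
#'   become singleton clusters.
#' @return list with `clusters` (list of character vectors, each sorted;
#'   clusters ordered by their first member) and `membership` (named
#'   integer vector).
#' @export
mcl_cluster <- function(edges, inflation = 1.1, expansion = 2,
                        max_iter = 200L, prune = 1e-6, tol = 1e-8,
                        nodes = NULL) {
  ids <- sort(unique(c(nodes, edges$from, edges$to)))
  if (length(ids) == 0) {
    return(list(clusters = list(), membership = integer()))
  }
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(edges) > 0) {
    if (any(edges$weight < 0)) stop("edge weights must be >= 0",
                                    call. = FALSE)
    for (i in seq_len(nrow(edges))) {
      a <- edges$from[i]; b <- edges$to[i]; w <- edges$weight[i]
      M[a, b] <- max(M[a, b], w)
      M[b, a] <- max(M[b, a], w)
    }
  }
  diag(M) <- 0
  loop <- apply(M, 2, max)
  loop[loop == 0] <- 1
  diag(M) <- loop
  M <- sweep(M, 2, colSums(M), "/")
  for (it in seq_len(max_iter)) {
    prev <- M
    # expansion
    P <- M
    for (e in seq_len(expansion - 1L)) P <- P %*% M
    M <- P
    # inflation (elementwise power + renormalisation), then pruning of
    # small normalised entries and a final renormalisation
    M <- M^inflation
    cs <- colSums(M)
    cs[cs == 0] <- 1
    M <- sweep(M, 2, cs, "/")
    M[M < prune] <- 0
    cs <- colSums(M)
    cs[cs == 0] <- 1
    M <- sweep(M, 2, cs, "/")
    # quantize so exact graph symmetries survive: without this, sub-1e-15
    # arithmetic noise between tied attractors is amplified by inflation
    # and breaks mathematical ties unpredictably
    M <- round(M, 12)
    if (max(abs(M - prev)) < tol) break
  }
  attractors <- ids[diag(M) > 1e-4]
  if (length(attractors) == 0) attractors <- ids  # pathological; no-op split
  sub <- M[attractors, , drop = FALSE]
  assign_to <- vapply(seq_len(n), function(j) {
    flows <- sub[, j]
    attractors[which(flows == max(flows))[1]]  # attractors sorted -> lexicographic tie-break
  }, character(1))
  # merge attractor systems: an attractor assigned to another attractor's
  # cluster pulls its own assignees along
  repeat {
    mapped <- setNames(assign_to, ids)[assign_to]
    if (identical(unname(mapped), unname(assign_to))) break
    assign_to <- unname(mapped)
  }
  groups <- split(ids, assign_to)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, character(1), 1))]
  names(groups) <- NULL
  membership <- integer(n)
  names(membership) <- ids
  for (k in seq_along(groups)) membership[groups[[k]]] <- k
  list(clusters = groups, membership = membership)
}

#' Pairwise ANI table for a set of genomes
#'
#' All-vs-all nucleotide comparison (BLASTN, word size 11 for sensitivity
#' down to ~80% identity). For each genome pair, ANI is the
#' alignment-length-weighted mean percent identity over all local
#' alignments, and the aligned fraction (AF) is the merged aligned length
#' on the shorter genome divided by its length.
#'
#' @param genomes list of [genome_record()] objects.
#' @return data frame: qid, sid (qid < sid), ani, af_shorter.
#' @export
ani_table <- function(genomes) {
  stopifnot(length(genomes) >= 1)
  seqs <- setNames(vapply(genomes, `[[`, character(1), "sequence"),
                   vapply(genomes, `[[`, character(1), "id"))
  lens <- nchar(seqs)
  hits <- blast_search(seqs, seqs, program = "blastn", evalue = 1e-3,
                       extra_args = c("-task", "blastn", "-dust", "no",
                                      "-max_target_seqs", "10000"))
  hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(data.frame(qid = character(), sid = character(), ani = numeric(),
                      af_shorter = numeric(), stringsAsFactors = FALSE))
  }
  a <- pmin(hits$qseqid, hits$sseqid)
  b <- pmax(hits$qseqid, hits$sseqid)
  rows <- lapply(split(hits, paste(a, b, sep = "\r")), function(h) {
    qid <- min(h$qseqid[1], h$sseqid[1])
    sid <- max(h$qseqid[1], h$sseqid[1])
    ani <- sum(h$pident * h$length) / sum(h$length)
    shorter <- if (lens[qid] <= lens[sid]) qid else sid
    ss <- ifelse(h$qseqid == shorter, h$qstart, pmin(h$sstart, h$send))
    ee <- ifelse(h$qseqid == shorter, h$qend, pmax(h$sstart, h$send))
    af <- merged_interval_length(ss, ee) / lens[shorter]
    data.frame(qid = qid, sid = sid, ani = ani,
               af_shorter = min(af, 1), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ANI and aligned fraction between two genomes
#'
#' @param a,b [genome_record()] objects, each at least 100 nt.
#' @return list: ani (percent), af_shorter (0-1). Genomes sharing no
#'   detectable alignment return ani NA and af_shorter 0.
#' @export
pairwise_ani <- function(a, b) {
  stopifnot(inherits(a, "genome_record"), inherits(b, "genome_record"))
  if (nchar(a$sequence) < 100 || nchar(b$sequence) < 100) {
    stop("sequences must be >= 100 nt", call. = FALSE)
  }
  if (identical(a$id, b$id)) {
    b <- genome_record(paste0(b$id, "__copy"), b$sequence)
  }
  tab <- ani_table(list(a, b))
  if (nrow(tab) == 0) return(list(ani = NA_real_, af_shorter = 0))
  list(ani = tab$ani[1], af_shorter = tab$af_shorter[1])
}

#' Build an ANI table from an external whole-genome aligner's coordinates
#'
#' Ingests tab-separated alignment coordinates in the common
#' "show-coords"-style layout (one alignment per line:
#' ref_start, ref_end, qry_start, qry_end, ref_aln_len, qry_aln_len,
#' percent_identity, ref_id, qry_id; no header) so vOTU clustering can be
#' run bit-compatibly from an external aligner's output instead of the
#' built-in BLASTN backend.
#'
#' @param path coordinate file.
#' @param lengths named numeric vector of genome lengths.
#' @return data frame compatible with [ani_table()].
#' @export
ani_from_coords <- function(path, lengths) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 9) stop("expected >= 9 tab-separated columns", call. = FALSE)
  names(df)[1:9] <- c("rstart", "rend", "qstart", "qend", "rlen_aln",
                      "qlen_aln", "pident", "rid", "qid")
  df <- df[df$rid != df$qid, , drop = FALSE]
  a <- pmin(df$rid, df$qid)
  b <- pmax(df$rid, df$qid)
  rows <- lapply(split(df, paste(a, b, sep = "\r")), function(h) {
    qid <- min(h$rid[1], h$qid[1]); sid <- max(h$rid[1], h$qid[1])
    w <- (h$rlen_aln + h$qlen_aln) / 2
    ani <- sum(h$pident * w) / sum(w)
    shorter <- if (lengths[qid] <= lengths[sid]) qid else sid
    ss <- ifelse(h$rid == shorter, pmin(h$rstart, h$rend),
                 pmin(h$qstart, h$qend))
    ee <- ifelse(h$rid == shorter, pmax(h$rstart, h$rend),
                 pmax(h$qstart, h$qend))
    af <- merged_interval_length(ss, ee) / lengths[shorter]
    data.frame(qid = qid, sid = sid, ani = ani, af_shorter = min(af, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Greedy dereplication of genomes into vOTUs
#'
#' Genomes are sorted by decreasing length (ties: lexicographic id) and
#' processed greedily: each genome joins the first existing representative
#' it matches at `min_ani` / `min_af`, otherwise it founds a new cluster,
#' so the longest sequence of each cluster is its representative. If
#' override ids are given (isolate or reference genomes that should
#' represent their cluster regardless of length), any cluster containing
#' one is re-pointed at that id.
#'
#' @param genomes list of [genome_record()] objects.
#' @param min_ani ANI threshold in percent (default 95).
#' @param min_af aligned-fraction threshold (default 0.85).
#' @param overrides optional character vector of preferred representative
#'   ids.
#' @param ani optional precomputed [ani_table()] result.
#' @return list of clusters, each a list(representative, members); class
#'   `votu_set`.
#' @export
cluster_votus <- function(genomes, min_ani = 95, min_af = 0.85,
                          overrides = NULL, ani = NULL) {
  ids <- vapply(genomes, `[[`, character(1), "id")
  lens <- vapply(genomes, function(g) nchar(g$sequence), numeric(1))
  if (anyDuplicated(ids)) stop("duplicate genome ids", call. = FALSE)
  if (is.null(ani)) ani <- ani_table(genomes)
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
  ani_of <- setNames(ani$ani, key(ani$qid, ani$sid))
  af_of <- setNames(ani$af_shorter, key(ani$qid, ani$sid))
  ord <- order(-lens, ids)
  reps <- character()
  members <- list()
  for (i in ord) {
    g <- ids[i]
    joined <- FALSE
    for (r in seq_along(reps)) {
      k <- key(g, reps[r])
      if (!is.na(ani_of[k]) && ani_of[k] >= min_ani &&
          af_of[k] >= min_af) {
        members[[r]] <- c(members[[r]], g)
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, g)
      members[[length(reps)]] <- g
    }
  }
  clusters <- lapply(seq_along(reps), function(r) {
    rep_id <- reps[r]
    ov <- sort(intersect(overrides, members[[r]]))
    if (length(ov) > 0) rep_id <- ov[1]
    list(representative = unname(rep_id), members = unname(sort(members[[r]])))
  })
  structure(clusters, class = "votu_set")
}

#' @export
print.votu_set <- function(x, ...) {
  cat(sprintf("<votu_set> %d vOTUs over %d genomes\n", length(x),
              sum(vapply(x, function(cl) length(cl$members), integer(1)))))
  invisible(x)
}

#' Genome-wide AAI edges for a set of proteomes
#'
#' One all-vs-all BLASTP over all proteins; for every ordered genome pair
#' the best hit per query protein is kept if it covers at least `min_cov`
#' of both query and subject at E <= `max_evalue`. Per unordered pair:
#' AAI is the mean percent identity over the retained best hits of both
#' directions; the cumulative bit score (mean of the two directional
#' sums) is normalised by the smaller of the two genomes' self-hit score
#' sums, so a genome against itself scores exactly 1.
#'
#' @param proteomes named list: genome id -> named character vector of
#'   proteins.
#' @param min_cov minimum query and subject coverage (default 0.50).
#' @param max_evalue E-value ceiling (default 1e-5).
#' @return data frame: qid, sid (qid < sid), aai, n_shared,
#'   norm_cum_bitscore.
#' @export
aai_edges <- function(proteomes, min_cov = 0.50, max_evalue = 1e-5) {
  stopifnot(is.list(proteomes), !is.null(names(proteomes)))
  genome_of <- unlist(lapply(names(proteomes), function(g) {
    setNames(rep(g, length(proteomes[[g]])), names(proteomes[[g]]))
  }))
  if (anyDuplicated(names(genome_of))) {
    stop("protein ids must be unique across genomes", call. = FALSE)
  }
  all_prot <- unlist(unname(proteomes))
  names(all_prot) <- names(genome_of)
  hits <- blast_search(all_prot, all_prot, program = "blastp",
                       evalue = max_evalue,
                       extra_args = c("-max_target_seqs", "10000"))
  empty <- data.frame(qid = character(), sid = character(), aai = numeric(),
                      n_shared = numeric(), norm_cum_bitscore = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(empty)
  hits$qgen <- genome_of[hits$qseqid]
  hits$sgen <- genome_of[hits$sseqid]
  hits$qcov <- (hits$qend - hits$qstart + 1) / hits$qlen
  hits$scov <- (abs(hits$send - hits$sstart) + 1) / hits$slen
  self_sum <- vapply(names(proteomes), function(g) {
    sh <- hits[hits$qseqid == hits$sseqid & hits$qgen == g, , drop = FALSE]
    sum(sh$bitscore)
  }, numeric(1))
  hits <- hits[hits$qgen != hits$sgen &
                 hits$qcov >= min_cov & hits$scov >= min_cov &
                 hits$evalue <= max_evalue, , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  # best hit per query protein per subject genome (ties: identity, then id)
  ord <- order(hits$qseqid, hits$sgen, -hits$bitscore, -hits$pident,
               hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$qseqid, hits$sgen, sep = "\r")), ,
               drop = FALSE]
  a <- pmin(hits$qgen, hits$sgen)
  b <- pmax(hits$qgen, hits$sgen)
  rows <- lapply(split(hits, paste(a, b, sep = "\r")), function(h) {
    qid <- min(h$qgen[1], h$sgen[1]); sid <- max(h$qgen[1], h$sgen[1])
    fwd <- h[h$qgen == qid, , drop = FALSE]
    rev <- h[h$qgen == sid, , drop = FALSE]
    cum <- mean(c(sum(fwd$bitscore), sum(rev$bitscore)))
    data.frame(qid = qid, sid = sid,
               aai = mean(h$pident),
               n_shared = mean(c(nrow(fwd), nrow(rev))),
               norm_cum_bitscore = cum / min(self_sum[qid], self_sum[sid]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genome-wide AAI of a single genome pair
#' @param proteins_a,proteins_b named character vectors of proteins.
#' @inheritParams aai_edges
#' @return list: aai, n_shared, norm_cum_bitscore (0 when no qualifying
#'   hits are shared).
#' @export
pairwise_aai <- function(proteins_a, proteins_b, min_cov = 0.50,
                         max_evalue = 1e-5) {
  stopifnot(length(proteins_a) >= 1, length(proteins_b) >= 1)
  names(proteins_a) <- paste0("gA.", names(proteins_a))
  names(proteins_b) <- paste0("gB.", names(proteins_b))
  tab <- aai_edges(list(gA = proteins_a, gB = proteins_b),
                   min_cov = min_cov, max_evalue = max_evalue)
  if (nrow(tab) == 0) {
    return(list(aai = NA_real_, n_shared = 0, norm_cum_bitscore = 0))
  }
  list(aai = tab$aai[1], n_shared = tab$n_shared[1],
       norm_cum_bitscore = tab$norm_cum_bitscore[1])
}

#' Group genomes by genome-wide AAI with Markov clustering
#'
#' Edges below the normalised cumulative bit-score floor are discarded,
#' remaining edges are weighted by AAI, and the graph is clustered with
#' [mcl_cluster()] at the given inflation.
#'
#' @param edges data frame from [aai_edges()].
#' @param genome_ids all genome ids (isolated genomes become singletons).
#' @param inflation Markov-clustering inflation (default 1.1).
#' @param min_norm_score minimum normalised cumulative bit score for an
#'   edge to be retained (default 0.05).
#' @return result of [mcl_cluster()].
#' @export
aai_groups <- function(edges, genome_ids = NULL, inflation = 1.1,
                       min_norm_score = 0.05) {
  keep <- edges[!is.na(edges$norm_cum_bitscore) &
                  edges$norm_cum_bitscore >= min_norm_score, , drop = FALSE]
  mcl_cluster(data.frame(from = keep$qid, to = keep$sid, weight = keep$aai,
                         stringsAsFactors = FALSE),
              inflation = inflation, nodes = genome_ids)
}
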