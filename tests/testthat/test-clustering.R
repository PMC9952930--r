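test_that("Markov clustering handles degenerate and well-separated graphs", {
  # two 4-node cliques, no connecting edge
  cl <- expand.grid(a = 1:4, b = 1:4)
  cl <- cl[cl$a < cl$b, ]
  edges <- rbind(
    data.frame(from = paste0("a", cl$a), to = paste0("a", cl$b), weight = 1),
    data.frame(from = paste0("b", cl$a), to = paste0("b", cl$b), weight = 1))
  out <- mcl_cluster(edges, inflation = 2)
  expect_length(out$clusters, 2)
  expect_equal(out$clusters[[1]], paste0("a", 1:4))
  expect_equal(out$clusters[[2]], paste0("b", 1:4))

  # single node; empty graph
  one <- mcl_cluster(data.frame(from = character(), to = character(),
                                weight = numeric()), nodes = "x")
  expect_equal(one$clusters, list("x"))
  none <- mcl_cluster(data.frame(from = character(), to = character(),
                                 weight = numeric()))
  expect_length(none$clusters, 0)

  # high inflation on weakly bridged cliques recovers the cliques
  bridged <- rbind(edges, data.frame(from = "a1", to = "b1", weight = 0.1))
  hi <- mcl_cluster(bridged, inflation = 10)
  expect_length(hi$clusters, 2)
})

test_that("pairwise ANI behaves on identical, mutated and unrelated genomes", {
  set.seed(201)
  a <- genome_record("a", virotax:::random_dna(20000, 0.45))
  self <- pairwise_ani(a, a)
  expect_equal(self$ani, 100)
  expect_equal(self$af_shorter, 1.0)

  # 4% substitutions: ANI within 0.5 of 96, AF >= 0.95
  set.seed(202)
  b <- genome_record("b", virotax:::mutate_dna(a$sequence, 0.04))
  ab <- pairwise_ani(a, b)
  expect_lt(abs(ab$ani - 96), 0.5)
  expect_gte(ab$af_shorter, 0.95)
  # symmetry
  ba <- pairwise_ani(b, a)
  expect_lt(abs(ab$ani - ba$ani), 0.1)
  expect_equal(ab$af_shorter, ba$af_shorter)

  # unrelated random genomes barely align
  set.seed(203)
  c_ <- genome_record("c", virotax:::random_dna(20000, 0.45))
  ac <- pairwise_ani(a, c_)
  expect_lt(ac$af_shorter, 0.05)

  expect_error(pairwise_ani(genome_record("s", "ACGT"), a), ">= 100 nt")
})

test_that("greedy vOTU clustering respects thresholds, order and overrides", {
  set.seed(211)
  base <- virotax:::random_dna(20000, 0.45)
  g1 <- genome_record("g1", base)
  g2 <- genome_record("g2", base)
  g3 <- genome_record("g3", base)
  v <- cluster_votus(list(g1, g2, g3))
  expect_length(v, 1)
  expect_equal(v[[1]]$members, c("g1", "g2", "g3"))

  # ANI above threshold but AF ~0.5: the pair stays apart
  set.seed(212)
  half <- paste0(virotax:::mutate_dna(substr(base, 1, 10000), 0.03),
                 virotax:::random_dna(10000, 0.45))
  g4 <- genome_record("g4", half)
  v2 <- cluster_votus(list(g1, g4))
  expect_length(v2, 2)

  # planted clusters with near-duplicates recover the exact truth
  set.seed(213)
  genomes <- list()
  truth <- integer()
  for (k in 1:5) {
    src <- virotax:::random_dna(15000 + 1000 * k, 0.45)
    for (j in 1:3) {
      id <- sprintf("c%d_m%d", k, j)
      s <- if (j == 1) src else virotax:::mutate_dna(src, 0.02)
      genomes[[id]] <- genome_record(id, s)
      truth[id] <- k
    }
  }
  v3 <- cluster_votus(genomes)
  expect_length(v3, 5)
  for (cl in v3) {
    expect_length(unique(truth[cl$members]), 1)
    expect_length(cl$members, 3)
    # longest member is the representative (all same length here: first id)
    expect_equal(cl$representative, sort(cl$members)[1])
  }

  # override re-points the representative
  v4 <- cluster_votus(genomes, overrides = "c1_m3")
  hit <- Filter(function(cl) "c1_m3" %in% cl$members, v4)[[1]]
  expect_equal(hit$representative, "c1_m3")
})

test_that("pairwise AAI matches an independent alignment oracle", {
  set.seed(221)
  pa <- setNames(vapply(1:20, function(i) virotax:::random_protein(250),
                        character(1)), sprintf("pa_%d", 1:20))
  # genome B shares mutated copies of 4 of A's genes plus 16 unrelated
  shared_idx <- 1:4
  pb <- c(vapply(pa[shared_idx],
                 function(p) virotax:::mutate_protein(p, 0.2),
                 character(1)),
          vapply(1:16, function(i) virotax:::random_protein(250),
                 character(1)))
  names(pb) <- sprintf("pb_%d", 1:20)

  self <- pairwise_aai(pa, pa)
  expect_equal(self$aai, 100)
  expect_equal(self$norm_cum_bitscore, 1.0)
  expect_equal(self$n_shared, 20)

  ab <- pairwise_aai(pa, pb)
  expect_equal(ab$n_shared, 4)
  # independent oracle: global alignment identity per shared gene pair
  oracle <- mean(vapply(shared_idx, function(i) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(pa[[i]]), Biostrings::AAString(pb[[i]]),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
    Biostrings::pid(al)
  }, numeric(1)))
  expect_lt(abs(ab$aai - oracle), 2)
  expect_gt(ab$norm_cum_bitscore, 0)
  expect_lt(ab$norm_cum_bitscore, 1)

  # disjoint proteomes: zero edge
  set.seed(222)
  pc <- setNames(vapply(1:10, function(i) virotax:::random_protein(250),
                        character(1)), sprintf("pc_%d", 1:10))
  ac <- pairwise_aai(pa, pc)
  expect_equal(ac$norm_cum_bitscore, 0)
})

test_that("AAI grouping recovers planted group structure", {
  af <- generate_aai_fixture(n_groups = 3, genomes_per_group = 3,
                             n_genes = 12, seed = 223)
  edges <- aai_edges(af$proteomes)
  within <- substr(edges$qid, 1, 5) == substr(edges$sid, 1, 5)
  expect_true(all(edges$norm_cum_bitscore[within] >= 0.05))
  grp <- aai_groups(edges, genome_ids = names(af$proteomes))
  expect_length(grp$clusters, 3)
  for (g in unique(af$truth)) {
    members <- names(af$truth)[af$truth == g]
    expect_length(unique(grp$membership[members]), 1)
  }
})
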