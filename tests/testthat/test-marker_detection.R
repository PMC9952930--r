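test_that("marker search finds planted markers and rejects shuffles", {
  fx <- small_fixture()
  ps <- small_profiles()
  # a genome's planted MCP protein scores high against its own family set
  mcp <- fx$marker_refs$MCP[1]
  hits <- search_markers(setNames(mcp, "fam01-g01_1"), ps)
  expect_gt(nrow(hits), 0)
  mcp_hits <- hits[hits$marker == "MCP", ]
  expect_gte(max(mcp_hits$bit_score), 100)
  expect_true(all(hits$e_value <= 0.01))
  expect_true(all(hits$bit_score >= 40))
  expect_true(all(hits$profile_coverage > 0 & hits$profile_coverage <= 1))

  # residue-shuffled protein of identical composition: no hit
  set.seed(71)
  shuffled <- paste(sample(strsplit(mcp, "")[[1]]), collapse = "")
  expect_equal(nrow(search_markers(setNames(shuffled, "shuf_1"), ps)), 0)

  # empty input
  expect_equal(nrow(search_markers(character(), ps)), 0)

  # determinism: identical repeated runs
  again <- search_markers(setNames(mcp, "fam01-g01_1"), ps)
  expect_identical(hits, again)
})

test_that("best-hit reduction keeps the top hit per genome and marker", {
  hits <- data.frame(
    genome_id = c("g1", "g1", "g1", "g1", "g2"),
    marker = c("MCP", "MCP", "ATPase", "PRO", "MCP"),
    profile_id = c("MCP_001", "MCP_002", "ATPase_001", "PRO_001", "MCP_001"),
    protein_id = c("g1_1", "g1_1", "g1_2", "g1_3", "g2_1"),
    bit_score = c(80, 120, 60, 55, 45),
    e_value = c(1e-20, 1e-30, 1e-9, 1e-8, 1e-5),
    profile_coverage = c(0.9, 0.95, 0.8, 0.7, 0.65),
    stringsAsFactors = FALSE)
  best <- best_hits(hits)
  g1_mcp <- best[best$genome_id == "g1" & best$marker == "MCP", ]
  expect_equal(g1_mcp$bit_score, 120)
  expect_equal(unique(best$n_markers_detected[best$genome_id == "g1"]), 3L)
  expect_equal(best$n_markers_detected[best$genome_id == "g2"], 1L)

  # tie on score resolves by lower E-value, then profile id
  tie <- hits[1:2, ]
  tie$bit_score <- c(100, 100)
  tie$e_value <- c(1e-30, 1e-20)
  expect_equal(best_hits(tie)$profile_id, "MCP_001")
  tie$e_value <- c(1e-30, 1e-30)
  tie$profile_id <- c("MCP_B", "MCP_A")
  expect_equal(best_hits(tie)$profile_id, "MCP_A")
})

test_that("class demarcation keys on the MCP score with the documented flags", {
  mk <- function(scores) {
    data.frame(genome_id = "g", marker = names(scores),
               profile_id = paste0(names(scores), "_001"),
               protein_id = paste0("g_", seq_along(scores)),
               bit_score = unname(scores), e_value = 1e-10,
               profile_coverage = 0.9,
               n_markers_detected = sum(names(scores) != "PLV"),
               stringsAsFactors = FALSE)
  }
  # strong MCP assigns the class; the call flips exactly at 50 bits
  expect_true(assign_class(mk(c(MCP = 120)))$in_maveriviricetes)
  expect_true(assign_class(mk(c(MCP = 50)))$in_maveriviricetes)
  expect_false(assign_class(mk(c(MCP = 49.9)))$in_maveriviricetes)

  # three strong non-MCP markers without a qualifying MCP: candidate
  cand <- assign_class(mk(c(MCP = 49, ATPase = 200, PRO = 150,
                            Penton = 90)))
  expect_false(cand$in_maveriviricetes)
  expect_true(cand$candidate_flag)

  # PLV hit flags only non-class genomes
  plv <- assign_class(mk(c(PLV = 60)))
  expect_true(plv$possible_plv)
  both <- assign_class(mk(c(MCP = 120, PLV = 60)))
  expect_true(both$in_maveriviricetes)
  expect_false(both$possible_plv)

  # monotonicity: raising the MCP score never loses the class
  for (s in c(50, 60, 100, 500)) {
    expect_true(assign_class(mk(c(MCP = s)))$in_maveriviricetes)
  }

  # genomes with no hits are reported, unassigned
  none <- assign_class(mk(c(MCP = 120)), genome_ids = c("g", "empty"))
  expect_equal(nrow(none), 2)
  expect_false(none$in_maveriviricetes[none$genome_id == "empty"])
})

test_that("profile-coverage filtering flips exactly at the threshold", {
  hits <- data.frame(genome_id = "g", marker = "MCP", profile_id = "p",
                     protein_id = "g_1", bit_score = 100, e_value = 1e-10,
                     profile_coverage = c(0.59, 0.60, 0.61),
                     stringsAsFactors = FALSE)
  kept <- filter_by_profile_coverage(hits)
  expect_equal(kept$profile_coverage, c(0.60, 0.61))
  expect_equal(nrow(filter_by_profile_coverage(hits[0, ])), 0)
})

test_that("profile building clusters references and enforces the group floor", {
  set.seed(81)
  base <- virotax:::random_protein(300)
  near <- vapply(1:30, function(i) virotax:::mutate_protein(base, 0.05),
                 character(1))
  names(near) <- sprintf("n%02d", 1:30)
  ps1 <- build_marker_profiles(list(MCP = near),
                               tempfile(fileext = ".hmm"))
  expect_equal(unname(attr(ps1, "n_profiles")["MCP"]), 1L)

  # two divergent 15-member groups split into two profiles
  base2 <- virotax:::random_protein(300)
  far <- vapply(1:15, function(i) virotax:::mutate_protein(base2, 0.05),
                character(1))
  names(far) <- sprintf("f%02d", 1:15)
  ps2 <- build_marker_profiles(list(ATPase = c(near[1:15], far)),
                               tempfile(fileext = ".hmm"))
  expect_equal(unname(attr(ps2, "n_profiles")["ATPase"]), 2L)

  # fewer sequences than the group floor is an error
  expect_error(build_marker_profiles(list(PRO = near[1:9]),
                                     tempfile(fileext = ".hmm")),
               "insufficient references")
})
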