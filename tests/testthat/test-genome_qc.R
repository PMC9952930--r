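test_that("planted terminal repeats are detected with the right kind", {
  set.seed(1)
  x <- virotax:::random_dna(1000, 0.45)
  R <- virotax:::random_dna(15, 0.5)
  d <- detect_terminal_repeats(paste0(R, x, R))
  expect_equal(d$kind, "direct")
  expect_equal(d$length, 15)
  expect_equal(d$repeat_seq, R)
  i <- detect_terminal_repeats(paste0(R, x, virotax:::revcomp(R)))
  expect_equal(i$kind, "inverted")
  expect_equal(i$length, 15)

  # detection flips exactly at the 10-nt floor
  expect_null(detect_terminal_repeats(paste0(substr(R, 1, 9), x,
                                             substr(R, 1, 9))))
  d10 <- detect_terminal_repeats(paste0(substr(R, 1, 10), x,
                                        substr(R, 1, 10)))
  expect_equal(d10$length, 10)

  # direct preferred over inverted at equal length (palindromic repeat)
  P <- "AAAAATTTTT"  # its own reverse complement
  dp <- detect_terminal_repeats(paste0(P, x, P))
  expect_equal(dp$kind, "direct")
})

test_that("terminal-repeat search equals the exhaustive oracle on short sequences", {
  set.seed(31)
  cases <- list()
  for (k in 1:12) {
    n <- sample(100:2000, 1)
    s <- virotax:::random_dna(n, runif(1, 0.3, 0.7))
    if (k %% 3 == 0) {  # plant a repeat of random length
      r <- virotax:::random_dna(sample(10:40, 1), 0.5)
      s <- paste0(r, s, if (k %% 2) r else virotax:::revcomp(r))
    }
    cases[[k]] <- s
  }
  for (s in cases) {
    got <- detect_terminal_repeats(s)
    want <- oracle_terminal_repeat(s)
    expect_equal(got, want)
  }
})

test_that("DTR trimming removes the 3' copy and is idempotent", {
  set.seed(1)
  core <- virotax:::random_dna(20000, 0.4)
  R <- substr(core, 1, 15)
  g <- genome_record("g", paste0(core, R))
  expect_equal(nchar(g$sequence), 20015)
  d <- detect_terminal_repeats(g)
  tr <- trim_dtr(g, d)
  expect_equal(nchar(tr$genome$sequence), 20000)
  expect_equal(tr$report$original_length - tr$report$trimmed_length,
               d$length)
  expect_equal(tr$genome$topology, "dtr_trimmed")
  expect_null(detect_terminal_repeats(tr$genome))

  itr <- list(kind = "inverted", length = 15, repeat_seq = R)
  expect_error(trim_dtr(g, itr), "ITRs are not trimmed")
})

test_that("junction-spanning genes are rotated into contiguity after trimming", {
  set.seed(4)
  ct <- virotax:::codons_by_aa()
  prot <- virotax:::random_protein(100)
  cassette <- paste0("TAA", virotax:::back_translate(prot, ct), "TAA")
  set.seed(40)
  spacer <- virotax:::random_dna(1500, 0.4)
  core <- paste0(cassette, spacer)
  # rotate so the gene spans the end/start junction, then append a DTR
  cut <- 150L
  n <- nchar(core)
  rotated <- paste0(substr(core, cut + 1, n), substr(core, 1, cut))
  g <- genome_record("g", paste0(rotated, substr(rotated, 1, 20)))
  d <- detect_terminal_repeats(g)
  expect_gte(d$length, 20)
  tr <- trim_dtr(g, d)
  expect_equal(tr$report$start_shift,
               oracle_junction_shift(substr(rotated, 1, n)))
  calls <- call_orfs(tr$genome, min_aa = 50)
  expect_true(prot %in% calls$protein)
})

test_that("GC profile windows behave at the boundaries", {
  s <- "GGCCAATT"
  expect_equal(gc_profile(s, window = 8), virotax:::gc_content(s))
  expect_equal(gc_profile(s, window = 100), 0.5)
  p <- gc_profile(paste0(strrep("G", 100), strrep("A", 100)), window = 100)
  expect_equal(p, c(1, 0))
})

test_that("integration screen reports long gaps and GC-shift boundaries", {
  set.seed(51)
  # uniform genome, dense gene calls: nothing to report
  g <- genome_record("u", virotax:::random_dna(12000, 0.45))
  calls <- data.frame(genome_id = "u", gene_index = 1:12,
                      start = seq(1, 11001, by = 1000),
                      end = seq(900, 11900, by = 1000),
                      strand = "+", protein = "M", stringsAsFactors = FALSE)
  scr <- screen_integration(g, calls)
  expect_equal(nrow(scr$long_intergenic_regions), 0)
  expect_length(scr$candidate_boundaries, 0)

  # a 1200-nt intergenic gap is listed
  calls2 <- calls[-c(6, 7), ]
  scr2 <- screen_integration(g, calls2)
  expect_equal(nrow(scr2$long_intergenic_regions), 1)
  gap_len <- scr2$long_intergenic_regions$end -
    scr2$long_intergenic_regions$start + 1
  expect_gte(gap_len, 1200)

  # 10-kb 60% GC host + 20-kb 35% GC element: boundary within 500 nt
  set.seed(52)
  host <- virotax:::random_dna(10000, 0.60)
  elem <- virotax:::random_dna(20000, 0.35)
  gb <- genome_record("b", paste0(host, elem))
  scr3 <- screen_integration(gb, data.frame(
    genome_id = character(), gene_index = integer(), start = integer(),
    end = integer(), strand = character(), protein = character(),
    stringsAsFactors = FALSE))
  expect_true(any(abs(scr3$candidate_boundaries - 10000) <= 500))
})

test_that("host-region excision keeps coordinate bookkeeping intact", {
  set.seed(61)
  g <- genome_record("g", virotax:::random_dna(40000, 0.5))
  tr <- trim_host_region(g, c(10001, 30000))
  expect_equal(nchar(tr$genome$sequence), 20000)
  expect_equal(substr(g$sequence, tr$report$element_start,
                      tr$report$element_end), tr$genome$sequence)
  whole <- trim_host_region(g, c(1, 40000))
  expect_equal(whole$genome$sequence, g$sequence)
  expect_error(trim_host_region(g, c(0, 100)), "boundaries")
})

test_that("completeness categories follow the documented precedence", {
  lin <- function(n) genome_record("g", strrep("ACGT", n / 4))
  expect_equal(call_completeness(lin(26000))$category, "large_linear")
  expect_true(call_completeness(lin(26000))$complete_or_near)
  # flips exactly at 25,000 nt
  expect_equal(call_completeness(lin(25000))$category, "large_linear")
  expect_equal(call_completeness(lin(24996))$category, "partial")
  expect_false(call_completeness(lin(24996))$complete_or_near)

  # external completeness estimate: >= 90 qualifies
  expect_equal(call_completeness(lin(20000), checkv_estimate = 91)$category,
               "checkv_high")
  expect_equal(call_completeness(lin(20000), checkv_estimate = 89)$category,
               "partial")

  # repeats beat the CheckV category; direct beats inverted
  dtr <- list(kind = "direct", length = 20, repeat_seq = "X")
  itr <- list(kind = "inverted", length = 20, repeat_seq = "X")
  expect_equal(call_completeness(lin(20000), repeat_hit = dtr,
                                 checkv_estimate = 95)$category, "dtr")
  expect_equal(call_completeness(lin(20000), repeat_hit = itr)$category,
               "itr")

  # integrated with >= 2 kb host-like flanks on both sides wins over dtr
  integ <- list(host_like_segments = data.frame(start = c(1, 38001),
                                                end = c(2500, 40000)))
  expect_equal(call_completeness(lin(40000), repeat_hit = dtr,
                                 integration = integ)$category,
               "integrated_flanked")
  # a single flank is not enough
  one <- list(host_like_segments = data.frame(start = 1, end = 2500))
  expect_equal(call_completeness(lin(40000), integration = one)$category,
               "large_linear")

  expect_equal(call_completeness(lin(100),
                                 is_isolate_reference = TRUE)$category,
               "isolate_reference")
})
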