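test_that("SSR scanner agrees with the per-position oracle", {
  set.seed(101)
  for (rep in 1:25) {
    S <- rand_dna(1500, gc = runif(1, 0.3, 0.6))
    # plant a couple of tracts to keep the comparison non-vacuous
    d <- o_chars(S)
    d[301:312] <- o_chars(strrep("A", 12))
    d[801:812] <- o_chars(strrep("AT", 6))
    S <- o_collapse(d)
    got <- find_ssrs(circular_sequence(S, circular = FALSE), min_tract = 10)
    want <- oracle_find_ssrs(S, min_tract = 10)
    expect_equal(got$start, want$start)
    expect_equal(got$motif, want$motif)
    expect_equal(got$copies, want$copies)
    expect_equal(got$tract_len, want$tract_len)
  }
})

test_that("planted tracts are exactly maximal, mono beats di-'AA'", {
  s <- circular_sequence(paste0("GC", strrep("A", 12), "GG", strrep("AT", 6),
                                "CCC"), circular = FALSE)
  loci <- find_ssrs(s, min_tract = 10)
  expect_equal(nrow(loci), 2L)
  expect_equal(loci$motif, c("A", "AT"))      # poly-A reported as mono only
  expect_equal(loci$copies, c(12L, 6L))
  expect_equal(loci$start, c(2L, 16L))
})

test_that("circular scanning detects origin-spanning tracts once", {
  # 5 A's at the end + 7 A's at the start = one 12-base tract over the origin
  set.seed(2)
  mid <- rand_dna(400)
  s <- circular_sequence(paste0(strrep("A", 7), "C", mid, "G", strrep("A", 5)))
  loci <- find_ssrs(s, min_tract = 10)
  polyA <- loci[loci$motif == "A", ]
  expect_equal(nrow(polyA), 1L)
  expect_equal(polyA$start, nchar(s$seq) - 5L)
  expect_equal(polyA$tract_len, 12L)
})

test_that("non-repetitive sequences and N runs yield no SSRs", {
  expect_equal(nrow(find_ssrs(circular_sequence("ACGGTCACTGATCGCATTGACCTGAT",
                                                circular = FALSE))), 0L)
  expect_equal(nrow(find_ssrs(circular_sequence(strrep("N", 40),
                                                circular = FALSE))), 0L)
})

test_that("canonical motifs make the scan strand-symmetric", {
  set.seed(55)
  for (rep in 1:10) {
    S <- rand_dna(800)
    d <- o_chars(S)
    d[101:115] <- o_chars(strrep("AAG", 5))
    d[401:412] <- o_chars(strrep("CT", 6))
    S <- o_collapse(d)
    f <- find_ssrs(circular_sequence(S, circular = FALSE), min_tract = 10)
    r <- find_ssrs(circular_sequence(o_revcomp(S), circular = FALSE),
                   min_tract = 10)
    expect_equal(sort(paste(f$motif, f$tract_len)),
                 sort(paste(r$motif, r$tract_len)))
    # coordinates mirror up to the phase slack of a partial trailing copy
    # (tracts are left-anchored to whole copies on whichever strand is read)
    L <- nchar(S)
    expect_true(all(abs(sort(r$start) -
                          sort(L - (f$start + f$tract_len))) < 6))
  }
})

test_that("SSR summary reproduces the printed-class arithmetic", {
  # a locus table with class counts 28/11/13/15/10/9
  counts <- c(28, 11, 13, 15, 10, 9)
  loci <- data.frame(motif_len = rep(1:6, counts))
  s <- summarize_ssrs(loci)
  expect_equal(s$total, 86)
  expect_equal(unname(s$counts), counts)
  expect_equal(s$frequency[["mono"]], 32.56)
  expect_equal(sum(s$frequency), 100, tolerance = 0.06 / 100)

  empty <- summarize_ssrs(data.frame(motif_len = integer()))
  expect_equal(empty$total, 0)
  expect_equal(unname(empty$frequency), rep(0, 6))
})

test_that("SSR summary frequencies always sum to ~100", {
  set.seed(77)
  for (rep in 1:20) {
    loci <- data.frame(motif_len = sample(1:6, sample(1:60, 1), replace = TRUE))
    s <- summarize_ssrs(loci)
    expect_lt(abs(sum(s$frequency) - 100), 0.06)
  }
})

test_that("long-repeat scanner agrees with the all-pairs oracle", {
  set.seed(202)
  for (rep in 1:10) {
    d <- o_chars(rand_dna(2000))
    # plant a direct pair and an inverted pair with guard breaks
    core1 <- rand_dna(60); core2 <- rand_dna(45)
    d[101:160] <- o_chars(core1); d[1001:1060] <- o_chars(core1)
    d[100] <- "A"; d[161] <- "A"; d[1000] <- "C"; d[1061] <- "C"
    d[1401:1445] <- o_chars(core2); d[1701:1745] <- o_chars(o_revcomp(core2))
    d[1400] <- "A"; d[1446] <- "A"; d[1700] <- "A"; d[1746] <- "A"
    S <- o_collapse(d)
    got <- find_long_repeats(circular_sequence(S, circular = FALSE),
                             min_len = 30)
    want <- oracle_long_repeats(S, min_len = 30)
    expect_equal(got$kind, want$kind)
    expect_equal(got$start1, want$start1)
    expect_equal(got$start2, want$start2)
    expect_equal(got$length, want$length)
    expect_true(any(got$kind == "direct" & got$length == 60))
    expect_true(any(got$kind == "inverted" & got$length == 45))
  }
})

test_that("repeat multiset is reverse-complement invariant", {
  set.seed(33)
  d <- o_chars(rand_dna(1500))
  core <- rand_dna(40)
  d[201:240] <- o_chars(core); d[901:940] <- o_chars(core)
  d[200] <- "A"; d[241] <- "A"; d[900] <- "C"; d[941] <- "C"
  S <- o_collapse(d)
  f <- find_long_repeats(circular_sequence(S, circular = FALSE), min_len = 30)
  r <- find_long_repeats(circular_sequence(o_revcomp(S), circular = FALSE),
                         min_len = 30)
  expect_equal(sort(paste(f$kind, f$length)), sort(paste(r$kind, r$length)))
})

test_that("five planted repeats above 50 bp are counted as five", {
  plants <- data.frame(
    kind = c("direct", "direct", "inverted", "direct", "inverted", "direct"),
    length = c(78L, 62L, 58L, 55L, 52L, 40L),
    region1 = "LSC", region2 = c("LSC", "SSC", "LSC", "SSC", "LSC", "SSC"),
    stringsAsFactors = FALSE)
  sim <- simulate_plastome(sim_params("test", seed = 61,
                                      repeat_plants = plants))
  ir <- find_inverted_repeat_pair(sim$genome$sequence, min_len = 1000)
  reps <- find_long_repeats(sim$genome$sequence, min_len = 30,
                            ir_exclude = ir)
  expect_equal(sum(reps$length > 50), 5L)
  expect_equal(nrow(reps), 6L)
})

test_that("the genome-scale IR pair is excluded, smaller IR-interior repeats kept", {
  sim <- simulate_plastome(sim_params("test", seed = 62))
  g <- sim$genome
  ir <- find_inverted_repeat_pair(g$sequence, min_len = 1000)
  with_ir <- find_long_repeats(g$sequence, min_len = 30)
  without <- find_long_repeats(g$sequence, min_len = 30, ir_exclude = ir)
  expect_true(max(with_ir$length) >= 1500)          # the IR itself
  expect_true(!nrow(without) || max(without$length) < 1500)
  # planted pairs survive the exclusion
  for (t in seq_len(nrow(sim$truth$repeats))) {
    tr <- sim$truth$repeats[t, ]
    expect_true(any(without$kind == tr$kind & without$start1 == tr$start1 &
                      without$start2 == tr$start2 &
                      without$length == tr$length))
  }
})
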