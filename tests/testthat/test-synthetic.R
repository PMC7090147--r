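test_that("simulation is deterministic and tiles to the requested size", {
  p <- sim_params("test", seed = 77)
  a <- simulate_plastome(p)
  b <- simulate_plastome(p)
  expect_identical(a$genome$sequence$seq, b$genome$sequence$seq)
  expect_identical(a$genome$features, b$genome$features)
  expect_equal(seq_length(a$genome), 9000 + 2000 + 2 * 1500)
  pt <- a$truth$partition
  expect_equal(pt$lsc[["len"]] + pt$ssc[["len"]] + 2 * pt$ira[["len"]],
               seq_length(a$genome))
  # a different seed gives a different genome
  c2 <- simulate_plastome(sim_params("test", seed = 78))
  expect_false(identical(a$genome$sequence$seq, c2$genome$sequence$seq))
})

test_that("every planted feature is recovered at its recorded coordinates", {
  sim <- simulate_plastome(sim_params("test", seed = 55))
  g <- sim$genome
  # structure
  ir <- find_inverted_repeat_pair(g$sequence, min_len = 1000)
  expect_identical(unname(ir$ira), unname(sim$truth$partition$ira))
  # SSRs (scan at the class thresholds the plants are designed against)
  loci <- find_ssrs(g$sequence, min_tract = ssr_class_thresholds())
  for (t in seq_len(nrow(sim$truth$ssr))) {
    tr <- sim$truth$ssr[t, ]
    hit <- loci[loci$start == tr$start, ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$motif, tr$motif)
    expect_equal(hit$copies, tr$copies)
    expect_equal(hit$tract_len, tr$tract_len)
  }
  # long repeats
  reps <- find_long_repeats(g$sequence, min_len = 30, ir_exclude = ir)
  for (t in seq_len(nrow(sim$truth$repeats))) {
    tr <- sim$truth$repeats[t, ]
    expect_true(any(reps$kind == tr$kind & reps$start1 == tr$start1 &
                      reps$start2 == tr$start2 & reps$length == tr$length))
  }
  # gene features address real exon structure
  s <- summarize_annotation(g, g$partition)
  expect_equal(s$n_unique_genes, 113L)
  expect_equal(s$n_ir_duplicated, 18L)
})

test_that("plants that do not fit raise a parameter error before generation", {
  expect_error(simulate_plastome(sim_params("test", ssc_len = 600)),
               "do not fit")
  expect_error(sim_params("test", lsc_len = 100, ssc_len = 2000), "exceed")
})

test_that("mutation honors rates, spectrum and records every event", {
  sim <- simulate_plastome(sim_params("test", seed = 3))
  g <- sim$genome
  # zero rate: identical sequence
  m0 <- mutate_genome(g, 0, seed = 1)
  expect_identical(m0$genome$sequence$seq, g$sequence$seq)
  expect_equal(nrow(m0$truth$substitutions), 0L)
  # recorded substitutions actually applied
  m1 <- mutate_genome(g, 0.01, tstv = 2, seed = 2)
  d0 <- o_chars(g$sequence$seq); d1 <- o_chars(m1$genome$sequence$seq)
  changed <- which(d0 != d1) - 1L
  expect_setequal(changed, m1$truth$substitutions$pos)
  expect_identical(d1[m1$truth$substitutions$pos + 1L],
                   m1$truth$substitutions$to)
  # realized transition fraction near tstv/(tstv+1)
  big <- annotated_genome(circular_sequence(rand_dna(100000), id = "bg"))
  mb <- mutate_genome(big, 0.01, tstv = 2, seed = 5)
  ts_frac <- mean(mb$truth$substitutions$transition)
  n <- nrow(mb$truth$substitutions)
  expect_lt(abs(ts_frac - 2 / 3), 3 * sqrt((2 / 3) * (1 / 3) / n))
  # cross-module conservation: aligned spectrum total = recorded count
  spec <- substitution_spectrum(align_pair(g, m1$genome,
                                           ids = c("ref", "mut")))
  expect_equal(spec$total, nrow(m1$truth$substitutions))
})

test_that("indels stay outside genes and features remap cleanly", {
  sim <- simulate_plastome(sim_params("test", seed = 13))
  g <- sim$genome
  mi <- mutate_genome(g, 0, indel_rate = 5e-4, seed = 9)
  expect_gt(nrow(mi$truth$indels), 0L)
  # every feature still addresses the same DNA as before
  for (i in seq_len(nrow(g$features))) {
    expect_identical(plastome:::feature_sequence(mi$genome, i),
                     plastome:::feature_sequence(g, i))
  }
  net <- sum(ifelse(mi$truth$indels$type == "ins", 1, -1) *
               mi$truth$indels$len)
  expect_equal(seq_length(mi$genome), seq_length(g) + net)
})

test_that("flip_ssc is an involution that only touches the SSC", {
  sim <- simulate_plastome(sim_params("test", seed = 25))
  g <- sim$genome
  p <- g$partition
  fl <- flip_ssc(g)
  expect_true(fl$truth$ssc_flipped)
  # LSC and both IRs byte-identical
  s0 <- p$ssc[["start"]]; sl <- p$ssc[["len"]]
  expect_identical(substr(fl$genome$sequence$seq, 1, s0),
                   substr(g$sequence$seq, 1, s0))
  expect_identical(substr(fl$genome$sequence$seq, s0 + sl + 1, seq_length(g)),
                   substr(g$sequence$seq, s0 + sl + 1, seq_length(g)))
  # SSC is the reverse complement
  expect_identical(substr(fl$genome$sequence$seq, s0 + 1, s0 + sl),
                   revcomp(substr(g$sequence$seq, s0 + 1, s0 + sl)))
  # involution on sequence and features
  back <- flip_ssc(fl$genome)$genome
  expect_identical(back$sequence$seq, g$sequence$seq)
  expect_identical(back$features$strand, g$features$strand)
  for (i in seq_len(nrow(g$features))) {
    expect_equal(unname(back$features$exons[[i]]),
                 unname(g$features$exons[[i]]))
  }
})

test_that("family simulation respects the tree and optional flips", {
  tr <- ape::read.tree(
    text = "((A:0.01,B:0.012):0.008,(C:0.011,D:0.009):0.007);")
  fam <- simulate_family(tr, sim_params("test"), seed = 6, flips = "C")
  expect_setequal(names(fam$genomes), tr$tip.label)
  # zero-length branches give identical leaves
  tr0 <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  fam0 <- simulate_family(tr0, sim_params("test"), seed = 6)
  seqs <- vapply(fam0$genomes, function(g) g$sequence$seq, character(1))
  expect_equal(length(unique(seqs)), 1L)
  # the flipped leaf calls "-" against an unflipped sibling
  oc <- call_ssc_orientation(fam$genomes[["C"]], fam$genomes[["D"]])
  expect_equal(oc$orientation, "-")
  oc2 <- call_ssc_orientation(fam$genomes[["A"]], fam$genomes[["B"]])
  expect_equal(oc2$orientation, "+")
})

test_that("fullscale preset reproduces the reference architecture", {
  sim <- simulate_plastome(sim_params("fullscale", seed = 1))
  g <- sim$genome
  expect_equal(seq_length(g), 162903)
  expect_equal(sim$truth$partition$ira[["len"]], 26533)
  expect_equal(sim$truth$partition$lsc[["len"]], 90351)
  expect_equal(sim$truth$partition$ssc[["len"]], 19486)
  expect_equal(nrow(sim$truth$ssr), 86)
  expect_equal(unname(table(factor(sim$truth$ssr$motif_len, levels = 1:6))),
               c(28L, 11L, 13L, 15L, 10L, 9L), ignore_attr = TRUE)
  expect_equal(sum(sim$truth$repeats$kind == "direct"), 30)
  expect_equal(sum(sim$truth$repeats$kind == "inverted"), 19)
  expect_equal(sum(sim$truth$repeats$length > 50), 5)
  expect_equal(gc_percent(g), 36.65, tolerance = 0.01)
  s <- summarize_annotation(g, g$partition)
  expect_equal(s$mean_intron_len, 907, tolerance = 0.001)
  expect_equal(s$longest_intron$gene, "trnK-UUU")
  expect_equal(s$longest_intron$len, 2599)
})
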