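test_that("alignment loading validates shape and classifies columns", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "AC-TNT", ">b", "ACGTN-"), tf)
  aln <- load_alignment(tf)
  expect_equal(aln$n_cols, 6L)
  expect_equal(column_classes(aln),
               c("ungapped_acgt", "ungapped_acgt", "gapped",
                 "ungapped_acgt", "ambiguous", "gapped"))
  # single-row and ragged files are rejected
  tf2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT"), tf2)
  expect_error(load_alignment(tf2), "fewer than 2")
  expect_error(seq_alignment(c("ACGT", "ACG")), "ragged")
  # round trip
  tf3 <- withr::local_tempfile(fileext = ".fa")
  write_alignment(aln, tf3)
  expect_equal(load_alignment(tf3)$seqs, aln$seqs)
})

test_that("align_pair handles identity, substitutions and deletions", {
  set.seed(9)
  A <- rand_dna(4000)
  # identity
  aln0 <- align_pair(A, A)
  expect_equal(aln0$n_cols, 4000L)
  expect_false(any(grepl("-", aln0$seqs, fixed = TRUE)))

  # exactly 10 substitutions -> 10 mismatch columns, no gaps
  d <- o_chars(A)
  pos <- seq(200, 3800, length.out = 10)
  for (p in pos) d[p] <- setdiff(c("A", "C", "G", "T"), d[p])[1]
  B <- o_collapse(d)
  aln1 <- align_pair(A, B)
  M <- as.matrix(aln1)
  expect_equal(aln1$n_cols, 4000L)
  expect_equal(sum(M[1, ] != M[2, ]), 10L)
  expect_false(any(M == "-"))

  # one 50 bp deletion -> a single gap run of 50 in the second row
  C <- paste0(substr(A, 1, 1500), substr(A, 1551, 4000))
  aln2 <- align_pair(A, C)
  gaps <- rle(o_chars(aln2$seqs[2]) == "-")
  expect_equal(sum(gaps$lengths[gaps$values]), 50L)
  expect_equal(sum(gaps$values), 1L)
  expect_false(grepl("-", aln2$seqs[1], fixed = TRUE))
})

test_that("sliding pi matches the brute-force recount on planted SNPs", {
  set.seed(17)
  A <- rand_dna(5000)
  d <- o_chars(A)
  snp <- sort(sample(5000, 60))
  for (p in snp) d[p] <- setdiff(c("A", "C", "G", "T"), d[p])[1]
  # a few ambiguous and gap columns must drop out of both computations
  d[c(100, 2500)] <- "N"
  aln <- seq_alignment(c(A, o_collapse(d)), ids = c("ref", "mut"))
  for (ws in list(c(800, 50), c(600, 100), c(137, 61))) {
    prof <- sliding_pi(aln, ws[1], ws[2])
    want <- oracle_window_pi(aln$seqs[1], aln$seqs[2], ws[1], ws[2])
    expect_equal(prof$pi, want)
    expect_true(all(prof$pi >= 0 & prof$pi <= 1, na.rm = TRUE))
  }
})

test_that("pi edge cases: identical, saturated, truncated, permuted", {
  aln_same <- seq_alignment(c("ACGTACGTAC", "ACGTACGTAC"))
  expect_true(all(sliding_pi(aln_same, 4, 2)$pi == 0))
  aln_diff <- seq_alignment(c("AAAA", "CCCC"))
  expect_true(all(sliding_pi(aln_diff, 2, 1)$pi == 1))
  expect_warning(p <- sliding_pi(aln_same, 50, 10), "truncated")
  expect_equal(nrow(p), 1L)
  # w = s = n_cols equals the global p-distance
  set.seed(4)
  a <- rand_dna(300); b <- rand_dna(300)
  aln <- seq_alignment(c(a, b))
  glob <- sliding_pi(aln, 300, 300)
  expect_equal(glob$pi, mean(o_chars(a) != o_chars(b)))
  # pi is invariant under row order
  aln3 <- seq_alignment(c(a, b, rand_dna(300)))
  p1 <- sliding_pi(aln3, 100, 50)$pi
  aln3r <- seq_alignment(rev(aln3$seqs))
  expect_equal(sliding_pi(aln3r, 100, 50)$pi, p1)
})

test_that("substitution spectrum pools the six unordered types", {
  # one mismatch of each unordered type
  aln <- seq_alignment(c("AAACCG", "CGTGTT"))
  sp <- substitution_spectrum(aln)
  expect_equal(unname(sp$counts), rep(1, 6))
  expect_equal(sp$total, 6)
  expect_equal(sp$ts, 2)
  expect_equal(sp$tv, 4)
  # identical rows -> zeros; strand behavior; conservation of mismatches
  expect_equal(substitution_spectrum(seq_alignment(c("ACGT", "ACGT")))$total, 0)
  set.seed(31)
  a <- rand_dna(800); b <- rand_dna(800)
  s1 <- substitution_spectrum(seq_alignment(c(a, b)))
  s2 <- substitution_spectrum(seq_alignment(c(o_revcomp(a), o_revcomp(b))))
  # reading both rows on the other strand maps each unordered pair to its
  # complement (A:G <-> C:T, A:C <-> G:T), leaving ts/tv/total unchanged
  expect_equal(s2$counts[["A:G"]], s1$counts[["C:T"]])
  expect_equal(s2$counts[["A:C"]], s1$counts[["G:T"]])
  expect_equal(s2$counts[["A:T"]], s1$counts[["A:T"]])
  expect_equal(s2$counts[["C:G"]], s1$counts[["C:G"]])
  expect_equal(s2$ts, s1$ts)
  expect_equal(s2$tv, s1$tv)
  expect_equal(s2$total, s1$total)
  ca <- o_chars(a); cb <- o_chars(b)
  expect_equal(s1$total, sum(ca != cb))
  expect_error(substitution_spectrum(seq_alignment(c(a, b, a))), "exactly 2")
})

test_that("hypervariable regions merge runs and name flanking genes", {
  # profile with two hot segments separated by a cold window
  mk_prof <- function(pi) {
    p <- data.frame(start = seq(1, by = 50, length.out = length(pi)),
                    midpoint = seq(1, by = 50, length.out = length(pi)) + 99.5,
                    pi = pi, usable_sites = 200)
    attr(p, "window") <- 200; attr(p, "step") <- 50
    class(p) <- c("pi_profile", "data.frame")
    p
  }
  cold <- mk_prof(rep(0.1, 10))
  expect_equal(nrow(call_hypervariable(cold, 0.7)), 0L)
  two <- mk_prof(c(0.1, 0.8, 0.9, 0.1, 0.1, 0.75, 0.1))
  hv <- call_hypervariable(two, 0.7)
  expect_equal(nrow(hv), 2L)
  expect_equal(hv$n_windows, c(2L, 1L))
  expect_equal(hv$peak_pi, c(0.9, 0.75))
  one <- mk_prof(c(0.1, 0.8, 0.9, 0.8, 0.1))
  expect_equal(nrow(call_hypervariable(one, 0.7)), 1L)

  # end-to-end: a planted high-divergence segment, named by flanking genes
  set.seed(8)
  A <- rand_dna(3000)
  d <- o_chars(A)
  hot <- 1501:1700
  for (p in hot) if (runif(1) < 0.5) d[p] <- setdiff(c("A","C","G","T"), d[p])[1]
  aln <- seq_alignment(c(A, o_collapse(d)), ids = c("ref", "mut"))
  ann <- annotated_genome(
    circular_sequence(A, id = "ref"),
    gene_features(c("atpH", "atpI"), c("CDS", "CDS"), c("+", "+"),
                  list(cbind(start = 1000, len = 200),
                       cbind(start = 2200, len = 200))))
  prof <- sliding_pi(aln, 200, 50)
  hv2 <- call_hypervariable(prof, 0.2, aln = aln, ann = ann)
  expect_equal(nrow(hv2), 1L)
  expect_equal(hv2$genes, "atpH-atpI")
  expect_true(hv2$genome_start <= 1501 && hv2$genome_end >= 1700)
})

test_that("per-gene divergence ranks planted variable genes first", {
  sim <- simulate_plastome(sim_params("test", seed = 19))
  g <- sim$genome
  # plant 5 SNPs inside rbcL exons, none elsewhere
  i <- which(g$features$name == "rbcL")
  ex <- g$features$exons[[i]]
  d <- o_chars(g$sequence$seq)
  pos <- ex[1, "start"] + c(5, 15, 25, 35, 45)   # 0-based
  for (p in pos) {
    old <- d[p + 1]
    d[p + 1] <- c(A = "G", G = "A", C = "T", T = "C")[old]
  }
  aln <- seq_alignment(c(g$sequence$seq, o_collapse(d)), ids = c("a", "b"))
  tab <- per_gene_divergence(aln, g)
  expect_equal(tab$gene[1], "rbcL")
  expect_equal(tab$differences[1], 5)
  expect_equal(tab$identity[1], 100 * (1 - 5 / 60))
  expect_true(all(tab$differences[-1] == 0))
  expect_true(all(tab$identity[-1] == 100))
  # a gene with zero differences reports identity 100
  expect_equal(unique(tab$identity[tab$differences == 0]), 100)
  # ranking ignores feature-table order
  g2 <- g; perm <- sample(nrow(g$features))
  g2$features <- g$features[perm, ]
  tab2 <- per_gene_divergence(aln, g2)
  expect_equal(tab2$gene, tab$gene)
  # genes beyond the aligned span are flagged, not dropped
  short <- seq_alignment(c(substr(g$sequence$seq, 1, 5000),
                           substr(o_collapse(d), 1, 5000)))
  tab3 <- per_gene_divergence(short, g)
  expect_true(any(tab3$flagged))
  expect_equal(nrow(tab3), length(unique(g$features$name)))
})
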