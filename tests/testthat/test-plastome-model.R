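test_that("GenBank writer and reader round-trip annotated genomes", {
  for (seed in c(2, 9, 31)) {
    sim <- simulate_plastome(sim_params("test", seed = seed))
    g <- sim$genome
    tf <- withr::local_tempfile(fileext = ".gb")
    write_genbank(g, tf)
    g2 <- read_genbank(tf)
    expect_identical(g2$sequence$seq, g$sequence$seq)
    expect_true(g2$sequence$circular)
    expect_identical(g2$features$name, g$features$name)
    expect_identical(g2$features$kind, g$features$kind)
    expect_identical(g2$features$strand, g$features$strand)
    for (i in seq_len(nrow(g$features))) {
      expect_equal(unname(g2$features$exons[[i]]),
                   unname(g$features$exons[[i]]))
    }
  }
})

test_that("GenBank handles minimal records, complement/join and wrapping", {
  # hand-written minimal record: one CDS on the complement strand
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       toy 40 bp    DNA     circular PLN 01-JAN-2020",
    "FEATURES             Location/Qualifiers",
    "     source          1..40",
    "     CDS             complement(5..16)",
    "                     /gene=\"psbA\"",
    "     CDS             join(20..25,30..35)",
    "                     /gene=\"ycf3\"",
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 4), collapse = " ")),
    "//"), tf)
  g <- read_genbank(tf)
  expect_equal(nrow(g$features), 2L)
  expect_equal(g$features$strand, c("-", "+"))
  expect_equal(nrow(g$features$exons[[1]]), 1L)
  # join CDS: 2 exons, intron = the gap between them
  ex <- g$features$exons[[2]]
  expect_equal(nrow(ex), 2L)
  intr <- plastome:::.feature_introns(ex, 40)
  expect_equal(nrow(intr), 1L)
  expect_equal(unname(intr[1, ]), c(25, 4))

  # an origin-wrapping feature survives a write/read cycle as one exon
  cs <- circular_sequence(strrep("ACGT", 25), id = "wrap")
  gw <- annotated_genome(cs, gene_features(
    "ndhF", "CDS", "+", list(cbind(start = 90, len = 30))))
  tf2 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(gw, tf2)
  gw2 <- read_genbank(tf2)
  expect_equal(unname(gw2$features$exons[[1]]), cbind(90, 30),
               ignore_attr = TRUE)

  # errors: malformed file names the problem; empty sequence rejected
  tf3 <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("DEFINITION  nothing here"), tf3)
  expect_error(read_genbank(tf3), "LOCUS")
  tf4 <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       x 0 bp DNA circular", "ORIGIN", "//"), tf4)
  expect_error(read_genbank(tf4), "zero-length")
})

test_that("FASTA I/O round-trips and rejects duplicate ids", {
  s1 <- circular_sequence(rand_dna(500), id = "a")
  s2 <- circular_sequence(rand_dna(321), id = "b")
  tf <- withr::local_tempfile(fileext = ".fa")
  write_fasta(list(s1, s2), tf)
  back <- read_fasta(tf)
  expect_identical(back[["a"]]$seq, s1$seq)
  expect_identical(back[["b"]]$seq, s2$seq)
  tf2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGT", ">x", "GGCC"), tf2)
  expect_error(read_fasta(tf2), "duplicate")
})

test_that("annotation summary reproduces the canonical gene census", {
  sim <- simulate_plastome(sim_params("test", seed = 4))
  g <- sim$genome
  s <- summarize_annotation(g, g$partition)
  expect_equal(s$n_unique_genes, 113L)
  expect_equal(s$n_protein, 79L)
  expect_equal(s$n_trna, 30L)
  expect_equal(s$n_rrna, 4L)
  expect_equal(s$n_ir_duplicated, 18L)
  expect_equal(s$n_intron_genes, 17L)
  expect_equal(s$n_single_intron, 15L)
  expect_equal(s$n_double_intron, 2L)
  # count identities hold
  expect_equal(s$n_unique_genes, s$n_protein + s$n_trna + s$n_rrna)
  expect_equal(s$n_intron_genes, s$n_single_intron + s$n_double_intron)
  expect_true(s$gc_percent >= 0 && s$gc_percent <= 100)
})

test_that("GC percent is exact and reverse-complement invariant", {
  expect_equal(gc_percent("ATGC"), 50.0)
  expect_equal(gc_percent("AAAA"), 0.0)
  # ambiguity codes drop out of the denominator
  expect_equal(gc_percent("ATGCNN"), 50.0)
  set.seed(11)
  for (i in 1:20) {
    s <- rand_dna(sample(50:400, 1), gc = runif(1, 0.2, 0.8))
    expect_equal(gc_percent(s), gc_percent(revcomp(s)))
  }
})

test_that("gene classification follows the bundled table", {
  sim <- simulate_plastome(sim_params("test", seed = 4))
  cl <- classify_genes(sim$genome)
  expect_true(all(c("psbA", "rbcL") %in% cl$photosynthesis))
  expect_true(all(c("matK", "cemA", "accD", "clpP", "ycf1", "ycf2") %in%
                    cl$other))
  expect_equal(lengths(cl)[["photosynthesis"]], 47L)
  expect_equal(lengths(cl)[["transcription_translation"]], 60L)
  expect_equal(lengths(cl)[["other"]], 6L)
  # unknown symbols fall through to unclassified
  g2 <- sim$genome
  g2$features <- rbind(g2$features,
                       gene_features("foo", "CDS", "+",
                                     list(cbind(start = 0, len = 9))))
  cl2 <- classify_genes(g2)
  expect_equal(cl2$unclassified, "foo")
})

test_that("annotation comparison reports missing genes and copy numbers", {
  sim <- simulate_plastome(sim_params("test", seed = 4))
  a <- sim$genome
  p <- a$partition
  expect_equal(nrow(compare_annotations(a, a, p, p)$copy_number_diffs), 0L)
  expect_equal(nrow(compare_annotations(a, a, p, p)$genes_only_in_a), 0L)

  # delete one IR copy of rps7 -> copy-number diff (rps7, 2, 1)
  b <- a
  idx <- which(b$features$name == "rps7")
  expect_length(idx, 2L)
  b$features <- b$features[-idx[2], ]
  d <- compare_annotations(a, b, p, p)
  expect_equal(d$copy_number_diffs,
               data.frame(name = "rps7", copies_a = 2L, copies_b = 1L),
               ignore_attr = TRUE)

  # delete k random IR-only genes entirely -> exactly those names, in IR
  set.seed(5)
  ir_only <- c("rrn16", "ycf2", "trnV-GAC")
  b2 <- a
  b2$features <- b2$features[!b2$features$name %in% ir_only, ]
  d2 <- compare_annotations(a, b2, p, p)
  expect_setequal(unique(d2$genes_only_in_a$name), ir_only)
  expect_true(all(d2$genes_only_in_a$region %in% c("IRA", "IRB")))
  expect_equal(nrow(d2$genes_only_in_b), 0L)
})

test_that("GFF3 export writes one line per exon with gene attributes", {
  sim <- simulate_plastome(sim_params("test", seed = 4))
  g <- sim$genome
  tf <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(g, tf)
  lines <- readLines(tf)
  body <- lines[!startsWith(lines, "#")]
  n_exons <- sum(vapply(g$features$exons, nrow, integer(1)))
  expect_equal(length(body), n_exons)
  expect_true(all(grepl("gene=", body)))
  f <- strsplit(body[1], "\t")[[1]]
  expect_equal(length(f), 9L)
  expect_true(as.integer(f[4]) >= 1)
})
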