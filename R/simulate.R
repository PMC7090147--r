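# Synthetic plastome generator with full ground truth: a circular
# LSC-IRa-SSC-IRb genome carrying a canonical gene complement, planted SSR
# tracts and long repeat pairs, plus mutation, SSC-flip and tree-family
# simulators. Every planted feature is recorded so downstream scanners can
# be checked against exact truth.

#' Default canonical gene table for the simulator
#'
#' 113 unique genes (79 protein-coding, 30 tRNA, 4 rRNA) laid out over the
#' quadripartite regions: 18 genes duplicated in the IRs (4 rRNA, 8 tRNA,
#' 4 ribosomal-protein genes, ndhB, ycf2), 11 SSC-resident genes (the ndh
#' cluster, ccsA, psaC, rpl32, ycf1), the rest in the LSC. 15 genes carry a
#' single intron and ycf3/clpP carry two, mirroring the canonical
#' angiosperm plastome. Gene lengths are placeholders scaled to the preset.
#'
#' @param preset `"test"` (desk-scale genes) or `"fullscale"`.
#' @return A data.frame: `name`, `kind`, `region` (LSC/SSC/IR), `strand`,
#'   `n_exons`, `exon_total`, `intron_len`.
#' @export
default_gene_table <- function(preset = c("test", "fullscale")) {
  preset <- match.arg(preset)
  lsc_cds <- c("psaA", "psaB", "psaI", "psaJ",
               "psbA", "psbB", "psbC", "psbD", "psbE", "psbF", "psbH",
               "psbI", "psbJ", "psbK", "psbL", "psbM", "psbN", "psbT",
               "psbZ",
               "petA", "petB", "petD", "petG", "petL", "petN",
               "atpA", "atpB", "atpE", "atpF", "atpH", "atpI",
               "ndhC", "ndhJ", "ndhK", "rbcL",
               "rpoA", "rpoB", "rpoC1", "rpoC2",
               "rps2", "rps3", "rps4", "rps8", "rps11", "rps14", "rps15",
               "rps16", "rps18", "rps19",
               "rpl14", "rpl16", "rpl20", "rpl22", "rpl33", "rpl36",
               "matK", "cemA", "accD", "clpP", "infA", "ycf3", "ycf4")
  lsc_trna <- c("trnC-GCA", "trnD-GUC", "trnE-UUC", "trnF-GAA", "trnfM-CAU",
                "trnG-GCC", "trnG-UCC", "trnK-UUU", "trnL-UAA", "trnL-UAG",
                "trnM-CAU", "trnP-UGG", "trnQ-UUG", "trnR-UCU", "trnS-GCU",
                "trnS-GGA", "trnS-UGA", "trnT-GGU", "trnT-UGU", "trnV-UAC",
                "trnW-CCA", "trnY-GUA")
  ir_rrna <- c("rrn16", "rrn23", "rrn4.5", "rrn5")
  ir_trna <- c("trnH-GUG", "trnI-CAU", "trnL-CAA", "trnV-GAC", "trnI-GAU",
               "trnA-UGC", "trnR-ACG", "trnN-GUU")
  ir_cds <- c("rpl2", "rpl23", "rps7", "rps12", "ndhB", "ycf2")
  ssc_cds <- c("ndhF", "rpl32", "ccsA", "ndhD", "psaC", "ndhE", "ndhG",
               "ndhI", "ndhA", "ndhH", "ycf1")
  single_intron <- c("trnK-UUU", "rps16", "trnG-UCC", "atpF", "rpoC1",
                     "trnL-UAA", "trnV-UAC", "petB", "petD", "rpl16",
                     "rpl2", "ndhB", "trnI-GAU", "trnA-UGC", "ndhA")
  double_intron <- c("ycf3", "clpP")

  tbl <- rbind(
    data.frame(name = lsc_cds, kind = "CDS", region = "LSC"),
    data.frame(name = lsc_trna, kind = "tRNA", region = "LSC"),
    data.frame(name = ir_rrna, kind = "rRNA", region = "IR"),
    data.frame(name = ir_trna, kind = "tRNA", region = "IR"),
    data.frame(name = ir_cds, kind = "CDS", region = "IR"),
    data.frame(name = ssc_cds, kind = "CDS", region = "SSC"))
  tbl$strand <- rep_len(c("+", "-"), nrow(tbl))
  tbl$n_exons <- 1L + ifelse(tbl$name %in% double_intron, 2L,
                             ifelse(tbl$name %in% single_intron, 1L, 0L))
  if (preset == "test") {
    len <- ifelse(tbl$kind == "tRNA", 40L, ifelse(tbl$kind == "rRNA", 60L, 60L))
    special <- c(rrn23 = 80, ycf1 = 240, ycf2 = 120, rpoC2 = 90, ndhF = 90)
    intron <- rep(30L, nrow(tbl))
  } else {
    len <- ifelse(tbl$kind == "tRNA", 75L, 900L)
    special <- c(rrn16 = 1490, rrn23 = 2810, `rrn4.5` = 100, rrn5 = 120,
                 ycf1 = 5600, ycf2 = 6900, rpoC2 = 4100, ndhF = 2200,
                 ndhB = 1530, rpl2 = 820, rps7 = 470, rps12 = 370,
                 rpl23 = 280, matK = 1500, accD = 1500, clpP = 590,
                 ycf3 = 500, rbcL = 1430, psbA = 1060, atpB = 1500,
                 rpoB = 3200, rpoC1 = 2000, rpl32 = 400, ccsA = 960,
                 ndhD = 1500, psaC = 250, ndhE = 300, ndhG = 530,
                 ndhI = 500, ndhA = 1100, ndhH = 1180)
    # trnK-UUU carries the longest intron (2599 bp); the remaining introns
    # are sized so the mean intron length across the 19 introns is 907 bp
    intron <- ifelse(tbl$name == "trnK-UUU", 2599L, 813L)
  }
  hit <- match(tbl$name, names(special))
  len[!is.na(hit)] <- special[hit[!is.na(hit)]]
  tbl$exon_total <- as.integer(len)
  tbl$intron_len <- as.integer(intron)
  tbl
}

#' MISA-style per-class SSR tract thresholds
#'
#' Minimum tract lengths (mono..hexa) under which planted SSR tracts stand
#' clear of the i.i.d. background at full genome scale: 10/12/15/16/20/18
#' bases (i.e. at least 10, 6, 5, 4, 4 and 3 motif copies). Use as the
#' `min_tract` argument of [find_ssrs()]; the flat default of 10 bases for
#' every class remains available for the loosest reading of a "10 nt"
#' threshold.
#'
#' @return Integer vector of length 6.
#' @export
ssr_class_thresholds <- function() c(10L, 12L, 15L, 16L, 20L, 18L)

.default_ssr_plants <- function(preset) {
  if (preset == "test") {
    return(data.frame(
      motif = c("A", "AT", "AAG", "AATC", "AACAT", "AACGAT"),
      copies = c(12L, 6L, 5L, 4L, 4L, 3L),
      region = c("LSC", "LSC", "LSC", "SSC", "SSC", "LSC"),
      stringsAsFactors = FALSE))
  }
  # class counts 28/11/13/15/10/9 (mono..hexa), total 86; copies chosen so
  # every tract clears the ssr_class_thresholds() line
  mk <- function(motifs, copies, n) {
    data.frame(motif = rep_len(motifs, n), copies = rep_len(copies, n),
               stringsAsFactors = FALSE)
  }
  plants <- rbind(
    mk(c("A", "T", "A", "C"), c(10L, 11L, 12L, 13L, 14L), 28L),
    mk(c("AT", "AG", "AC", "TC"), c(6L, 7L), 11L),
    mk(c("AAT", "AAG", "ATC", "AGG"), 5L, 13L),
    mk(c("AAAT", "AATG", "ATCC", "AGAT"), 4L, 15L),
    mk(c("AATAG", "AATCC", "ATGGA"), 4L, 10L),
    mk(c("AATAGG", "ATCGGA", "AATTCC"), 3L, 9L))
  plants$region <- rep_len(c("LSC", "LSC", "LSC", "SSC"), nrow(plants))
  plants
}

.default_repeat_plants <- function(preset) {
  if (preset == "test") {
    return(data.frame(kind = c("direct", "inverted"),
                      length = c(60L, 45L),
                      region1 = c("LSC", "LSC"), region2 = c("SSC", "SSC"),
                      stringsAsFactors = FALSE))
  }
  # 30 direct + 19 inverted, exactly five pairs exceeding 50 bp
  dir_len <- c(78L, 65L, 55L, rep_len(seq(30L, 50L, by = 4L), 27L))
  inv_len <- c(58L, 52L, rep_len(seq(31L, 49L, by = 3L), 17L))
  out <- rbind(
    data.frame(kind = "direct", length = dir_len, stringsAsFactors = FALSE),
    data.frame(kind = "inverted", length = inv_len, stringsAsFactors = FALSE))
  out$region1 <- "LSC"
  out$region2 <- rep_len(c("LSC", "LSC", "SSC"), nrow(out))
  out
}

#' Simulation parameters
#'
#' The `"test"` preset (LSC 9,000 / SSC 2,000 / IR 1,500 bp) keeps every
#' brute-force oracle fast; `"fullscale"` uses the dimensions of a real
#' Malvaceae plastome (LSC 90,351 / SSC 19,486 / IR 26,533 bp) with the
#' matching planted-feature census (86 SSRs in classes 28/11/13/15/10/9;
#' 30 direct + 19 inverted repeat pairs, five exceeding 50 bp). Background
#' composition is i.i.d. with GC 36.65% by default.
#'
#' @param preset `"test"` or `"fullscale"`.
#' @param lsc_len,ssc_len,ir_len Region lengths in bases (override preset).
#' @param gc Background GC proportion.
#' @param gene_table See [default_gene_table()].
#' @param ssr_plants Data.frame `motif`, `copies`, `region` (LSC/SSC).
#' @param repeat_plants Data.frame `kind`, `length`, `region1`, `region2`.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(preset = c("test", "fullscale"), lsc_len = NULL,
                       ssc_len = NULL, ir_len = NULL, gc = 0.3665,
                       gene_table = NULL, ssr_plants = NULL,
                       repeat_plants = NULL, seed = 1) {
  preset <- match.arg(preset)
  dims <- if (preset == "test") c(9000L, 2000L, 1500L) else
    c(90351L, 19486L, 26533L)
  p <- list(
    preset = preset,
    lsc_len = as.integer(lsc_len %||% dims[1]),
    ssc_len = as.integer(ssc_len %||% dims[2]),
    ir_len = as.integer(ir_len %||% dims[3]),
    gc = gc,
    gene_table = gene_table %||% default_gene_table(preset),
    ssr_plants = ssr_plants %||% .default_ssr_plants(preset),
    repeat_plants = repeat_plants %||% .default_repeat_plants(preset),
    seed = as.integer(seed))
  if (any(c(p$lsc_len, p$ssc_len, p$ir_len) <= 0)) {
    stop("region lengths must be positive", call. = FALSE)
  }
  if (p$lsc_len <= p$ssc_len) {
    stop("lsc_len must exceed ssc_len", call. = FALSE)
  }
  class(p) <- "sim_params"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an annotated plastome with ground truth
#'
#' Builds LSC + IRa + SSC + IRb with IRb the exact reverse complement of
#' IRa, genes (with introns) laid out per the gene table, SSR tracts and
#' repeat-pair arms planted in intergenic spacers with guard bases that make
#' every plant exactly maximal, and i.i.d. background at the requested GC.
#' Identical seeds give byte-identical genomes.
#'
#' @param params A [sim_params()] object.
#' @return A list: `genome` (an [annotated_genome()] with the true partition
#'   attached as `$partition`) and `truth` (class `plastome_truth`:
#'   partition, planted SSR loci, planted repeat pairs, gene features,
#'   `ssc_flipped`, seed, params).
#' @export
simulate_plastome <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$seed, .simulate_impl(params))
}

.simulate_impl <- function(p) {
  gt <- p$gene_table
  gt$span <- gt$exon_total + (gt$n_exons - 1L) * gt$intron_len

  # element length bookkeeping per region (parameter error before generation)
  ssr_el_len <- nchar(p$ssr_plants$motif) * p$ssr_plants$copies + 2L
  rep_el_len <- p$repeat_plants$length + 2L
  for (reg in c("LSC", "SSC", "IR")) {
    rl <- switch(reg, LSC = p$lsc_len, SSC = p$ssc_len, IR = p$ir_len)
    fixed <- sum(gt$span[gt$region == reg]) +
      sum(ssr_el_len[p$ssr_plants$region == reg]) +
      sum(rep_el_len[p$repeat_plants$region1 == reg]) +
      sum(rep_el_len[p$repeat_plants$region2 == reg])
    n_el <- sum(gt$region == reg) + sum(p$ssr_plants$region == reg) +
      sum(p$repeat_plants$region1 == reg) +
      sum(p$repeat_plants$region2 == reg)
    if (rl - fixed < 2L * (n_el + 1L)) {
      stop(sprintf("planted genes/features do not fit in %s (%d bp needed, %d available)",
                   reg, fixed + 2L * (n_el + 1L), rl), call. = FALSE)
    }
  }

  # pre-generate repeat cores (each used twice)
  rep_cores <- lapply(p$repeat_plants$length, random_dna, gc = p$gc)

  # build element lists per region
  elements <- list(LSC = list(), SSC = list(), IR = list())
  for (reg in c("LSC", "SSC", "IR")) {
    gi <- which(gt$region == reg)
    els <- lapply(gi, function(i) list(type = "gene", idx = i))
    plant_els <- list()
    for (si in which(p$ssr_plants$region == reg)) {
      plant_els[[length(plant_els) + 1L]] <- list(type = "ssr", idx = si)
    }
    for (ri in seq_len(nrow(p$repeat_plants))) {
      if (p$repeat_plants$region1[ri] == reg) {
        plant_els[[length(plant_els) + 1L]] <- list(type = "rep", idx = ri,
                                                    arm = 1L)
      }
      if (p$repeat_plants$region2[ri] == reg) {
        plant_els[[length(plant_els) + 1L]] <- list(type = "rep", idx = ri,
                                                    arm = 2L)
      }
    }
    # interleave plants among genes at evenly spaced slots
    if (length(plant_els)) {
      npl <- length(plant_els)
      slots <- round(seq_along(plant_els) * length(els) / (npl + 1L))
      merged <- list()
      pl_i <- 1L
      for (gpos in seq_along(els)) {
        merged[[length(merged) + 1L]] <- els[[gpos]]
        while (pl_i <= npl && slots[pl_i] == gpos) {
          merged[[length(merged) + 1L]] <- plant_els[[pl_i]]
          pl_i <- pl_i + 1L
        }
      }
      while (pl_i <= npl) {
        merged[[length(merged) + 1L]] <- plant_els[[pl_i]]
        pl_i <- pl_i + 1L
      }
      els <- merged
    }
    elements[[reg]] <- els
  }

  # realize each region: sequence + feature/truth records at region offsets
  realize <- function(reg, region_len) {
    els <- elements[[reg]]
    # element strings
    strs <- character(length(els))
    gene_rel <- list()   # per gene element: exon matrix relative to element
    for (t in seq_along(els)) {
      el <- els[[t]]
      if (el$type == "gene") {
        i <- el$idx
        ne <- gt$n_exons[i]
        exl <- rep(gt$exon_total[i] %/% ne, ne)
        exl[ne] <- exl[ne] + gt$exon_total[i] %% ne
        rel <- matrix(0, ne, 2, dimnames = list(NULL, c("start", "len")))
        off <- 0L
        pieces <- character()
        for (e in seq_len(ne)) {
          rel[e, ] <- c(off, exl[e])
          pieces <- c(pieces, random_dna(exl[e], p$gc))
          off <- off + exl[e]
          if (e < ne) {
            pieces <- c(pieces, random_dna(gt$intron_len[i], p$gc))
            off <- off + gt$intron_len[i]
          }
        }
        strs[t] <- .collapse(pieces)
        gene_rel[[t]] <- rel
      } else if (el$type == "ssr") {
        mo <- p$ssr_plants$motif[el$idx]
        cp <- p$ssr_plants$copies[el$idx]
        m <- nchar(mo)
        gl <- setdiff(c("C", "G", "A", "T"), substr(mo, m, m))[1]
        gr <- setdiff(c("G", "C", "T", "A"), substr(mo, 1, 1))[1]
        strs[t] <- paste0(gl, strrep(mo, cp), gr)
      } else {
        core <- rep_cores[[el$idx]]
        kind <- p$repeat_plants$kind[el$idx]
        if (el$arm == 2L) {
          strs[t] <- if (kind == "inverted") paste0("A", revcomp(core), "A")
            else paste0("C", core, "C")
        } else {
          strs[t] <- paste0("A", core, "A")
        }
      }
    }
    fixed <- sum(nchar(strs))
    n_sp <- length(els) + 1L
    budget <- region_len - fixed
    base_sp <- budget %/% n_sp
    sp_len <- rep(base_sp, n_sp)
    sp_len[n_sp] <- sp_len[n_sp] + budget %% n_sp
    pieces <- character(); pos <- 0L
    feat <- list(); ssr_tr <- list(); rep_tr <- list()
    for (t in seq_along(els)) {
      sp <- random_dna(sp_len[t], p$gc)
      pieces <- c(pieces, sp); pos <- pos + sp_len[t]
      el <- els[[t]]
      if (el$type == "gene") {
        rel <- gene_rel[[t]]
        rel[, "start"] <- rel[, "start"] + pos
        feat[[length(feat) + 1L]] <- list(idx = el$idx, exons = rel)
      } else if (el$type == "ssr") {
        mo <- p$ssr_plants$motif[el$idx]
        ssr_tr[[length(ssr_tr) + 1L]] <- data.frame(
          motif = .canonical_motif(mo), motif_len = nchar(mo),
          copies = p$ssr_plants$copies[el$idx],
          start = pos + 1L,
          tract_len = nchar(mo) * p$ssr_plants$copies[el$idx],
          region = reg, stringsAsFactors = FALSE)
      } else {
        rep_tr[[length(rep_tr) + 1L]] <- data.frame(
          idx = el$idx, arm = el$arm, start = pos + 1L,
          length = p$repeat_plants$length[el$idx], stringsAsFactors = FALSE)
      }
      pieces <- c(pieces, strs[t]); pos <- pos + nchar(strs[t])
    }
    pieces <- c(pieces, random_dna(sp_len[n_sp], p$gc))
    list(seq = .collapse(pieces), feat = feat,
         ssr = if (length(ssr_tr)) do.call(rbind, ssr_tr) else NULL,
         rep = if (length(rep_tr)) do.call(rbind, rep_tr) else NULL)
  }

  lsc <- realize("LSC", p$lsc_len)
  ira <- realize("IR", p$ir_len)
  ssc <- realize("SSC", p$ssc_len)
  irb_seq <- revcomp(ira$seq)
  L <- p$lsc_len + 2L * p$ir_len + p$ssc_len
  off <- c(LSC = 0L, IRA = p$lsc_len, SSC = p$lsc_len + p$ir_len,
           IRB = p$lsc_len + p$ir_len + p$ssc_len)
  genome_seq <- paste0(lsc$seq, ira$seq, ssc$seq, irb_seq)

  # junction guards: keep the IR pair exactly maximal at both junctions
  d <- .chars(genome_seq)
  comp1 <- function(b) chartr("ACGT", "TGCA", b)
  # outward junction: last LSC base vs complement of first LSC base
  if (d[off[["IRA"]]] == comp1(d[1])) {
    d[off[["IRA"]]] <- setdiff(c("A", "C", "G", "T"),
                               c(comp1(d[1]), d[off[["IRA"]]]))[1]
  }
  # inward junction: first SSC base vs complement of last SSC base
  if (d[off[["SSC"]] + 1L] == comp1(d[off[["IRB"]]])) {
    d[off[["IRB"]]] <- setdiff(c("A", "C", "G", "T"),
                               c(comp1(d[off[["SSC"]] + 1L]), d[off[["IRB"]]]))[1]
  }
  genome_seq <- .collapse(d)

  # assemble features with absolute coordinates; IRb mirrors IRa
  nm <- character(); kd <- character(); sd <- character(); ex <- list()
  add_feats <- function(fl, offset) {
    for (f in fl) {
      i <- f$idx
      e <- f$exons
      e[, "start"] <- e[, "start"] + offset
      nm <<- c(nm, gt$name[i]); kd <<- c(kd, gt$kind[i])
      sd <<- c(sd, gt$strand[i]); ex <<- c(ex, list(e))
    }
  }
  add_feats(lsc$feat, off[["LSC"]])
  add_feats(ira$feat, off[["IRA"]])
  add_feats(ssc$feat, off[["SSC"]])
  for (f in ira$feat) {  # mirrored copy in IRb
    i <- f$idx
    e <- f$exons
    e[, "start"] <- off[["IRB"]] + p$ir_len - (e[, "start"] + e[, "len"])
    e <- e[order(e[, "start"]), , drop = FALSE]
    nm <- c(nm, gt$name[i]); kd <- c(kd, gt$kind[i])
    sd <- c(sd, ifelse(gt$strand[i] == "+", "-", "+")); ex <- c(ex, list(e))
  }
  features <- gene_features(nm, kd, sd, ex)

  ssr_truth <- do.call(rbind, Filter(Negate(is.null),
                                     list(lsc$ssr, ssc$ssr)))
  if (!is.null(ssr_truth)) {
    # realize() records 0-based tract starts relative to the region
    ssr_truth$start <- ssr_truth$start +
      ifelse(ssr_truth$region == "LSC", off[["LSC"]], off[["SSC"]])
  } else {
    ssr_truth <- data.frame(motif = character(), motif_len = integer(),
                            copies = integer(), start = integer(),
                            tract_len = integer(), region = character())
  }

  arm_rows <- do.call(rbind, Filter(Negate(is.null), list(
    if (!is.null(lsc$rep)) cbind(lsc$rep, region = "LSC"),
    if (!is.null(ssc$rep)) cbind(ssc$rep, region = "SSC"),
    if (!is.null(ira$rep)) cbind(ira$rep, region = "IR"))))
  rep_truth <- data.frame(kind = character(), start1 = integer(),
                          start2 = integer(), length = integer())
  if (!is.null(arm_rows)) {
    arm_rows$abs <- arm_rows$start +
      ifelse(arm_rows$region == "LSC", off[["LSC"]],
             ifelse(arm_rows$region == "SSC", off[["SSC"]], off[["IRA"]]))
    rep_truth <- do.call(rbind, lapply(seq_len(nrow(p$repeat_plants)),
                                       function(ri) {
      a <- arm_rows[arm_rows$idx == ri, ]
      if (nrow(a) != 2L) return(NULL)
      s <- sort(a$abs)
      data.frame(kind = p$repeat_plants$kind[ri], start1 = s[1], start2 = s[2],
                 length = p$repeat_plants$length[ri], stringsAsFactors = FALSE)
    }))
  }

  partition <- structure(list(
    lsc = c(start = 0, len = p$lsc_len),
    ira = c(start = off[["IRA"]], len = p$ir_len),
    ssc = c(start = off[["SSC"]], len = p$ssc_len),
    irb = c(start = off[["IRB"]], len = p$ir_len),
    L = L), class = "quadripartite_partition")

  genome <- annotated_genome(
    circular_sequence(genome_seq, id = sprintf("sim_%s_%d", p$preset, p$seed)),
    features, source = "synthetic")
  genome$partition <- partition

  truth <- structure(list(partition = partition, ssr = ssr_truth,
                          repeats = rep_truth, genes = features,
                          ssc_flipped = FALSE, seed = p$seed, params = p),
                     class = "plastome_truth")
  list(genome = genome, truth = truth)
}

.TS_MAP <- c(A = "G", G = "A", C = "T", T = "C")
.TV_MAP <- list(A = c("C", "T"), G = c("C", "T"),
                C = c("A", "G"), T = c("A", "G"))

#' Mutate a genome with substitutions and indels
#'
#' Substitutions are drawn independently per site at `sub_rate`; given a
#' substitution, a transition occurs with probability `tstv/(tstv+1)`, so
#' the realized six-type spectrum has expected transition fraction
#' `tstv/(tstv+1)`. When the genome carries a quadripartite partition and
#' `sync_ir = TRUE` (the default), substitutions drawn in IRa are mirrored
#' (complemented) into IRb instead of being drawn independently, emulating
#' the concerted evolution that keeps real plastome IRs near-identical;
#' per-site rates are unchanged. Indels are geometric-length events placed
#' only outside annotated features, the IRs (under `sync_ir`) and any
#' `protect` intervals, so feature coordinates remap cleanly. All events
#' are recorded.
#'
#' @param g An [annotated_genome()].
#' @param sub_rate Per-site substitution probability in `[0, 0.5]`.
#' @param tstv Transition:transversion ratio (default 2).
#' @param indel_rate Per-site indel event probability in `[0, 0.5]`.
#' @param seed Integer seed.
#' @param protect Optional list of intervals `c(start, len)` shielded from
#'   indels (planted repeats/SSRs, typically from the truth record).
#' @param sync_ir Keep the two IR copies identical under mutation (requires
#'   `g$partition`; silently off without one).
#' @return A list: `genome` and `truth` (substitution and indel tables).
#' @export
mutate_genome <- function(g, sub_rate, tstv = 2, indel_rate = 0, seed = 1,
                          protect = NULL, sync_ir = TRUE) {
  stopifnot(inherits(g, "annotated_genome"),
            sub_rate >= 0, sub_rate <= 0.5,
            indel_rate >= 0, indel_rate <= 0.5)
  part <- if (sync_ir) g$partition else NULL
  withr::with_seed(seed, {
    d <- .chars(g$sequence$seq)
    L <- length(d)
    editable <- d %in% c("A", "C", "G", "T")
    idx <- which(stats::runif(L) < sub_rate & editable)
    if (!is.null(part)) {
      # draw on LSC + IRa + SSC only; IRb mirrors IRa (concerted evolution)
      ib <- part$irb
      in_irb <- ((idx - 1L - ib[["start"]]) %% L) < ib[["len"]]
      idx <- idx[!in_irb]
    }
    subs <- data.frame(pos = integer(), from = character(), to = character(),
                       transition = logical())
    if (length(idx)) {
      from <- d[idx]
      is_ts <- stats::runif(length(idx)) < tstv / (tstv + 1)
      to <- character(length(idx))
      to[is_ts] <- .TS_MAP[from[is_ts]]
      pick2 <- stats::runif(sum(!is_ts)) < 0.5
      tv_from <- from[!is_ts]
      to[!is_ts] <- vapply(seq_along(tv_from), function(t) {
        .TV_MAP[[tv_from[t]]][if (pick2[t]) 1L else 2L]
      }, character(1))
      d[idx] <- to
      subs <- data.frame(pos = idx - 1L, from = from, to = to,
                         transition = is_ts, stringsAsFactors = FALSE)
      if (!is.null(part)) {   # mirror IRa substitutions into IRb
        ia <- part$ira; ib <- part$irb
        off <- (idx - 1L - ia[["start"]]) %% L
        in_ira <- off < ia[["len"]]
        if (any(in_ira)) {
          mpos0 <- (ib[["start"]] + ib[["len"]] - 1L - off[in_ira]) %% L
          cmp <- function(b) chartr("ACGT", "TGCA", b)
          d[mpos0 + 1L] <- cmp(to[in_ira])
          subs <- rbind(subs, data.frame(
            pos = mpos0, from = cmp(from[in_ira]), to = cmp(to[in_ira]),
            transition = is_ts[in_ira], stringsAsFactors = FALSE))
          subs <- subs[order(subs$pos), ]
          rownames(subs) <- NULL
        }
      }
    }
    indels <- data.frame(pos = integer(), type = character(), len = integer())
    if (indel_rate > 0) {
      shield <- c(lapply(g$features$exons, function(e) {
        .feature_span(e, L)
      }), protect %||% list())
      if (!is.null(part)) shield <- c(shield, list(part$ira, part$irb))
      cand <- which(stats::runif(L) < indel_rate)
      lens <- stats::rgeom(length(cand), 0.5) + 1L
      is_del <- stats::runif(length(cand)) < 0.5
      keep <- vapply(seq_along(cand), function(t) {
        span <- c(start = cand[t] - 1L, len = lens[t])
        !any(vapply(shield, function(iv) .intervals_overlap(iv, span, L),
                    logical(1)))
      }, logical(1))
      cand <- cand[keep]; lens <- lens[keep]; is_del <- is_del[keep]
      ord <- order(cand, decreasing = TRUE)
      for (t in ord) {
        p0 <- cand[t]  # 1-based
        if (is_del[t]) {
          if (p0 + lens[t] - 1L > length(d)) next
          d <- d[-(p0:(p0 + lens[t] - 1L))]
          g$features$exons <- lapply(g$features$exons, function(e) {
            e[, "start"] <- e[, "start"] - ifelse(e[, "start"] >= p0, lens[t], 0)
            e
          })
        } else {
          ins <- .chars(random_dna(lens[t], 0.5))
          d <- append(d, ins, after = p0 - 1L)
          g$features$exons <- lapply(g$features$exons, function(e) {
            e[, "start"] <- e[, "start"] + ifelse(e[, "start"] >= p0 - 1L,
                                                  lens[t], 0)
            e
          })
        }
      }
      indels <- data.frame(pos = cand - 1L,
                           type = ifelse(is_del, "del", "ins"),
                           len = lens, stringsAsFactors = FALSE)
      g$partition <- NULL  # coordinates shifted; structure must be re-detected
    }
    g$sequence$seq <- .collapse(d)
    list(genome = g,
         truth = list(substitutions = subs, indels = indels,
                      sub_rate = sub_rate, tstv = tstv, seed = seed))
  })
}

#' Flip the SSC segment of a genome
#'
#' Replaces the SSC with its reverse complement (the other orientation
#' isomer produced in vivo by recombination between the IRs); SSC-resident
#' features are strand-flipped and coordinate-mirrored. Applying the flip
#' twice restores the original genome exactly.
#'
#' @param g An [annotated_genome()].
#' @param partition Optional [quadripartite_partition]; taken from
#'   `g$partition` or detected when missing.
#' @return A list: `genome` and `truth` (`ssc_flipped = TRUE`, the interval).
#' @export
flip_ssc <- function(g, partition = NULL) {
  stopifnot(inherits(g, "annotated_genome"))
  p <- partition %||% g$partition
  if (is.null(p)) {
    ir <- find_inverted_repeat_pair(g$sequence,
                                    min_len = max(100, seq_length(g) %/% 20))
    if (!ir$found) stop("cannot resolve quadripartite structure for flip",
                        call. = FALSE)
    p <- partition_genome(g$sequence, ir)
  }
  L <- seq_length(g)
  s0 <- p$ssc[["start"]]; sl <- p$ssc[["len"]]
  if (s0 + sl > L) stop("SSC wraps the origin; canonicalize first",
                        call. = FALSE)
  S <- g$sequence$seq
  g$sequence$seq <- paste0(substr0(S, 0, s0),
                           revcomp(substr0(S, s0, sl)),
                           substr0(S, s0 + sl, L - s0 - sl))
  if (nrow(g$features)) {
    inside <- vapply(seq_len(nrow(g$features)), function(i) {
      .interval_contains(p$ssc, .feature_span(g$features$exons[[i]], L), L)
    }, logical(1))
    for (i in which(inside)) {
      e <- g$features$exons[[i]]
      e[, "start"] <- 2 * s0 + sl - (e[, "start"] + e[, "len"])
      g$features$exons[[i]] <- e[order(e[, "start"]), , drop = FALSE]
      g$features$strand[i] <- ifelse(g$features$strand[i] == "+", "-", "+")
    }
  }
  g$partition <- p
  list(genome = g, truth = list(ssc_flipped = TRUE, interval = p$ssc))
}

#' Simulate a family of plastomes along a phylogeny
#'
#' A root genome is simulated and evolved along each branch with
#' [mutate_genome()] at a per-site substitution rate equal to the branch
#' length (substitutions/site). Optionally, the SSC of chosen leaves is
#' flipped to the other orientation isomer.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param root_params [sim_params()] for the root genome.
#' @param seed Integer master seed (per-edge seeds are derived from it).
#' @param tstv Transition:transversion ratio along every branch.
#' @param flips Character vector of tip labels whose SSC is flipped.
#' @return A list: `genomes` (named by tip label) and `truth` (tree, flips,
#'   per-edge substitution counts, root truth record).
#' @export
simulate_family <- function(tree, root_params = sim_params(), seed = 1,
                            tstv = 2, flips = character()) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  root_params$seed <- .subseed(seed, 0L)
  root <- simulate_plastome(root_params)
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "cladewise")
  node_genomes <- vector("list", ntip + tr$Nnode)
  root_node <- ntip + 1L
  node_genomes[[root_node]] <- root$genome
  edge_subs <- integer(nrow(tr$edge))
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; chd <- tr$edge[e, 2]
    mut <- mutate_genome(node_genomes[[par]], sub_rate = tr$edge.length[e],
                         tstv = tstv, seed = .subseed(seed, e))
    node_genomes[[chd]] <- mut$genome
    edge_subs[e] <- nrow(mut$truth$substitutions)
  }
  genomes <- stats::setNames(node_genomes[seq_len(ntip)], tr$tip.label)
  for (lab in intersect(flips, tr$tip.label)) {
    genomes[[lab]] <- flip_ssc(genomes[[lab]])$genome
  }
  for (lab in names(genomes)) genomes[[lab]]$sequence$id <- lab
  list(genomes = genomes,
       truth = list(tree = tree, flips = flips, edge_substitutions = edge_subs,
                    root_truth = root$truth))
}
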