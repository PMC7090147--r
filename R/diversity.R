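# Divergence statistics on alignments: sliding-window nucleotide diversity,
# the six-type substitution spectrum, hypervariable-region calling, and
# per-gene conservation ranking.

.ACGT <- c("A", "C", "G", "T")

# per-pair usable/difference indicator vectors over alignment columns
.pair_indicators <- function(M) {
  r <- nrow(M)
  pairs <- utils::combn(r, 2)
  ok <- M %in% .ACGT; dim(ok) <- dim(M)
  lapply(seq_len(ncol(pairs)), function(t) {
    i <- pairs[1, t]; j <- pairs[2, t]
    usable <- ok[i, ] & ok[j, ]
    list(i = i, j = j, usable = usable, diff = usable & (M[i, ] != M[j, ]))
  })
}

#' Sliding-window nucleotide diversity
#'
#' For each window of `window` alignment columns advanced by `step`, the
#' nucleotide diversity is the average over row pairs of (mismatching usable
#' columns)/(usable columns), where usable columns carry unambiguous,
#' ungapped bases in both rows (complete exclusion per window). Windows with
#' no usable site get `NA`. For two sequences this reduces to the per-window
#' p-distance.
#'
#' @param aln A [seq_alignment()] (2 or more rows).
#' @param window Window length in alignment columns (default 800).
#' @param step Step size in columns (default 50).
#' @return A data.frame of class `pi_profile` with `start` (1-based first
#'   column), `midpoint`, `pi`, `usable_sites` (averaged over pairs), and
#'   attributes `window`/`step`. If `window > n_cols` a single truncated
#'   window is returned with a warning.
#' @export
sliding_pi <- function(aln, window = 800, step = 50) {
  stopifnot(inherits(aln, "seq_alignment"))
  M <- as.matrix(aln)
  n <- ncol(M)
  if (window > n) {
    warning("window (", window, ") exceeds alignment length (", n,
            "); returning a single truncated window")
    window <- n
    starts <- 1L
  } else {
    starts <- seq(1L, n - window + 1L, by = step)
  }
  ind <- .pair_indicators(M)
  cu <- lapply(ind, function(p) c(0, cumsum(p$usable)))
  cd <- lapply(ind, function(p) c(0, cumsum(p$diff)))
  pi_v <- numeric(length(starts)); us_v <- numeric(length(starts))
  for (w in seq_along(starts)) {
    s0 <- starts[w]; e0 <- s0 + window - 1L
    u <- vapply(cu, function(x) x[e0 + 1L] - x[s0], numeric(1))
    d <- vapply(cd, function(x) x[e0 + 1L] - x[s0], numeric(1))
    has <- u > 0
    pi_v[w] <- if (any(has)) mean(d[has] / u[has]) else NA_real_
    us_v[w] <- mean(u)
  }
  out <- data.frame(start = starts, midpoint = starts + (window - 1) / 2,
                    pi = pi_v, usable_sites = us_v)
  attr(out, "window") <- window
  attr(out, "step") <- step
  class(out) <- c("pi_profile", "data.frame")
  out
}

#' Six-type substitution spectrum of a pairwise alignment
#'
#' Counts mismatching usable columns pooled into the six non-strand-specific
#' unordered base-pair types (A:C, A:G, A:T, C:G, C:T, G:T); complementary
#' substitution directions collapse together (G->A is counted with C->T in
#' the A:G transition class). Transitions are A:G + C:T.
#'
#' @param aln A [seq_alignment()] with exactly 2 rows.
#' @return Object of class `substitution_spectrum`: `counts` (named, the six
#'   types), `total`, `ts`, `tv`.
#' @export
substitution_spectrum <- function(aln) {
  stopifnot(inherits(aln, "seq_alignment"))
  if (length(aln$seqs) != 2L) {
    stop("substitution spectrum is defined for exactly 2 sequences",
         call. = FALSE)
  }
  M <- as.matrix(aln)
  x <- M[1, ]; y <- M[2, ]
  usable <- x %in% .ACGT & y %in% .ACGT
  mm <- usable & x != y
  types <- c("A:C", "A:G", "A:T", "C:G", "C:T", "G:T")
  key <- paste(pmin(x[mm], y[mm]), pmax(x[mm], y[mm]), sep = ":")
  counts <- stats::setNames(as.numeric(table(factor(key, levels = types))),
                            types)
  total <- sum(counts)
  ts <- counts[["A:G"]] + counts[["C:T"]]
  structure(list(counts = counts, total = total, ts = ts, tv = total - ts),
            class = "substitution_spectrum")
}

#' @export
print.substitution_spectrum <- function(x, ...) {
  cat(sprintf("Substitution spectrum: %d sites (ts %d, tv %d)\n",
              x$total, x$ts, x$tv))
  print(x$counts)
  invisible(x)
}

# map alignment columns to 1-based positions on the first row's genome
.col_to_genome <- function(row1_chars) cumsum(row1_chars != "-")

#' Call hypervariable regions from a diversity profile
#'
#' Maximal runs of consecutive windows with `pi >= threshold` are merged
#' into regions. When the alignment and an annotated genome (the first
#' alignment row's genome) are supplied, regions are located on the genome
#' and named by overlapping genes, or by the flanking gene pair when they
#' fall between genes.
#'
#' @param p A [sliding_pi()] profile.
#' @param threshold Diversity threshold (default 0.7).
#' @param aln Optional [seq_alignment()] the profile came from (for genome
#'   coordinates).
#' @param ann Optional [annotated_genome()] of the first alignment row (for
#'   gene naming).
#' @return A data.frame of class `hypervariable_regions`: `start`, `end`
#'   (1-based alignment columns), `genome_start`, `genome_end`, `n_windows`,
#'   `peak_pi`, `genes`.
#' @export
call_hypervariable <- function(p, threshold = 0.7, aln = NULL, ann = NULL) {
  stopifnot(inherits(p, "pi_profile"), nrow(p) >= 1)
  w <- attr(p, "window")
  hot <- !is.na(p$pi) & p$pi >= threshold
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  out <- data.frame(start = numeric(), end = numeric(),
                    genome_start = numeric(), genome_end = numeric(),
                    n_windows = integer(), peak_pi = numeric(),
                    genes = character(), stringsAsFactors = FALSE)
  sel <- which(r$values)
  if (!length(sel)) { class(out) <- c("hypervariable_regions", "data.frame"); return(out) }
  g_map <- NULL
  if (!is.null(aln)) g_map <- .col_to_genome(.chars(aln$seqs[1]))
  rows <- lapply(sel, function(si) {
    i0 <- ends[si] - r$lengths[si] + 1L; i1 <- ends[si]
    s_aln <- p$start[i0]; e_aln <- p$start[i1] + w - 1L
    gs <- ge <- NA_real_
    if (!is.null(g_map)) { gs <- max(g_map[s_aln], 1); ge <- g_map[e_aln] }
    genes <- NA_character_
    if (!is.null(ann) && !is.na(gs)) {
      genes <- .name_region_by_genes(ann, gs - 1, ge - gs + 1)
    }
    data.frame(start = s_aln, end = e_aln, genome_start = gs, genome_end = ge,
               n_windows = i1 - i0 + 1L, peak_pi = max(p$pi[i0:i1]),
               genes = genes, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("hypervariable_regions", "data.frame")
  out
}

# label a genome interval by overlapping genes, else by flanking gene pair
.name_region_by_genes <- function(ann, start0, len) {
  f <- ann$features
  if (!nrow(f)) return(NA_character_)
  L <- seq_length(ann)
  spans <- t(vapply(f$exons, .feature_span, numeric(2), L = L))
  iv <- c(start = start0 %% L, len = len)
  ov <- vapply(seq_len(nrow(f)), function(i) {
    .intervals_overlap(iv, c(start = unname(spans[i, 1]),
                             len = unname(spans[i, 2])), L)
  }, logical(1))
  if (any(ov)) return(paste(unique(f$name[ov]), collapse = ","))
  # flanking: nearest gene end before the region and nearest start after
  gaps_before <- (start0 - (spans[, 1] + spans[, 2])) %% L
  gaps_after <- (spans[, 1] - (start0 + len)) %% L
  paste0(f$name[which.min(gaps_before)], "-", f$name[which.min(gaps_after)])
}

#' Per-gene divergence across an alignment
#'
#' Maps each annotated gene of the first alignment row's genome to alignment
#' columns (exons only) and reports usable sites, differences (averaged over
#' row pairs for multi-row alignments) and percent identity. Genes outside
#' the aligned span are flagged, not dropped. The table is ranked most
#' variable first (ascending identity), ties broken alphabetically.
#'
#' @param aln A [seq_alignment()]; row 1 is the coordinate frame.
#' @param ann [annotated_genome()] for the first row.
#' @return A data.frame of class `gene_divergence`: `gene`, `usable_sites`,
#'   `differences`, `identity`, `flagged`.
#' @export
per_gene_divergence <- function(aln, ann) {
  stopifnot(inherits(aln, "seq_alignment"), inherits(ann, "annotated_genome"))
  M <- as.matrix(aln)
  row1 <- M[1, ]
  gpos <- which(row1 != "-")  # alignment column of each genome position
  Lg <- seq_length(ann)
  ind <- .pair_indicators(M)
  f <- ann$features
  rows <- lapply(seq_len(nrow(f)), function(i) {
    ex <- f$exons[[i]]
    pos1 <- unlist(lapply(seq_len(nrow(ex)), function(j) {
      ((ex[j, "start"] + seq_len(ex[j, "len"]) - 1) %% Lg) + 1
    }))
    flagged <- any(pos1 > length(gpos))
    cols <- gpos[pos1[pos1 <= length(gpos)]]
    u <- mean(vapply(ind, function(pp) sum(pp$usable[cols]), numeric(1)))
    d <- mean(vapply(ind, function(pp) sum(pp$diff[cols]), numeric(1)))
    data.frame(gene = f$name[i], usable_sites = u, differences = d,
               identity = if (u > 0) 100 * (1 - d / u) else NA_real_,
               flagged = flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # collapse duplicate gene copies (IR duplicates): pool sites/differences
  agg_u <- tapply(out$usable_sites, out$gene, sum)
  agg_d <- tapply(out$differences, out$gene, sum)
  agg_f <- tapply(out$flagged, out$gene, any)
  genes <- names(agg_u)
  out <- data.frame(gene = genes, usable_sites = as.numeric(agg_u),
                    differences = as.numeric(agg_d),
                    identity = ifelse(agg_u > 0, 100 * (1 - agg_d / agg_u),
                                      NA_real_),
                    flagged = as.logical(agg_f), stringsAsFactors = FALSE)
  out <- out[order(out$identity, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_divergence", "data.frame")
  out
}
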