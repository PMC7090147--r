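# Pairwise genome alignment (anchor chaining + banded gap filling) and the
# gapped-alignment container used by the divergence statistics.

#' Construct a sequence alignment
#'
#' @param seqs Character vector of equal-length gapped sequences (gap `-`).
#' @param ids Row identifiers.
#' @return Object of class `seq_alignment`: `ids`, `seqs`, `n_cols`.
#' @export
seq_alignment <- function(seqs, ids = names(seqs)) {
  seqs <- toupper(unname(seqs))
  if (length(seqs) < 2L) stop("an alignment needs at least 2 rows",
                              call. = FALSE)
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("ragged alignment: rows differ in length",
                            call. = FALSE)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  structure(list(ids = as.character(ids), seqs = seqs, n_cols = w),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("<seq_alignment> %d rows x %d columns (%s)\n",
              length(x$seqs), x$n_cols,
              paste(utils::head(x$ids, 4), collapse = ", ")))
  invisible(x)
}

#' @export
as.matrix.seq_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

#' Classify alignment columns
#'
#' @param aln A [seq_alignment()].
#' @return Character vector over columns: `ungapped_acgt` (all rows A/C/G/T),
#'   `gapped` (any `-`), or `ambiguous`.
#' @export
column_classes <- function(aln) {
  M <- as.matrix(aln)
  acgt <- M %in% c("A", "C", "G", "T")
  dim(acgt) <- dim(M)
  all_acgt <- colSums(acgt) == nrow(M)
  any_gap <- colSums(M == "-") > 0
  ifelse(all_acgt, "ungapped_acgt", ifelse(any_gap, "gapped", "ambiguous"))
}

#' Load an aligned FASTA file
#'
#' @param path Path to an aligned (gapped) multi-FASTA file.
#' @return A [seq_alignment()]. Errors on ragged rows or fewer than 2 rows.
#' @export
load_alignment <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) < 2L) stop("alignment file has fewer than 2 sequences: ",
                             path, call. = FALSE)
  seq_alignment(toupper(as.character(set)), ids = sub("\\s.*$", "", names(set)))
}

#' Write an alignment as gapped FASTA
#' @param aln A [seq_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(aln$seqs)) {
    writeLines(paste0(">", aln$ids[i]), con)
    L <- nchar(aln$seqs[i])
    st <- seq(1L, L, by = 70L)
    writeLines(substring(aln$seqs[i], st, pmin(st + 69L, L)), con)
  }
  invisible(path)
}

# cached nucleotide scoring matrix for the DP gap filler
.submat_env <- new.env(parent = emptyenv())
.nuc_submat <- function() {
  if (is.null(.submat_env$m)) {
    .submat_env$m <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE, type = "DNA")
  }
  .submat_env$m
}

.dp_align <- function(sa, sb) {
  pa <- Biostrings::pairwiseAlignment(
    sa, sb, type = "global", substitutionMatrix = .nuc_submat(),
    gapOpening = 4, gapExtension = 1)
  c(as.character(Biostrings::pattern(pa)),
    as.character(Biostrings::subject(pa)))
}

# align two unanchored segments; "" means pure gap on that side
.fill_segment <- function(sa, sb) {
  na <- nchar(sa); nb <- nchar(sb)
  if (na == 0L && nb == 0L) return(NULL)
  if (nb == 0L) return(c(sa, strrep("-", na)))
  if (na == 0L) return(c(strrep("-", nb), sb))
  if (na == nb && na <= 3L) return(c(sa, sb))  # gapless is DP-optimal here
  .dp_align(sa, sb)
}

# strictly-increasing longest chain of anchor positions (patience LIS)
.lis <- function(v) {
  n <- length(v)
  if (!n) return(integer())
  if (!is.unsorted(v, strictly = TRUE)) return(seq_len(n))
  tails_val <- numeric(n); tails_idx <- integer(n); prev <- integer(n)
  len <- 0L
  for (i in seq_len(n)) {
    x <- v[i]; lo <- 1L; hi <- len + 1L
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (tails_val[mid] < x) lo <- mid + 1L else hi <- mid
    }
    tails_val[lo] <- x; tails_idx[lo] <- i
    prev[i] <- if (lo > 1L) tails_idx[lo - 1L] else 0L
    if (lo > len) len <- lo
  }
  out <- integer(len); j <- tails_idx[len]
  for (t in len:1) { out[t] <- j; j <- prev[j] }
  out
}

# anchors: k-mers unique within each sequence and shared between them
.unique_kmer_anchors <- function(A, B, k) {
  nA <- nchar(A); nB <- nchar(B)
  if (nA < k || nB < k) return(data.frame(a = integer(), b = integer()))
  ka <- substring(A, 1:(nA - k + 1L), k:nA)
  kb <- substring(B, 1:(nB - k + 1L), k:nB)
  ua <- !(duplicated(ka) | duplicated(ka, fromLast = TRUE))
  ub <- !(duplicated(kb) | duplicated(kb, fromLast = TRUE))
  pa <- which(ua); pb <- which(ub)
  m <- match(ka[pa], kb[pb])
  sel <- !is.na(m)
  data.frame(a = pa[sel] - 1L, b = pb[m[sel]] - 1L)  # 0-based
}

#' Globally align two genome sequences
#'
#' Deterministic anchored alignment: k-mers unique in both sequences are
#' chained (longest strictly increasing chain), collinear anchors are merged
#' into exact blocks, and the unanchored segments between blocks are aligned
#' by global dynamic programming (Needleman-Wunsch via Biostrings). Inputs
#' are expected pre-canonicalized (same frame and orientation). When no
#' anchors exist the whole pair falls back to full dynamic programming if
#' both sequences are at most `max_full_dp` bases, otherwise an error
#' advises external alignment.
#'
#' @param a,b Sequences ([circular_sequence()], [annotated_genome()], or
#'   plain strings).
#' @param k Anchor k-mer length.
#' @param max_full_dp Size ceiling for the full-DP fallback.
#' @param ids Row ids for the output (defaults to the input ids).
#' @return A [seq_alignment()] with 2 rows.
#' @export
align_pair <- function(a, b, k = 21, max_full_dp = 20000, ids = NULL) {
  A <- .as_seq_string(a); B <- .as_seq_string(b)
  if (!nchar(A) || !nchar(B)) stop("cannot align empty sequences",
                                   call. = FALSE)
  if (is.null(ids)) {
    ids <- c(if (inherits(a, "annotated_genome")) a$sequence$id else
      if (inherits(a, "circular_sequence")) a$id else "seq1",
      if (inherits(b, "annotated_genome")) b$sequence$id else
        if (inherits(b, "circular_sequence")) b$id else "seq2")
    if (ids[1] == ids[2]) ids <- paste0(ids, c(".1", ".2"))
  }
  anc <- .unique_kmer_anchors(A, B, k)
  if (!nrow(anc)) {
    if (nchar(A) <= max_full_dp && nchar(B) <= max_full_dp) {
      rows <- .dp_align(A, B)
      return(seq_alignment(rows, ids = ids))
    }
    stop("no alignment anchors found and sequences exceed the exact-DP ",
         "ceiling; align externally and use load_alignment()", call. = FALSE)
  }
  anc <- anc[order(anc$a), , drop = FALSE]
  anc <- anc[.lis(anc$b), , drop = FALSE]

  # collapse same-diagonal, overlapping/adjacent anchors into blocks
  dg <- anc$b - anc$a
  newblk <- c(TRUE, diff(dg) != 0L | diff(anc$a) > k)
  blk <- cumsum(newblk)
  aS <- tapply(anc$a, blk, min); aE <- tapply(anc$a, blk, max) + k
  bS <- tapply(anc$b, blk, min); bE <- tapply(anc$b, blk, max) + k
  blocks <- data.frame(aS = as.vector(aS), aE = as.vector(aE),
                       bS = as.vector(bS), bE = as.vector(bE))
  # trim overlaps between consecutive blocks on different diagonals
  kept <- list(blocks[1, ])
  for (t in seq_len(nrow(blocks))[-1]) {
    cur <- kept[[length(kept)]]
    nb <- blocks[t, ]
    sft <- max(cur$aE - nb$aS, cur$bE - nb$bS, 0)
    nb$aS <- nb$aS + sft; nb$bS <- nb$bS + sft
    if (nb$aS < nb$aE && nb$bS < nb$bE) kept[[length(kept) + 1L]] <- nb
  }
  blocks <- do.call(rbind, kept)

  rowA <- character(); rowB <- character()
  prevA <- 0L; prevB <- 0L
  for (t in seq_len(nrow(blocks))) {
    bk <- blocks[t, ]
    seg <- .fill_segment(substr0(A, prevA, bk$aS - prevA),
                         substr0(B, prevB, bk$bS - prevB))
    if (!is.null(seg)) { rowA <- c(rowA, seg[1]); rowB <- c(rowB, seg[2]) }
    rowA <- c(rowA, substr0(A, bk$aS, bk$aE - bk$aS))
    rowB <- c(rowB, substr0(B, bk$bS, bk$bE - bk$bS))
    prevA <- bk$aE; prevB <- bk$bE
  }
  seg <- .fill_segment(substr0(A, prevA, nchar(A) - prevA),
                       substr0(B, prevB, nchar(B) - prevB))
  if (!is.null(seg)) { rowA <- c(rowA, seg[1]); rowB <- c(rowB, seg[2]) }
  seq_alignment(c(.collapse(rowA), .collapse(rowB)), ids = ids)
}
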