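# Circular nucleotide sequences: the base container for a plastome.
# Coordinates are 0-based, half-open everywhere inside the package; report
# files and GenBank output use 1-based inclusive coordinates.

#' Create a circular (or linear) nucleotide sequence
#'
#' @param seq Character scalar; DNA in the IUPAC alphabet (case-insensitive,
#'   stored uppercase).
#' @param id Sequence identifier.
#' @param circular Logical; plastomes are circular, test fixtures may be
#'   linear, in which case no coordinate arithmetic wraps the origin.
#' @return An object of class `circular_sequence` with fields `id`, `seq`,
#'   `circular`.
#' @examples
#' cs <- circular_sequence("ACGTACGT", id = "toy")
#' seq_length(cs)
#' @export
circular_sequence <- function(seq, id = "seq", circular = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("zero-length sequence", call. = FALSE)
  if (!.is_dna_string(seq)) {
    stop("sequence contains characters outside the IUPAC DNA alphabet",
         call. = FALSE)
  }
  structure(list(id = as.character(id), seq = seq,
                 circular = isTRUE(circular)),
            class = "circular_sequence")
}

#' Length of a sequence in bases
#' @param x A `circular_sequence` or `annotated_genome`.
#' @return Integer number of bases.
#' @export
seq_length <- function(x) {
  if (inherits(x, "annotated_genome")) x <- x$sequence
  nchar(x$seq)
}

# coerce annotated_genome / circular_sequence / string to plain string
.as_seq_string <- function(x) {
  if (inherits(x, "annotated_genome")) return(x$sequence$seq)
  if (inherits(x, "circular_sequence")) return(x$seq)
  stopifnot(is.character(x), length(x) == 1L)
  toupper(x)
}

.is_circular <- function(x) {
  if (inherits(x, "annotated_genome")) x <- x$sequence
  if (inherits(x, "circular_sequence")) return(x$circular)
  TRUE
}

#' Extract a subsequence by 0-based half-open coordinates
#'
#' Wraps around the origin when the sequence is circular.
#'
#' @param x A `circular_sequence`.
#' @param start 0-based start.
#' @param len Length in bases (`len <= seq_length(x)`).
#' @return Character scalar.
#' @export
cs_subseq <- function(x, start, len) {
  s <- .as_seq_string(x)
  L <- nchar(s)
  stopifnot(len >= 0, len <= L)
  start <- start %% L
  if (start + len <= L) return(substr0(s, start, len))
  if (!.is_circular(x)) stop("interval runs past the end of a linear sequence",
                             call. = FALSE)
  paste0(substr0(s, start, L - start), substr0(s, 0, len - (L - start)))
}

#' Rotate a circular sequence so that `offset` becomes coordinate 0
#' @param x A `circular_sequence`.
#' @param offset 0-based coordinate of the new origin.
#' @return A rotated `circular_sequence`.
#' @export
cs_rotate <- function(x, offset) {
  s <- .as_seq_string(x)
  L <- nchar(s)
  offset <- offset %% L
  if (offset == 0) return(x)
  if (!.is_circular(x)) stop("cannot rotate a linear sequence", call. = FALSE)
  out <- x
  out$seq <- paste0(substr0(s, offset, L - offset), substr0(s, 0, offset))
  out
}

#' GC content as a percentage
#'
#' Computed as 100 * (G + C) / (A + C + G + T); ambiguity codes are legal in
#' the sequence but excluded from both numerator and denominator.
#'
#' @param x A `circular_sequence`, `annotated_genome`, or character scalar.
#' @return Percentage in `[0, 100]`.
#' @examples
#' gc_percent("ATGC")
#' @export
gc_percent <- function(x) {
  s <- .as_seq_string(x)
  n <- vapply(c("A", "C", "G", "T"), function(b) {
    lengths(regmatches(s, gregexpr(b, s, fixed = TRUE)))
  }, numeric(1))
  tot <- sum(n)
  if (tot == 0) return(NA_real_)
  100 * (n[["G"]] + n[["C"]]) / tot
}

#' @export
print.circular_sequence <- function(x, ...) {
  cat(sprintf("<circular_sequence> %s: %d bp, %s\n", x$id, nchar(x$seq),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}
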