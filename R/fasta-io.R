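# FASTA input (via Biostrings) and plain writers for FASTA and GFF3.

#' Read a multi-FASTA file as circular sequences
#'
#' @param path Path to a FASTA file.
#' @param circular Logical; topology to assign (FASTA carries none).
#' @return A list of [circular_sequence()] objects, named by id.
#' @export
read_fasta <- function(path, circular = TRUE) {
  set <- Biostrings::readDNAStringSet(path)
  if (!length(set)) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_along(set), function(i) {
    circular_sequence(toupper(as.character(set[[i]])), id = ids[i],
                      circular = circular)
  })
  names(out) <- ids
  out
}

#' Write sequences to a multi-FASTA file
#'
#' @param seqs A [circular_sequence()], [annotated_genome()], or a list of
#'   either.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (inherits(seqs, c("circular_sequence", "annotated_genome"))) {
    seqs <- list(seqs)
  }
  con <- file(path, "w"); on.exit(close(con))
  for (x in seqs) {
    if (inherits(x, "annotated_genome")) x <- x$sequence
    writeLines(paste0(">", x$id), con)
    L <- nchar(x$seq)
    starts <- seq(1L, L, by = width)
    writeLines(substring(x$seq, starts, pmin(starts + width - 1L, L)), con)
  }
  invisible(path)
}

#' Export gene features as GFF3
#'
#' One line per exon, with the gene symbol in a `gene` attribute; coordinates
#' are 1-based inclusive as the format requires.
#'
#' @param g An [annotated_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(g, path) {
  stopifnot(inherits(g, "annotated_genome"))
  L <- seq_length(g)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", g$sequence$id, L), con)
  for (i in seq_len(nrow(g$features))) {
    ex <- g$features$exons[[i]]
    for (j in seq_len(nrow(ex))) {
      st <- ex[j, "start"]; len <- ex[j, "len"]
      ends <- if (st + len <= L) {
        cbind(st + 1, st + len)
      } else {  # origin-wrapping exon as two lines
        rbind(c(st + 1, L), c(1, st + len - L))
      }
      for (r in seq_len(nrow(ends))) {
        writeLines(sprintf("%s\tplastome\t%s\t%d\t%d\t.\t%s\t.\tgene=%s",
                           g$sequence$id, g$features$kind[i],
                           ends[r, 1], ends[r, 2], g$features$strand[i],
                           g$features$name[i]), con)
      }
    }
  }
  invisible(path)
}
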