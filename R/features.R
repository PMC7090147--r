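# Gene features on a circular genome and the annotated-genome container.
#
# A feature table is a data.frame with columns
#   name   gene symbol (case-sensitive; IR duplicates repeat the name)
#   kind   one of CDS / tRNA / rRNA
#   strand "+" or "-"
#   exons  list column; each element a 2-column matrix (start, len),
#          0-based, exons in ascending genome order; an exon may wrap the
#          origin (its span is interpreted modulo L)
# Introns are the gaps between consecutive exons.

.FEATURE_KINDS <- c("CDS", "tRNA", "rRNA")

#' Build a gene-feature table
#'
#' @param name Character vector of gene symbols.
#' @param kind Character vector: `CDS`, `tRNA` or `rRNA`.
#' @param strand Character vector: `"+"` or `"-"`.
#' @param exons List of 2-column matrices `(start, len)` with 0-based starts,
#'   one matrix per feature, exons in ascending order.
#' @return A data.frame usable as the `features` slot of an
#'   [annotated_genome()].
#' @export
gene_features <- function(name = character(), kind = character(),
                          strand = character(), exons = list()) {
  stopifnot(length(name) == length(kind),
            length(name) == length(strand),
            length(name) == length(exons))
  if (length(kind) && !all(kind %in% .FEATURE_KINDS)) {
    stop("kind must be one of ", paste(.FEATURE_KINDS, collapse = "/"),
         call. = FALSE)
  }
  if (length(strand) && !all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  exons <- lapply(exons, function(e) {
    e <- matrix(as.numeric(e), ncol = 2,
                dimnames = list(NULL, c("start", "len")))
    if (nrow(e) == 0L) stop("feature with no exons", call. = FALSE)
    if (any(e[, "len"] <= 0)) stop("exon with non-positive length",
                                   call. = FALSE)
    e
  })
  df <- data.frame(name = as.character(name), kind = as.character(kind),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  df$exons <- exons
  df
}

#' Assemble an annotated genome
#'
#' @param sequence A [circular_sequence()].
#' @param features A feature table from [gene_features()].
#' @param source Free-text provenance tag (file path, accession, or a
#'   synthetic-truth tag).
#' @return Object of class `annotated_genome`.
#' @export
annotated_genome <- function(sequence, features = gene_features(),
                             source = "") {
  stopifnot(inherits(sequence, "circular_sequence"))
  L <- nchar(sequence$seq)
  for (e in features$exons) {
    if (any(e[, "start"] < 0 | e[, "start"] >= L) || any(e[, "len"] > L)) {
      stop("feature exon outside [0, L)", call. = FALSE)
    }
  }
  structure(list(sequence = sequence, features = features,
                 source = as.character(source)),
            class = "annotated_genome")
}

# span of a feature: c(start, len) from first exon start to last exon end,
# modulo L for wrapping genes
.feature_span <- function(exons, L) {
  st <- unname(exons[1, "start"])
  en <- unname(exons[nrow(exons), "start"] + exons[nrow(exons), "len"])
  len <- (en - st) %% L
  if (len == 0) len <- L
  c(start = st, len = len)
}

# intron intervals (start, len) between consecutive exons, modulo L
.feature_introns <- function(exons, L) {
  n <- nrow(exons)
  if (n < 2L) {
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "len"))))
  }
  st <- unname(exons[-n, "start"] + exons[-n, "len"]) %% L
  len <- (unname(exons[-1, "start"]) - st) %% L
  cbind(start = st, len = len)
}

# extract the spliced (exon-only) sequence of one feature, on its own strand
feature_sequence <- function(g, i) {
  ex <- g$features$exons[[i]]
  s <- .collapse(vapply(seq_len(nrow(ex)), function(j) {
    cs_subseq(g$sequence, ex[j, "start"], ex[j, "len"])
  }, character(1)))
  if (g$features$strand[i] == "-") revcomp(s) else s
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %d bp, %d features (%s)\n",
              x$sequence$id, seq_length(x), nrow(x$features),
              paste(names(table(x$features$kind)),
                    table(x$features$kind), sep = ":", collapse = " ")))
  invisible(x)
}

# shift all feature coordinates by -offset (rotation remap), modulo L
.shift_features <- function(features, offset, L) {
  features$exons <- lapply(features$exons, function(e) {
    e[, "start"] <- (e[, "start"] - offset) %% L
    # keep exons in ascending genome order where possible (wrapping genes
    # keep their original exon order)
    e
  })
  features
}
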