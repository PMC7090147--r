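# Internal string/DNA helpers shared across modules.

.IUPAC      <- "ACGTRYSWKMBDHVN"
.IUPAC_COMP <- "TGCAYRSWMKVHDBN"

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

.collapse <- function(v) paste(v, collapse = "")

#' Reverse complement of a DNA string
#'
#' Complements IUPAC ambiguity codes and reverses the string. Gap characters
#' (`-`) are preserved in place.
#'
#' @param x A character scalar (DNA, IUPAC alphabet, upper or lower case).
#' @return A character scalar of the same length.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  comp <- chartr(paste0(.IUPAC, tolower(.IUPAC)),
                 paste0(.IUPAC_COMP, tolower(.IUPAC_COMP)), x)
  intToUtf8(rev(utf8ToInt(comp)))
}

# i.i.d. random DNA with a given GC proportion
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  .collapse(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)))
}

# substring by 0-based half-open coordinates on a plain string
substr0 <- function(x, start, len) {
  if (len <= 0) return("")
  substr(x, start + 1L, start + len)
}

.is_dna_string <- function(x) {
  grepl(paste0("^[", .IUPAC, "]*$"), x)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# deterministic integer sub-seed derived from a base seed (kept < 2^31)
.subseed <- function(seed, i) {
  (as.integer(seed) + 7919L * as.integer(i)) %% 2147483629L
}
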