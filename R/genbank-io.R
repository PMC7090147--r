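# Minimal single-record GenBank flat-file reader/writer.
#
# The writer emits LOCUS / FEATURES / ORIGIN sections with CDS, tRNA and
# rRNA feature keys and /gene qualifiers; locations use 1-based inclusive
# coordinates, join() for multi-exon genes, complement() for the minus
# strand, and an origin-wrapping exon is emitted as a join of two spans.
# The reader resolves those locations back into 0-based exon lists, so
# read_genbank(write_genbank(g)) is the identity on sequence and features.

#' Read a single-record GenBank flat file
#'
#' Parses the LOCUS line, the CDS/tRNA/rRNA features (with `join`,
#' `complement` and origin-wrapping locations) and the ORIGIN sequence.
#' Feature names are taken from the `/gene` qualifier, falling back to
#' `/product`.
#'
#' @param path Path to a GenBank flat file containing one record.
#' @return An [annotated_genome()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty GenBank file: ", path, call. = FALSE)

  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("malformed GenBank file (no LOCUS line): ", path,
                             call. = FALSE)
  locus <- lines[locus_i[1]]
  toks <- strsplit(trimws(sub("^LOCUS", "", locus)), "[[:space:]]+")[[1]]
  id <- toks[1]
  circular <- any(tolower(toks) == "circular")

  origin_i <- grep("^ORIGIN", lines)
  if (!length(origin_i)) stop("malformed GenBank file (no ORIGIN block): ",
                              path, call. = FALSE)
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > origin_i[1]][1] else length(lines) + 1L
  seq_lines <- if (end_i - 1L >= origin_i[1] + 1L) {
    lines[seq(origin_i[1] + 1L, end_i - 1L)]
  } else character()
  seq <- toupper(gsub("[0-9[:space:]]", "", .collapse(seq_lines)))
  if (nchar(seq) == 0L) stop("zero-length sequence in ", path, call. = FALSE)

  feat_i <- grep("^FEATURES", lines)
  features <- gene_features()
  if (length(feat_i)) {
    block <- lines[seq(feat_i[1] + 1L, origin_i[1] - 1L)]
    lineno <- seq(feat_i[1] + 1L, origin_i[1] - 1L)
    features <- .parse_feature_block(block, lineno, nchar(seq))
  }
  annotated_genome(circular_sequence(seq, id = id, circular = circular),
                   features, source = path)
}

.parse_feature_block <- function(block, lineno, L) {
  # a new feature starts at column 6 (5 leading spaces, non-space at 6)
  is_key <- grepl("^ {5}[^ ]", block)
  starts <- which(is_key)
  name <- character(); kind <- character(); strand <- character()
  exons <- list()
  for (si in seq_along(starts)) {
    i0 <- starts[si]
    i1 <- if (si < length(starts)) starts[si + 1L] - 1L else length(block)
    key <- sub("^ +([^ ]+).*$", "\\1", block[i0])
    body <- c(sub("^ {5}[^ ]+ +", "", block[i0]),
              trimws(block[seq_len(i1 - i0) + i0]))
    # location = leading lines up to the first qualifier
    qual_start <- grep("^/", body)
    loc_lines <- if (length(qual_start)) body[seq_len(qual_start[1] - 1L)] else body
    loc <- gsub("[[:space:]]", "", .collapse(loc_lines))
    quals <- if (length(qual_start)) body[seq(qual_start[1], length(body))] else character()
    if (!key %in% .FEATURE_KINDS) next
    parsed <- tryCatch(.parse_location(loc, L),
                       error = function(e) {
                         stop(sprintf("cannot parse location at line %d: %s",
                                      lineno[i0], conditionMessage(e)),
                              call. = FALSE)
                       })
    gname <- .qualifier_value(quals, "gene")
    if (is.na(gname)) gname <- .qualifier_value(quals, "product")
    if (is.na(gname)) gname <- paste0(key, "_", si)
    name <- c(name, gname); kind <- c(kind, key)
    strand <- c(strand, parsed$strand)
    exons <- c(exons, list(parsed$exons))
  }
  gene_features(name, kind, strand, exons)
}

.qualifier_value <- function(quals, what) {
  hit <- grep(paste0("^/", what, "="), quals, value = TRUE)
  if (!length(hit)) return(NA_character_)
  gsub('^[^=]*="?|"$', "", hit[1])
}

# parse a GenBank location string into 0-based exons + strand
.parse_location <- function(loc, L) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  spans <- strsplit(loc, ",", fixed = TRUE)[[1]]
  if (!length(spans)) stop("empty location")
  mat <- t(vapply(spans, function(sp) {
    if (grepl("^<?[0-9]+\\.\\.>?[0-9]+$", sp)) {
      ab <- as.numeric(strsplit(gsub("[<>]", "", sp), "..", fixed = TRUE)[[1]])
    } else if (grepl("^[0-9]+$", sp)) {
      ab <- c(as.numeric(sp), as.numeric(sp))
    } else stop("bad span '", sp, "'")
    if (ab[2] < ab[1]) stop("span end before start in '", sp, "'")
    c(ab[1] - 1, ab[2] - ab[1] + 1)  # 0-based start, len
  }, numeric(2)))
  dimnames(mat) <- list(NULL, c("start", "len"))
  # merge a span pair that represents one exon wrapping the origin
  if (nrow(mat) >= 2) {
    keep <- rep(TRUE, nrow(mat))
    for (i in seq_len(nrow(mat) - 1L)) {
      if (!keep[i]) next
      if (mat[i, "start"] + mat[i, "len"] == L && mat[i + 1L, "start"] == 0) {
        mat[i, "len"] <- mat[i, "len"] + mat[i + 1L, "len"]
        keep[i + 1L] <- FALSE
      }
    }
    mat <- mat[keep, , drop = FALSE]
  }
  list(strand = strand, exons = mat)
}

#' Write an annotated genome as a GenBank flat file
#'
#' @param g An [annotated_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(g, path) {
  stopifnot(inherits(g, "annotated_genome"))
  L <- seq_length(g)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing", call. = FALSE)
  })
  on.exit(close(con))
  topo <- if (g$sequence$circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s PLN 01-JAN-2020",
                     g$sequence$id, L, topo), con)
  writeLines(sprintf("DEFINITION  %s.", g$sequence$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  if (nrow(g$features)) {
    for (i in seq_len(nrow(g$features))) {
      loc <- .format_location(g$features$exons[[i]],
                              g$features$strand[i], L)
      writeLines(sprintf("     %-16s%s", g$features$kind[i], loc), con)
      writeLines(sprintf("                     /gene=\"%s\"",
                         g$features$name[i]), con)
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(g$sequence$seq)
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, L))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

.format_location <- function(exons, strand, L) {
  spans <- character()
  for (i in seq_len(nrow(exons))) {
    st <- exons[i, "start"]; len <- exons[i, "len"]
    if (st + len <= L) {
      spans <- c(spans, sprintf("%d..%d", st + 1, st + len))
    } else {  # origin-wrapping exon -> two spans
      spans <- c(spans, sprintf("%d..%d", st + 1, L),
                 sprintf("1..%d", st + len - L))
    }
  }
  loc <- if (length(spans) > 1L) {
    sprintf("join(%s)", paste(spans, collapse = ","))
  } else spans
  if (strand == "-") sprintf("complement(%s)", loc) else loc
}
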