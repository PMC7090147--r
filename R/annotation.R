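# Annotation summaries, functional classification, and annotation-set
# comparison between two genomes on a common quadripartite frame.

#' Load the bundled canonical plastid gene-class table
#'
#' A TSV mapping canonical plastid gene symbols to one of three functional
#' classes: `photosynthesis`, `transcription_translation`, `other`. The file
#' ships under `extdata` and is editable; pass your own path to override.
#'
#' @param path Optional path to an alternative two-column TSV
#'   (`gene`, `class`).
#' @return Named character vector: gene symbol -> class.
#' @export
plastid_gene_classes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "plastid_gene_classes.tsv",
                        package = "plastome", mustWork = TRUE)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(df$class, df$gene)
}

#' Summarize a genome annotation
#'
#' Counts are over *unique* gene names (the two IR copies of a duplicated
#' gene collapse to one), which is the convention under which a typical
#' plastome reports ~113 genes while carrying ~131 features. Intron
#' statistics use one copy per gene; `mean_exon_len` averages over the exons
#' of intron-containing genes.
#'
#' @param g An [annotated_genome()] with at least one feature.
#' @param partition Optional [quadripartite_partition]; required for
#'   `n_ir_duplicated` (NA otherwise).
#' @return A list of class `annotation_summary`.
#' @export
summarize_annotation <- function(g, partition = NULL) {
  stopifnot(inherits(g, "annotated_genome"))
  f <- g$features
  if (!nrow(f)) stop("genome has no features", call. = FALSE)
  L <- seq_length(g)

  first_idx <- match(unique(f$name), f$name)
  kinds <- f$kind[first_idx]
  n_unique <- length(first_idx)

  # intron statistics over unique genes (first copy of each name)
  intron_len <- list(); exon_len_intron_genes <- numeric()
  n_single <- 0L; n_double <- 0L
  for (i in first_idx) {
    intr <- .feature_introns(f$exons[[i]], L)
    if (nrow(intr) == 1L) n_single <- n_single + 1L
    if (nrow(intr) >= 2L) n_double <- n_double + 1L
    if (nrow(intr)) {
      intron_len[[f$name[i]]] <- intr[, "len"]
      exon_len_intron_genes <- c(exon_len_intron_genes,
                                 f$exons[[i]][, "len"])
    }
  }
  all_introns <- unlist(intron_len)
  longest <- shortest <- list(gene = NA_character_, len = NA_real_)
  if (length(all_introns)) {
    per_gene_max <- vapply(intron_len, max, numeric(1))
    per_gene_min <- vapply(intron_len, min, numeric(1))
    longest <- list(gene = names(which.max(per_gene_max)),
                    len = max(per_gene_max))
    shortest <- list(gene = names(which.min(per_gene_min)),
                     len = min(per_gene_min))
  }

  n_ir_dup <- NA_integer_
  if (!is.null(partition)) {
    in_region <- function(i, reg) {
      sp <- .feature_span(f$exons[[i]], L)
      .interval_contains(partition[[reg]], sp, L)
    }
    dup_names <- unique(f$name[duplicated(f$name)])
    n_ir_dup <- sum(vapply(dup_names, function(nm) {
      idx <- which(f$name == nm)
      any(vapply(idx, in_region, logical(1), reg = "ira")) &&
        any(vapply(idx, in_region, logical(1), reg = "irb"))
    }, logical(1)))
  }

  structure(list(
    n_unique_genes = n_unique,
    n_protein = sum(kinds == "CDS"),
    n_trna = sum(kinds == "tRNA"),
    n_rrna = sum(kinds == "rRNA"),
    n_ir_duplicated = n_ir_dup,
    n_intron_genes = n_single + n_double,
    n_single_intron = n_single,
    n_double_intron = n_double,
    mean_intron_len = if (length(all_introns)) mean(all_introns) else NA_real_,
    mean_exon_len = if (length(exon_len_intron_genes)) {
      mean(exon_len_intron_genes)
    } else NA_real_,
    longest_intron = longest,
    shortest_intron = shortest,
    gc_percent = gc_percent(g)
  ), class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Annotation summary\n",
    "  unique genes: %d (CDS %d, tRNA %d, rRNA %d)\n",
    "  IR-duplicated: %s; intron genes: %d (%d single, %d double)\n",
    "  mean intron %.1f bp, mean exon %.1f bp; GC %.2f%%\n"),
    x$n_unique_genes, x$n_protein, x$n_trna, x$n_rrna,
    ifelse(is.na(x$n_ir_duplicated), "NA", x$n_ir_duplicated),
    x$n_intron_genes, x$n_single_intron, x$n_double_intron,
    x$mean_intron_len, x$mean_exon_len, x$gc_percent))
  invisible(x)
}

#' @export
as.data.frame.annotation_summary <- function(x, ...) {
  data.frame(
    statistic = c("n_unique_genes", "n_protein", "n_trna", "n_rrna",
                  "n_ir_duplicated", "n_intron_genes", "n_single_intron",
                  "n_double_intron", "mean_intron_len", "mean_exon_len",
                  "longest_intron_gene", "longest_intron_len",
                  "shortest_intron_gene", "shortest_intron_len",
                  "gc_percent"),
    value = c(x$n_unique_genes, x$n_protein, x$n_trna, x$n_rrna,
              x$n_ir_duplicated, x$n_intron_genes, x$n_single_intron,
              x$n_double_intron, x$mean_intron_len, x$mean_exon_len,
              x$longest_intron$gene, x$longest_intron$len,
              x$shortest_intron$gene, x$shortest_intron$len,
              x$gc_percent),
    stringsAsFactors = FALSE)
}

#' Write an annotation summary as TSV
#' @param x An `annotation_summary` from [summarize_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_summary <- function(x, path) {
  .write_tsv(as.data.frame(x), path)
  invisible(path)
}

#' Classify genes into functional groups
#'
#' @param g An [annotated_genome()].
#' @param table Named character vector from [plastid_gene_classes()].
#' @return A list `photosynthesis` / `transcription_translation` / `other` /
#'   `unclassified`, each a character vector of unique gene names.
#' @export
classify_genes <- function(g, table = plastid_gene_classes()) {
  nm <- unique(g$features$name)
  cls <- unname(table[nm])
  cls[is.na(cls)] <- "unclassified"
  out <- split(nm, factor(cls, levels = c("photosynthesis",
                                          "transcription_translation",
                                          "other", "unclassified")))
  lapply(out, as.character)
}

# which quadripartite region contains a feature span (by its start)
.region_of <- function(span, partition) {
  for (reg in c("lsc", "ira", "ssc", "irb")) {
    if (.point_in_interval(partition[[reg]], span["start"], partition$L)) {
      return(toupper(reg))
    }
  }
  NA_character_
}

#' Compare two genome annotations region by region
#'
#' Reports genes present in only one genome (with the quadripartite region
#' of each copy) and genes present in both with different copy numbers.
#'
#' @param a,b [annotated_genome()] objects.
#' @param pa,pb Their [quadripartite_partition]s.
#' @return A list of class `annotation_diff` with elements `genes_only_in_a`,
#'   `genes_only_in_b` (data.frames `name`, `region`) and
#'   `copy_number_diffs` (`name`, `copies_a`, `copies_b`).
#' @export
compare_annotations <- function(a, b, pa, pb) {
  tab <- function(g, p) {
    f <- g$features
    L <- seq_length(g)
    region <- vapply(seq_len(nrow(f)), function(i) {
      .region_of(.feature_span(f$exons[[i]], L), p)
    }, character(1))
    data.frame(name = f$name, region = region, stringsAsFactors = FALSE)
  }
  ta <- tab(a, pa); tb <- tab(b, pb)
  only_a <- ta[!(ta$name %in% tb$name), , drop = FALSE]
  only_b <- tb[!(tb$name %in% ta$name), , drop = FALSE]
  shared <- intersect(unique(ta$name), unique(tb$name))
  ca <- table(ta$name)[shared]; cb <- table(tb$name)[shared]
  diff <- shared[ca != cb]
  structure(list(
    genes_only_in_a = only_a[order(only_a$name), , drop = FALSE],
    genes_only_in_b = only_b[order(only_b$name), , drop = FALSE],
    copy_number_diffs = data.frame(name = diff,
                                   copies_a = as.integer(ca[diff]),
                                   copies_b = as.integer(cb[diff]),
                                   stringsAsFactors = FALSE)
  ), class = "annotation_diff")
}

#' @export
print.annotation_diff <- function(x, ...) {
  cat(sprintf("Annotation diff: %d only in a, %d only in b, %d copy-number diffs\n",
              nrow(x$genes_only_in_a), nrow(x$genes_only_in_b),
              nrow(x$copy_number_diffs)))
  invisible(x)
}
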