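# End-to-end orchestration: structure -> repeats -> divergence -> phylogeny
# over a set of genomes, with TSV tables and a machine-readable summary.

#' Build a pipeline configuration
#'
#' Defaults follow the package's standard analysis settings: diversity
#' window 800 bp / step 50 bp, hypervariable threshold pi >= 0.7, SSR tract
#' >= 10 nt, long repeats >= 30 bp, K2P distances with pairwise deletion.
#'
#' @param genomes Named list of [annotated_genome()] objects and/or file
#'   paths (`.gb`/`.gbk` GenBank, `.fa`/`.fasta` FASTA).
#' @param reference Optional reference genome (object or path) for the SSC
#'   orientation survey.
#' @param outdir Output directory (created).
#' @param window,step Sliding-window diversity parameters (columns).
#' @param pi_threshold Hypervariable-region threshold.
#' @param ssr_min_tract Minimum SSR tract length.
#' @param repeat_min_len Minimum long-repeat length.
#' @param ir_min_len,ir_max_mismatch IR-detection parameters.
#' @param model,deletion Distance model and gap handling for the tree stage.
#' @param seed Integer seed echoed into every output.
#' @return A list of class `run_config`.
#' @export
run_config <- function(genomes, reference = NULL,
                       outdir = file.path(tempdir(), "plastome_report"),
                       window = 800, step = 50, pi_threshold = 0.7,
                       ssr_min_tract = 10, repeat_min_len = 30,
                       ir_min_len = 1000, ir_max_mismatch = 0.001,
                       model = "k2p", deletion = "pairwise", seed = 1) {
  structure(list(genomes = genomes, reference = reference, outdir = outdir,
                 window = window, step = step, pi_threshold = pi_threshold,
                 ssr_min_tract = ssr_min_tract,
                 repeat_min_len = repeat_min_len, ir_min_len = ir_min_len,
                 ir_max_mismatch = ir_max_mismatch, model = model,
                 deletion = deletion, seed = as.integer(seed)),
            class = "run_config")
}

.load_genome_arg <- function(x, id = NULL) {
  if (inherits(x, "annotated_genome")) return(x)
  if (inherits(x, "circular_sequence")) return(annotated_genome(x))
  stopifnot(is.character(x), length(x) == 1L)
  if (grepl("\\.(gb|gbk|genbank)$", x, ignore.case = TRUE)) {
    return(read_genbank(x))
  }
  seqs <- read_fasta(x)
  annotated_genome(seqs[[1]], source = x)
}

#' Run the full comparative-analysis pipeline
#'
#' Per genome: quadripartite structure, SSR scan, long-repeat scan (TSV
#' tables, 1-based coordinates). With a reference: SSC orientation survey.
#' With 2 or more genomes: all canonical pairwise alignments, sliding-window
#' diversity and substitution spectra. With 3 or more: a neighbor-joining
#' tree from the chosen distance model, written as Newick. A summary JSON
#' collects every computed number together with the configuration echo.
#' Stage failures are isolated per genome/pair; the run only fails if
#' nothing succeeded. Rerunning with the same config and seed reproduces
#' the outputs byte for byte.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory results (`structure`,
#'   `ssr`, `repeats`, `survey`, `pairs`, `distance`, `tree`,
#'   `summary_path`).
#' @export
run_report <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  ids <- names(cfg$genomes)
  genomes <- lapply(seq_along(cfg$genomes), function(i) {
    tryCatch(suppressWarnings(.load_genome_arg(cfg$genomes[[i]])),
             error = function(e) e)
  })
  if (is.null(ids)) {
    ids <- vapply(seq_along(genomes), function(i) {
      if (inherits(genomes[[i]], "error")) paste0("genome", i)
      else genomes[[i]]$sequence$id
    }, character(1))
  }
  names(genomes) <- ids
  message("plastome report: ", length(genomes), " genome(s), seed ", cfg$seed)

  struct_rows <- list(); ssr_all <- list(); rep_all <- list()
  canon <- list()
  for (id in ids) {
    g <- genomes[[id]]
    if (inherits(g, "error")) {
      struct_rows[[id]] <- data.frame(
        genome_id = id, L = NA_real_, lsc_len = NA_real_, ssc_len = NA_real_,
        ir_len = NA_real_, ir_mismatch = NA_real_, n_ssr = NA_integer_,
        n_repeats = NA_integer_, status = conditionMessage(g))
      next
    }
    row <- tryCatch({
      ir <- find_inverted_repeat_pair(g$sequence, min_len = cfg$ir_min_len,
                                      max_mismatch = cfg$ir_max_mismatch)
      p <- if (ir$found) partition_genome(g$sequence, ir) else NULL
      if (!is.null(p)) {
        g$partition <- p
        canon[[id]] <- canonicalize(g, p)
      }
      if (nrow(g$features) && !is.null(p)) {
        write_annotation_summary(summarize_annotation(g, p),
                                 file.path(cfg$outdir,
                                           paste0("annotation_", id, ".tsv")))
      }
      loci <- find_ssrs(g$sequence, min_tract = cfg$ssr_min_tract)
      reps <- find_long_repeats(g$sequence, min_len = cfg$repeat_min_len,
                                ir_exclude = if (ir$found) ir else NULL)
      ssr_out <- data.frame(genome_id = id, motif = loci$motif,
                            class = c("mono", "di", "tri", "tetra", "penta",
                                      "hexa")[loci$motif_len],
                            copies = loci$copies, start = loci$start + 1,
                            end = loci$start + loci$tract_len)
      rep_out <- data.frame(genome_id = id, kind = reps$kind,
                            start1 = reps$start1 + 1, start2 = reps$start2 + 1,
                            length = reps$length)
      ssr_all[[id]] <- ssr_out; rep_all[[id]] <- rep_out
      data.frame(genome_id = id, L = seq_length(g),
                 lsc_len = if (is.null(p)) NA_real_ else p$lsc[["len"]],
                 ssc_len = if (is.null(p)) NA_real_ else p$ssc[["len"]],
                 ir_len = if (is.null(p)) NA_real_ else p$ira[["len"]],
                 ir_mismatch = if (ir$found) ir$mismatch_fraction else NA_real_,
                 n_ssr = nrow(loci), n_repeats = nrow(reps), status = "ok")
    }, error = function(e) {
      data.frame(genome_id = id, L = seq_length(g), lsc_len = NA_real_,
                 ssc_len = NA_real_, ir_len = NA_real_,
                 ir_mismatch = NA_real_, n_ssr = NA_integer_,
                 n_repeats = NA_integer_, status = conditionMessage(e))
    })
    struct_rows[[id]] <- row
  }
  structure_tab <- do.call(rbind, struct_rows)
  rownames(structure_tab) <- NULL
  .write_tsv(structure_tab, file.path(cfg$outdir, "structure.tsv"))
  ssr_tab <- if (length(ssr_all)) do.call(rbind, ssr_all) else NULL
  rep_tab <- if (length(rep_all)) do.call(rbind, rep_all) else NULL
  if (!is.null(ssr_tab)) .write_tsv(ssr_tab, file.path(cfg$outdir, "ssr.tsv"))
  if (!is.null(rep_tab)) {
    .write_tsv(rep_tab, file.path(cfg$outdir, "repeats.tsv"))
  }

  survey <- NULL
  if (!is.null(cfg$reference)) {
    ref <- tryCatch(.load_genome_arg(cfg$reference), error = function(e) e)
    if (!inherits(ref, "error")) {
      ok_g <- genomes[!vapply(genomes, inherits, logical(1), "error")]
      survey <- orientation_survey(ok_g, ref, ir_min_len = cfg$ir_min_len,
                                   max_mismatch = cfg$ir_max_mismatch)
      .write_tsv(survey, file.path(cfg$outdir, "orientation_survey.tsv"))
    }
  }

  pairs <- list(); D <- NULL; tree <- NULL
  usable <- names(canon)
  if (length(usable) >= 2) {
    pr <- utils::combn(usable, 2)
    aligned <- list()
    for (t in seq_len(ncol(pr))) {
      id1 <- pr[1, t]; id2 <- pr[2, t]
      res <- tryCatch({
        aln <- align_pair(canon[[id1]], canon[[id2]], ids = c(id1, id2))
        prof <- sliding_pi(aln, window = cfg$window, step = cfg$step)
        spec <- substitution_spectrum(aln)
        hv <- call_hypervariable(prof, threshold = cfg$pi_threshold,
                                 aln = aln, ann = canon[[id1]])
        key <- paste0(id1, "__", id2)
        .write_tsv(prof, file.path(cfg$outdir, paste0("pi_", key, ".tsv")))
        .write_tsv(data.frame(type = names(spec$counts), count = spec$counts),
                   file.path(cfg$outdir, paste0("spectrum_", key, ".tsv")))
        if (nrow(canon[[id1]]$features)) {
          .write_tsv(per_gene_divergence(aln, canon[[id1]]),
                     file.path(cfg$outdir, paste0("genescan_", key, ".tsv")))
        }
        aligned[[key]] <- aln
        list(id1 = id1, id2 = id2, mean_pi = mean(prof$pi, na.rm = TRUE),
             n_substitutions = spec$total, ts = spec$ts, tv = spec$tv,
             hypervariable = hv)
      }, error = function(e) list(id1 = id1, id2 = id2,
                                  error = conditionMessage(e)))
      pairs[[paste0(id1, "__", id2)]] <- res
    }
    # distance matrix from the pairwise alignments (pairwise-deletion style)
    n <- length(usable)
    Dm <- matrix(0, n, n, dimnames = list(usable, usable))
    ok_all <- TRUE
    for (t in seq_len(ncol(pr))) {
      key <- paste0(pr[1, t], "__", pr[2, t])
      if (is.null(aligned[[key]])) { ok_all <- FALSE; next }
      dmat <- pairwise_distance(aligned[[key]], model = cfg$model,
                                deletion = cfg$deletion)
      Dm[pr[1, t], pr[2, t]] <- Dm[pr[2, t], pr[1, t]] <- dmat$d[1, 2]
    }
    if (ok_all && !anyNA(Dm)) {
      D <- Dm
      .write_tsv(data.frame(id = rownames(D), D, check.names = FALSE),
                 file.path(cfg$outdir, "distances.tsv"))
      if (n >= 3) {
        tree <- nj_tree(D)
        write_newick(tree, file.path(cfg$outdir, "tree.nwk"))
      }
    }
  }

  if (all(structure_tab$status != "ok") && length(genomes)) {
    stop("no genome could be processed", call. = FALSE)
  }

  summary <- list(
    # config echo omits paths so reruns in different directories compare
    config = cfg[setdiff(names(cfg), c("genomes", "reference", "outdir"))],
    package_version = as.character(utils::packageVersion("plastome")),
    genomes = structure_tab,
    ssr_totals = if (!is.null(ssr_tab)) {
      as.list(table(ssr_tab$genome_id))
    } else NULL,
    orientation_totals = if (!is.null(survey)) {
      as.list(attr(survey, "totals"))
    } else NULL,
    pairs = lapply(pairs, function(x) x[setdiff(names(x), "hypervariable")]),
    tree_newick = if (!is.null(tree)) ape::write.tree(tree) else NULL)
  summary_path <- file.path(cfg$outdir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(list(structure = structure_tab, ssr = ssr_tab, repeats = rep_tab,
                 survey = survey, pairs = pairs, distance = D, tree = tree,
                 summary_path = summary_path))
}
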