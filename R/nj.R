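# Neighbor-joining tree construction and Newick input/output.

#' Build a neighbor-joining tree
#'
#' Standard NJ agglomeration on the Q-criterion with a deterministic
#' tie-break (the lexicographically lowest active index pair). Negative
#' intermediate branch lengths are clamped to zero with the deficit
#' transferred to the sibling edge, so path lengths between the joined
#' nodes are preserved. Returns an unrooted `phylo` tree (trifurcating at
#' the last join). On an additive matrix NJ recovers the generating tree
#' exactly.
#'
#' @param dm A [pairwise_distance()] result or a symmetric numeric matrix
#'   with dimnames.
#' @return An [ape::read.tree()]-style `phylo` object.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "distance_matrix")) {
    if (!dm$usable) stop("distance matrix has undefined entries; ",
                         "cannot build NJ tree", call. = FALSE)
    D <- dm$d; ids <- dm$ids
  } else {
    stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
    D <- dm; ids <- rownames(dm)
    if (is.null(ids)) ids <- paste0("t", seq_len(nrow(dm)))
  }
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (any(!is.finite(D))) stop("missing distances", call. = FALSE)

  frag <- paste0("t", seq_len(n))  # safe tokens; real labels restored below
  fmt <- function(x) sprintf("%.10g", x)
  active <- seq_len(n)
  m <- n
  while (m > 3L) {
    rs <- rowSums(D)
    Q <- (m - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    hits <- which(Q <= qmin + abs(qmin) * 1e-12, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    li <- 0.5 * D[i, j] + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- max(0, lj + li); li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- matrix(0, m - 1L, m - 1L)
    D2[seq_len(m - 2L), seq_len(m - 2L)] <- D[keep, keep]
    D2[m - 1L, seq_len(m - 2L)] <- dk[keep]
    D2[seq_len(m - 2L), m - 1L] <- dk[keep]
    D <- D2
    frag <- c(frag[keep], newfrag)
    m <- m - 1L
  }
  la <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(la),
                 frag[2], fmt(lb), frag[3], fmt(lc))
  tree <- ape::read.tree(text = nwk)
  tree$tip.label <- ids[as.integer(sub("^t", "", tree$tip.label))]
  tree
}

#' Total branch length of a tree
#' @param t A `phylo` tree.
#' @return Sum of all branch lengths (substitutions/site).
#' @export
total_branch_length <- function(t) {
  stopifnot(inherits(t, "phylo"))
  sum(t$edge.length)
}

.needs_quote <- function(lab) grepl("[^A-Za-z0-9_.|/+-]", lab)

#' Write a tree in Newick format
#'
#' Branch lengths are written to 10 significant digits; labels containing
#' spaces or other special characters are single-quoted (with internal
#' quotes doubled, per the Newick convention).
#'
#' @param t A `phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(t, path) {
  stopifnot(inherits(t, "phylo"))
  writeLines(.phylo_to_newick(t), path)
  invisible(path)
}

.phylo_to_newick <- function(t, digits = 10) {
  children <- split(seq_len(nrow(t$edge)), t$edge[, 1])
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  lab <- function(l) {
    if (.needs_quote(l)) paste0("'", gsub("'", "''", l), "'") else l
  }
  rec <- function(node) {
    kids <- children[[as.character(node)]]
    if (is.null(kids)) return(lab(t$tip.label[node]))
    paste0("(", paste(vapply(kids, function(e) {
      paste0(rec(t$edge[e, 2]),
             if (!is.null(t$edge.length)) paste0(":", fmt(t$edge.length[e])))
    }, character(1)), collapse = ","), ")")
  }
  paste0(rec(length(t$tip.label) + 1L), ";")
}

#' Read a tree from a Newick file
#'
#' @param path Path to a Newick file. Single-quoted labels are supported.
#' @return A `phylo` tree.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(trimws(txt))) stop("empty Newick file: ", path, call. = FALSE)
  .check_newick_balance(txt)
  # shelter quoted labels from the parser
  qpat <- "'((?:[^']|'')*)'"
  m <- gregexpr(qpat, txt)
  labels <- regmatches(txt, m)[[1]]
  tokens <- character(0)
  if (length(labels)) {
    tokens <- sprintf("PLQLBL%dX", seq_along(labels))
    regmatches(txt, m) <- list(tokens)
  }
  tree <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree)) stop("malformed Newick in ", path, call. = FALSE)
  if (length(labels)) {
    raw <- gsub("''", "'", gsub("^'|'$", "", labels))
    hit <- match(tree$tip.label, tokens)
    tree$tip.label[!is.na(hit)] <- raw[hit[!is.na(hit)]]
  }
  tree
}

.check_newick_balance <- function(txt) {
  ch <- .chars(txt)
  depth <- 0L; inq <- FALSE
  for (i in seq_along(ch)) {
    if (ch[i] == "'") inq <- !inq
    if (inq) next
    if (ch[i] == "(") depth <- depth + 1L
    if (ch[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("malformed Newick: unbalanced ')' at position ", i,
                           call. = FALSE)
    }
  }
  if (depth != 0L) stop("malformed Newick: ", depth,
                        " unclosed '(' at end of input", call. = FALSE)
  invisible(TRUE)
}
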