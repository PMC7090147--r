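# Repeat scanning: perfect microsatellites (SSRs, motifs of 1-6 nt) and
# long exact direct/inverted repeat pairs.

# lexicographically least among all rotations of the motif and of its
# reverse complement
.canonical_motif <- function(m) {
  ch <- .chars(m); n <- length(ch)
  rots <- function(v) vapply(0:(n - 1L), function(i) {
    .collapse(v[((seq_len(n) - 1L + i) %% n) + 1L])
  }, character(1))
  min(c(rots(ch), rots(.chars(revcomp(m)))))
}

# TRUE when the motif is not a repetition of a shorter motif
.is_primitive <- function(m) {
  n <- nchar(m)
  for (p in seq_len(n - 1L)) {
    if (n %% p == 0L && strrep(substr(m, 1, p), n %/% p) == m) return(FALSE)
  }
  TRUE
}

#' Scan for perfect microsatellite tracts (SSRs)
#'
#' Finds all maximal perfect tandem repeats of primitive motifs of 1-6 nt
#' whose tract (whole copies only; a trailing partial copy is not counted)
#' reaches `min_tract` bases. A tract whose motif is a repetition of a
#' shorter motif is reported only under the shortest motif (a poly-A run is
#' mono, never di-"AA"). On circular sequences tracts spanning the origin
#' are detected. Homopolymer runs of N are never SSRs.
#'
#' @param s A [circular_sequence()] or [annotated_genome()].
#' @param min_tract Minimum tract length in bases; either a scalar applied
#'   to every motif class, or a length-6 vector of per-class thresholds
#'   (mono..hexa) for MISA-style settings.
#' @return A data.frame of class `ssr_loci`: `motif` (canonical: least among
#'   rotations and reverse-complement rotations), `motif_len`, `copies`,
#'   `start` (0-based), `tract_len`. Empty when no tract qualifies.
#' @export
find_ssrs <- function(s, min_tract = 10) {
  S <- .as_seq_string(s)
  L <- nchar(S)
  circ <- .is_circular(s)
  mt <- if (length(min_tract) == 1L) rep(min_tract, 6L) else {
    stopifnot(length(min_tract) == 6L); min_tract
  }
  T2 <- if (circ) paste0(S, S) else S
  d <- .chars(T2); n <- length(d)
  motif <- character(); mlen <- integer(); copies <- integer()
  start0 <- integer(); tract <- integer()
  for (m in 1:6) {
    if (n <= m) next
    eq <- d[seq_len(n - m)] == d[seq_len(n - m) + m]
    r <- rle(eq)
    need_rl <- max(mt[m], 2L * m) - m
    ends <- cumsum(r$lengths)
    sel <- which(r$values & r$lengths >= need_rl)
    for (si in sel) {
      st <- ends[si] - r$lengths[si] + 1L      # 1-based in T2
      if (circ && (st < 2L || st > L + 1L)) next
      cp <- (r$lengths[si] + m) %/% m
      tl <- cp * m
      if (cp < 2L || tl < mt[m]) next
      if (circ && tl > L) next
      mo <- substr(T2, st, st + m - 1L)
      if (grepl("[^ACGT]", mo)) next
      if (!.is_primitive(mo)) next
      motif <- c(motif, .canonical_motif(mo)); mlen <- c(mlen, m)
      copies <- c(copies, cp); start0 <- c(start0, (st - 1L) %% L)
      tract <- c(tract, tl)
    }
  }
  out <- data.frame(motif = motif, motif_len = mlen, copies = copies,
                    start = start0, tract_len = tract,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$motif_len), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ssr_loci", "data.frame")
  out
}

#' Summarize SSR loci per motif class
#'
#' @param loci Output of [find_ssrs()].
#' @return A list of class `ssr_summary`: `counts` (named mono..hexa),
#'   `total`, `frequency` (percent per class, 2 decimals; zeros when the
#'   input is empty).
#' @export
summarize_ssrs <- function(loci) {
  counts <- tabulate(loci$motif_len, nbins = 6L)
  names(counts) <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  total <- sum(counts)
  freq <- if (total > 0) round(100 * counts / total, 2) else {
    stats::setNames(rep(0, 6L), names(counts))
  }
  structure(list(counts = counts, total = total, frequency = freq),
            class = "ssr_summary")
}

#' @export
print.ssr_summary <- function(x, ...) {
  cat(sprintf("SSR summary: %d loci\n", x$total))
  print(rbind(count = x$counts, `freq%` = x$frequency))
  invisible(x)
}

#' Find long exact direct and inverted repeat pairs
#'
#' Reports all maximal exact repeat pairs of at least `min_len` bases
#' (REPuter-style, exact matches only). Self-overlapping pairs are excluded,
#' and the genome-scale IR pair itself is excluded when supplied. Output is
#' sorted by length (descending), then by first position.
#'
#' @param s A [circular_sequence()] or [annotated_genome()].
#' @param min_len Minimum repeat length (default 30).
#' @param ir_exclude Optional `ir_pair`: matches lying on the diagonal of
#'   the genome-scale inverted repeat are dropped.
#' @return A data.frame of class `repeat_pairs`: `kind`
#'   (`direct`/`inverted`), `start1`, `start2` (0-based, `start1 < start2`),
#'   `length`.
#' @export
find_long_repeats <- function(s, min_len = 30, ir_exclude = NULL) {
  S <- .as_seq_string(s)
  L <- nchar(S)
  circ <- .is_circular(s)
  k <- as.integer(min_len)
  empty <- data.frame(kind = character(), start1 = integer(),
                      start2 = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  if (L <= k) { class(empty) <- c("repeat_pairs", "data.frame"); return(empty) }
  T2 <- if (circ) paste0(S, S) else S
  nT <- nchar(T2)
  starts <- 0:(nT - k)
  km <- substring(T2, starts + 1L, starts + k)

  # direct repeats: duplicated k-mers among forward starts
  u <- unique(km)
  code <- match(km, u)
  df <- data.frame(code = code, pos = starts)
  mm <- merge(df, df, by = "code")
  mm <- mm[mm$pos.y > mm$pos.x, , drop = FALSE]
  if (circ) mm <- mm[((mm$pos.y - mm$pos.x) %% L) != 0L, , drop = FALSE]
  dir_runs <- .pair_runs(mm$pos.x, mm$pos.y, k)
  empty_cand <- data.frame(kind = character(), a1 = integer(),
                           a2 = integer(), length = integer(),
                           stringsAsFactors = FALSE)
  dir <- if (nrow(dir_runs)) {
    data.frame(kind = "direct", a1 = dir_runs$i0 %% L, a2 = dir_runs$j0 %% L,
               length = dir_runs$len, stringsAsFactors = FALSE)
  } else empty_cand

  # inverted repeats: forward k-mers vs reverse-complement k-mers
  RC2 <- if (circ) paste0(revcomp(S), revcomp(S)) else revcomp(S)
  rk <- substring(RC2, starts + 1L, starts + k)
  u2 <- unique(c(km, rk))
  fi <- match(km, u2); ri <- match(rk, u2)
  tf <- tabulate(fi, nbins = length(u2)); tr <- tabulate(ri, nbins = length(u2))
  ok <- tf > 0L & tr > 0L
  f_df <- data.frame(code = fi[ok[fi]], pos = starts[ok[fi]])
  r_df <- data.frame(code = ri[ok[ri]], pos = starts[ok[ri]])
  im <- merge(f_df, r_df, by = "code")
  inv_runs <- .pair_runs(im$pos.x, im$pos.y, k)
  inv <- if (nrow(inv_runs)) {
    data.frame(kind = "inverted", a1 = inv_runs$i0 %% L,
               a2 = (L - 1L - ((inv_runs$j0 + inv_runs$len - 1L) %% L)) %% L,
               length = inv_runs$len, stringsAsFactors = FALSE)
  } else empty_cand

  out <- rbind(dir, inv)
  if (!nrow(out)) { class(empty) <- c("repeat_pairs", "data.frame"); return(empty) }

  # drop self-overlapping pairs; canonical order; dedupe circular copies
  keep <- logical(nrow(out))
  for (t in seq_len(nrow(out))) {
    iv1 <- c(start = out$a1[t], len = out$length[t])
    iv2 <- c(start = out$a2[t], len = out$length[t])
    if (out$length[t] > L) next
    if (out$a1[t] == out$a2[t]) next
    if (.intervals_overlap(iv1, iv2, L)) next
    keep[t] <- TRUE
  }
  out <- out[keep, , drop = FALSE]
  if (nrow(out)) {
    s1 <- pmin(out$a1, out$a2); s2 <- pmax(out$a1, out$a2)
    out <- data.frame(kind = out$kind, start1 = s1, start2 = s2,
                      length = out$length, stringsAsFactors = FALSE)
    out <- unique(out)
    if (!is.null(ir_exclude) && ir_exclude$found) {
      out <- out[!.on_ir_diagonal(out, ir_exclude, L), , drop = FALSE]
    }
    out <- out[order(-out$length, out$start1, out$start2), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- empty
  }
  class(out) <- c("repeat_pairs", "data.frame")
  out
}

# collapse matched position pairs into maximal collinear runs; for direct
# repeats collinearity is pos.y - pos.x constant, for inverted matches the
# rc-side coordinate also advances by +1 per base, so the same grouping works
.pair_runs <- function(px, py, k) {
  if (!length(px)) {
    return(data.frame(i0 = integer(), j0 = integer(), len = integer()))
  }
  dg <- py - px
  ord <- order(dg, px)
  dgo <- dg[ord]; pxo <- px[ord]; pyo <- py[ord]
  newrun <- c(TRUE, diff(pxo) != 1L | diff(dgo) != 0L)
  runid <- cumsum(newrun)
  rl <- tabulate(runid)
  data.frame(i0 = pxo[newrun], j0 = pyo[newrun], len = rl + k - 1L)
}

# TRUE for inverted pairs that are fragments of the genome-scale IR match
.on_ir_diagonal <- function(out, ir, L) {
  ia <- ir$ira; ib <- ir$irb
  vapply(seq_len(nrow(out)), function(t) {
    if (out$kind[t] != "inverted") return(FALSE)
    for (arms in list(c(out$start1[t], out$start2[t]),
                      c(out$start2[t], out$start1[t]))) {
      sp1 <- c(start = arms[1], len = out$length[t])
      sp2 <- c(start = arms[2], len = out$length[t])
      if (.interval_contains(ia, sp1, L) && .interval_contains(ib, sp2, L)) {
        off <- (arms[1] - ia[["start"]]) %% L
        expected <- (ib[["start"]] + ib[["len"]] - off - out$length[t]) %% L
        dd <- min((arms[2] - expected) %% L, (expected - arms[2]) %% L)
        if (dd <= 2) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
}
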