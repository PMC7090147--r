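# Independent brute-force oracles and small fixture builders. These are
# deliberately naive (dynamic programming over all cells, per-position motif
# walks) and share no code with the package's seed-and-extend scanners.

o_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
o_collapse <- function(v) paste(v, collapse = "")
o_revcomp <- function(s) o_collapse(rev(o_chars(chartr("ACGTN", "TGCAN", s))))

rand_dna <- function(n, gc = 0.5) {
  o_collapse(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)))
}

# All maximal exact match runs of length >= min_len between char vectors x
# and y, by row-vectorized longest-common-suffix DP. Returns 1-based run
# ends and lengths. With self_direct = TRUE only cells j > i are kept
# (direct self-comparison).
oracle_match_runs <- function(x, y, min_len, self_direct = FALSE) {
  n <- length(x); m <- length(y)
  prev <- integer(m)
  out_i <- integer(); out_j <- integer(); out_len <- integer()
  for (i in seq_len(n)) {
    hit <- y == x[i]
    cur <- integer(m)
    cur[hit] <- c(0L, prev[-m])[hit] + 1L
    if (self_direct) cur[seq_len(min(i, m))] <- 0L
    ended <- which(prev >= min_len & c(cur[-1], 0L) == 0L)
    if (length(ended)) {
      out_i <- c(out_i, rep(i - 1L, length(ended)))
      out_j <- c(out_j, ended); out_len <- c(out_len, prev[ended])
    }
    prev <- cur
  }
  ended <- which(prev >= min_len)
  if (length(ended)) {
    out_i <- c(out_i, rep(n, length(ended)))
    out_j <- c(out_j, ended); out_len <- c(out_len, prev[ended])
  }
  data.frame(end_i = out_i, end_j = out_j, len = out_len)
}

# longest inverted-repeat pair of a linear sequence (disjoint arms),
# returning length and all (start1, start2) 0-based achieving it
oracle_longest_inverted <- function(S, min_len = 10) {
  x <- o_chars(S); y <- o_chars(o_revcomp(S))
  n <- length(x)
  runs <- oracle_match_runs(x, y, min_len)
  if (!nrow(runs)) return(list(length = 0L, arms = NULL))
  s1 <- runs$end_i - runs$len + 1L           # 1-based arm1 start
  s2 <- n + 1L - runs$end_j                  # 1-based arm2 start
  keep <- rep(TRUE, nrow(runs))
  for (t in seq_len(nrow(runs))) {           # disjoint arms only
    a <- sort(c(s1[t], s2[t]))
    if (a[1] + runs$len[t] - 1L >= a[2]) keep[t] <- FALSE
  }
  runs <- runs[keep, , drop = FALSE]; s1 <- s1[keep]; s2 <- s2[keep]
  if (!nrow(runs)) return(list(length = 0L, arms = NULL))
  best <- max(runs$len)
  sel <- runs$len == best
  arms <- unique(data.frame(start1 = pmin(s1[sel], s2[sel]) - 1L,
                            start2 = pmax(s1[sel], s2[sel]) - 1L))
  list(length = best, arms = arms[order(arms$start1), , drop = FALSE])
}

# all maximal exact repeat pairs >= min_len of a linear sequence,
# direct and inverted, 0-based starts, non-overlapping arms
oracle_long_repeats <- function(S, min_len = 30) {
  x <- o_chars(S); n <- length(x)
  dir <- oracle_match_runs(x, x, min_len, self_direct = TRUE)
  rows <- list()
  if (nrow(dir)) {
    rows[[1]] <- data.frame(kind = "direct",
                            start1 = dir$end_i - dir$len,
                            start2 = dir$end_j - dir$len,
                            length = dir$len, stringsAsFactors = FALSE)
  }
  inv <- oracle_match_runs(x, o_chars(o_revcomp(S)), min_len)
  if (nrow(inv)) {
    s1 <- inv$end_i - inv$len; s2 <- n - inv$end_j
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "inverted", start1 = pmin(s1, s2), start2 = pmax(s1, s2),
      length = inv$len, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(kind = character(), start1 = integer(),
                      start2 = integer(), length = integer()))
  }
  out <- unique(do.call(rbind, rows))
  keep <- (out$start1 + out$length) <= out$start2   # disjoint arms
  out <- out[keep, , drop = FALSE]
  out <- out[order(-out$length, out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-position, per-motif-length SSR walk over a linear sequence;
# 0-based starts, canonical motifs via the package's rule recomputed here
oracle_canonical_motif <- function(m) {
  ch <- o_chars(m); n <- length(ch)
  rots <- function(v) vapply(0:(n - 1L), function(i) {
    o_collapse(v[((seq_len(n) - 1L + i) %% n) + 1L])
  }, character(1))
  min(c(rots(ch), rots(o_chars(o_revcomp(m)))))
}

oracle_find_ssrs <- function(S, min_tract = 10) {
  mt <- if (length(min_tract) == 1L) rep(min_tract, 6L) else min_tract
  d <- o_chars(S); n <- length(d)
  res <- list()
  for (start in seq_len(n)) {
    for (m in 1:6) {
      if (start + 2L * m - 1L > n) next
      motif <- substr(S, start, start + m - 1L)
      if (grepl("[^ACGT]", motif)) next
      # left-anchored: the period must break just before `start`
      if (start > 1L && start - 1L + m <= n &&
          d[start - 1L] == d[start - 1L + m]) next
      cp <- 1L
      while (start + (cp + 1L) * m - 1L <= n &&
             substr(S, start + cp * m, start + (cp + 1L) * m - 1L) == motif) {
        cp <- cp + 1L
      }
      if (cp < 2L || cp * m < mt[m]) next
      prim <- TRUE
      for (p in seq_len(m - 1L)) {
        if (m %% p == 0L && strrep(substr(motif, 1, p), m %/% p) == motif) {
          prim <- FALSE; break
        }
      }
      if (!prim) next
      res[[length(res) + 1L]] <- data.frame(
        motif = oracle_canonical_motif(motif), motif_len = m, copies = cp,
        start = start - 1L, tract_len = cp * m, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(motif = character(), motif_len = integer(),
                      copies = integer(), start = integer(),
                      tract_len = integer()))
  }
  out <- do.call(rbind, res)
  out[order(out$start, out$motif_len), , drop = FALSE]
}

# per-window recount of pairwise diversity (2-row alignments)
oracle_window_pi <- function(row1, row2, window, step) {
  a <- o_chars(row1); b <- o_chars(row2)
  n <- length(a)
  starts <- seq(1L, n - window + 1L, by = step)
  vapply(starts, function(s0) {
    idx <- s0:(s0 + window - 1L)
    ok <- a[idx] %in% c("A", "C", "G", "T") & b[idx] %in% c("A", "C", "G", "T")
    if (!any(ok)) return(NA_real_)
    sum(a[idx][ok] != b[idx][ok]) / sum(ok)
  }, numeric(1))
}

# least-squares branch-length fit of every unrooted topology; returns the
# best-fitting tree (requires phangorn for topology enumeration). The
# topology set and path-incidence design matrices depend only on the taxon
# labels, so they are memoized across calls.
.ls_cache <- new.env(parent = emptyenv())

.ls_designs <- function(ids) {
  key <- paste(ids, collapse = "|")
  if (!is.null(.ls_cache[[key]])) return(.ls_cache[[key]])
  tops <- phangorn::allTrees(length(ids), rooted = FALSE, tip.label = ids)
  prs <- utils::combn(length(ids), 2)
  designs <- lapply(seq_along(tops), function(k) {
    tp <- tops[[k]]   # [[ ]] dispatch restores tip labels (multiPhylo)
    A <- matrix(0, ncol(prs), nrow(tp$edge))
    for (t in seq_len(ncol(prs))) {
      pth <- ape::nodepath(tp, prs[1, t], prs[2, t])
      for (s in seq_len(length(pth) - 1L)) {
        e <- which((tp$edge[, 1] == pth[s] & tp$edge[, 2] == pth[s + 1]) |
                     (tp$edge[, 2] == pth[s] & tp$edge[, 1] == pth[s + 1]))
        A[t, e] <- 1
      }
    }
    list(tree = tp, qr = qr(A), A = A)
  })
  out <- list(designs = designs, prs = prs)
  .ls_cache[[key]] <- out
  out
}

oracle_ls_best_tree <- function(D) {
  ids <- rownames(D)
  dz <- .ls_designs(ids)
  dv <- D[cbind(dz$prs[1, ], dz$prs[2, ])]
  best <- NULL; best_rss <- Inf
  for (dg in dz$designs) {
    cf <- qr.coef(dg$qr, dv)
    rss <- sum((dg$A %*% cf - dv)^2)
    if (rss < best_rss - 1e-10) {
      best_rss <- rss
      best <- dg$tree; best$edge.length <- as.numeric(cf)
    }
  }
  best
}

# plant an exact inverted-repeat pair of the given arm length in a random
# linear sequence; guard bases keep the planted arms exactly maximal
plant_ir_fixture <- function(L, arm_len, seed) {
  set.seed(seed)
  bg <- o_chars(rand_dna(L))
  arm <- rand_dna(arm_len)
  gap <- max(50L, L %/% 6L)
  p1 <- sample(10:(L - 2L * arm_len - gap - 10L), 1)
  p2 <- p1 + arm_len + sample(gap:(L - p1 - 2L * arm_len - 5L), 1)
  a1 <- o_chars(arm); a2 <- o_chars(o_revcomp(arm))
  bg[(p1 + 1):(p1 + arm_len)] <- a1
  bg[(p2 + 1):(p2 + arm_len)] <- a2
  # break single-base extensions at all four arm ends
  comp <- function(b) chartr("ACGT", "TGCA", b)
  if (bg[p1] == comp(bg[p2 + arm_len + 1])) {
    bg[p1] <- setdiff(c("A", "C", "G", "T"),
                      c(bg[p1], comp(bg[p2 + arm_len + 1])))[1]
  }
  if (bg[p1 + arm_len + 1] == comp(bg[p2])) {
    bg[p2] <- setdiff(c("A", "C", "G", "T"),
                      c(bg[p2], comp(bg[p1 + arm_len + 1])))[1]
  }
  list(seq = o_collapse(bg), start1 = p1, start2 = p2, arm_len = arm_len)
}
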