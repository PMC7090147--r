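# Pairwise evolutionary distances from a (multiple) alignment.

#' Pairwise evolutionary distances
#'
#' Computes a symmetric distance matrix under one of four models:
#' \describe{
#'   \item{p}{raw proportion of differing usable sites.}
#'   \item{jc69}{Jukes-Cantor: \eqn{-3/4 \log(1 - 4p/3)}.}
#'   \item{k2p}{Kimura two-parameter from the transition proportion P and
#'     transversion proportion Q: \eqn{-\log(1-2P-Q)/2 - \log(1-2Q)/4}.}
#'   \item{mcl}{composite-likelihood style Tamura-Nei distance: base
#'     frequencies are pooled across all sequences (parameters shared by
#'     every pair), with per-pair purine-transition, pyrimidine-transition
#'     and transversion proportions.}
#' }
#' `deletion = "pairwise"` removes gap/ambiguous columns independently for
#' each pair; `"complete"` removes them across all rows and reports the
#' common usable-site count.
#'
#' @param aln A [seq_alignment()] (2 or more rows).
#' @param model Distance model (default `"k2p"`).
#' @param deletion Gap/ambiguity handling (default `"pairwise"`).
#' @return Object of class `distance_matrix`: `ids`, `d` (matrix,
#'   substitutions/site), `positions_used` (per-pair matrix, or a scalar for
#'   complete deletion), `model`, `deletion`, `usable` (FALSE when any
#'   distance was undefined, e.g. log of a non-positive number; such entries
#'   are `NA` and the matrix is not usable for NJ).
#' @export
pairwise_distance <- function(aln,
                              model = c("k2p", "p", "jc69", "mcl"),
                              deletion = c("pairwise", "complete")) {
  stopifnot(inherits(aln, "seq_alignment"))
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  M <- as.matrix(aln)
  r <- nrow(M)
  ok <- M %in% .ACGT; dim(ok) <- dim(M)
  all_ok <- colSums(ok) == r
  pooled_n <- sum(all_ok)

  # pooled base frequencies for the composite (mcl) model
  freqs <- NULL
  if (model == "mcl") {
    use_cols <- if (deletion == "complete") all_ok else rep(TRUE, ncol(M))
    bases <- M[, use_cols, drop = FALSE]
    bases <- bases[bases %in% .ACGT]
    freqs <- table(factor(bases, levels = .ACGT)) / length(bases)
    freqs <- as.numeric(freqs); names(freqs) <- .ACGT
  }

  D <- matrix(0, r, r, dimnames = list(aln$ids, aln$ids))
  P_used <- matrix(NA_real_, r, r, dimnames = list(aln$ids, aln$ids))
  notes <- character()
  for (i in seq_len(r - 1L)) {
    for (j in seq(i + 1L, r)) {
      mask <- if (deletion == "complete") all_ok else ok[i, ] & ok[j, ]
      n <- sum(mask)
      P_used[i, j] <- P_used[j, i] <- n
      if (n == 0L) {
        D[i, j] <- D[j, i] <- NA_real_
        notes <- c(notes, sprintf("%s/%s: no usable sites",
                                  aln$ids[i], aln$ids[j]))
        next
      }
      x <- M[i, mask]; y <- M[j, mask]
      diff <- x != y
      p_mm <- mean(diff)
      ts_ag <- (x == "A" & y == "G") | (x == "G" & y == "A")
      ts_ct <- (x == "C" & y == "T") | (x == "T" & y == "C")
      P1 <- mean(ts_ag); P2 <- mean(ts_ct)
      P <- P1 + P2; Q <- p_mm - P
      d <- switch(model,
        p = p_mm,
        jc69 = {
          arg <- 1 - 4 * p_mm / 3
          if (arg <= 0) NA_real_ else -0.75 * log(arg)
        },
        k2p = {
          a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
          if (a1 <= 0 || a2 <= 0) NA_real_ else {
            -0.5 * log(a1) - 0.25 * log(a2)
          }
        },
        mcl = .tn93_distance(P1, P2, Q, freqs))
      if (is.na(d)) {
        notes <- c(notes, sprintf("%s/%s: %s distance undefined (saturation)",
                                  aln$ids[i], aln$ids[j], model))
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  if (deletion == "complete") P_used <- pooled_n
  structure(list(ids = aln$ids, d = D, positions_used = P_used,
                 model = model, deletion = deletion,
                 usable = !anyNA(D), notes = notes),
            class = "distance_matrix")
}

# Tamura-Nei distance with supplied (pooled) base frequencies
.tn93_distance <- function(P1, P2, Q, f) {
  pR <- f[["A"]] + f[["G"]]; pY <- f[["C"]] + f[["T"]]
  if (pR <= 0 || pY <= 0 || f[["A"]] * f[["G"]] == 0 ||
      f[["C"]] * f[["T"]] == 0) {
    return(NA_real_)
  }
  k1 <- 2 * f[["A"]] * f[["G"]] / pR
  k2 <- 2 * f[["C"]] * f[["T"]] / pY
  k3 <- 2 * (pR * pY - f[["A"]] * f[["G"]] * pY / pR -
               f[["C"]] * f[["T"]] * pR / pY)
  w1 <- 1 - P1 / k1 - Q / (2 * pR)
  w2 <- 1 - P2 / k2 - Q / (2 * pY)
  w3 <- 1 - Q / (2 * pR * pY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(NA_real_)
  -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d taxa, model %s, %s deletion%s\n",
              length(x$ids), x$model, x$deletion,
              if (x$usable) "" else " [NOT usable: undefined entries]"))
  print(round(x$d, 6))
  invisible(x)
}
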