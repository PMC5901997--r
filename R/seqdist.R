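#' Pairwise p-distance with pairwise deletion
#'
#' Proportion of mismatching sites among the effective sites of a pair: the
#' aligned positions where both characters are plain bases (`A C G T`).
#' Positions with a gap or `N` in either sequence are ignored for that pair
#' only (pairwise deletion).
#'
#' @param a,b equal-length aligned sequences (character strings).
#' @return mismatch proportion in \[0,1\]; `NA` when the pair shares no
#'   effective site.
#' @export
p_distance <- function(a, b) {
  x <- strsplit(toupper(a), "")[[1L]]
  y <- strsplit(toupper(b), "")[[1L]]
  if (length(x) != length(y)) stop("sequences must have equal aligned length")
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  if (!any(ok)) return(NA_real_)
  sum(x[ok] != y[ok]) / sum(ok)
}

# per-pair substitution-class proportions over effective sites
pair_class_counts <- function(x, y) {
  base <- c("A", "C", "G", "T")
  ok <- x %in% base & y %in% base
  n <- sum(ok)
  if (n == 0L)
    return(c(n = 0, p1 = NA_real_, p2 = NA_real_, q = NA_real_))
  x <- x[ok]; y <- y[ok]
  diff <- x != y
  ag <- diff & ((x == "A" & y == "G") | (x == "G" & y == "A"))
  ct <- diff & ((x == "C" & y == "T") | (x == "T" & y == "C"))
  q <- diff & !ag & !ct
  c(n = n, p1 = sum(ag) / n, p2 = sum(ct) / n, q = sum(q) / n)
}

tn93_pair <- function(p1, p2, q, freqs) {
  piA <- freqs["A"]; piC <- freqs["C"]; piG <- freqs["G"]; piT <- freqs["T"]
  piR <- piA + piG; piY <- piC + piT
  k1 <- 2 * piA * piG / piR
  k2 <- 2 * piC * piT / piY
  k3 <- 2 * (piR * piY - piA * piG * piY / piR - piC * piT * piR / piY)
  w1 <- 1 - piR * p1 / (2 * piA * piG) - q / (2 * piR)
  w2 <- 1 - piY * p2 / (2 * piC * piT) - q / (2 * piY)
  w3 <- 1 - q / (2 * piR * piY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(NA_real_)  # saturated
  unname(-k1 * log(w1) - k2 * log(w2) - k3 * log(w3))
}

#' Genetic distances under the composite-frequency Tamura-Nei model
#'
#' Number of base substitutions per site between every sequence pair,
#' estimated with the Tamura-Nei (TN93) formula in which base frequencies
#' are pooled over ALL sequences in the collection — the composite element
#' of "maximum composite likelihood" distances as popularized by MEGA. With
#' `pooled = FALSE` frequencies are instead estimated per pair. Sites with a
#' gap or `N` in either member of a pair are excluded for that pair
#' (pairwise deletion). Pairs whose correction logarithms have non-positive
#' arguments are saturated and reported as `NA`.
#'
#' @param seqs a [sequence_collection()] of equal-length aligned sequences
#'   (at least 2).
#' @param pooled pool base frequencies across the whole alignment
#'   (default) or estimate per pair.
#' @return a [distance_matrix()] in substitutions/site.
#' @export
mcl_distance <- function(seqs, pooled = TRUE) {
  stopifnot(inherits(seqs, "sequence_collection"))
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  m <- seq_matrix(seqs)
  n <- nrow(m)
  base <- c("A", "C", "G", "T")
  if (pooled) {
    counts <- table(factor(m[m %in% base], levels = base))
    if (any(counts == 0))
      stop("pooled frequencies require every base to occur in the alignment")
    freqs <- as.numeric(counts) / sum(counts)
    names(freqs) <- base
  }
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    cc <- pair_class_counts(m[i, ], m[j, ])
    if (cc["n"] == 0) { d[i, j] <- d[j, i] <- NA_real_; next }
    fr <- if (pooled) freqs else {
      pc <- table(factor(c(m[i, ], m[j, ])[c(m[i, ], m[j, ]) %in% base],
                         levels = base))
      f <- as.numeric(pc) / sum(pc); names(f) <- base
      if (any(f == 0)) freqs_fallback(m) else f
    }
    d[i, j] <- d[j, i] <- tn93_pair(cc["p1"], cc["p2"], cc["q"], fr)
  }
  distance_matrix(d, names(seqs))
}

freqs_fallback <- function(m) {
  base <- c("A", "C", "G", "T")
  counts <- table(factor(m[m %in% base], levels = base))
  f <- as.numeric(counts) / sum(counts)
  names(f) <- base
  f
}

#' Fraction of identical effective sites between two aligned sequences
#' @param a,b equal-length sequences.
#' @return identity in \[0,1\] (`1 - p_distance`); `NA` with no overlap.
#' @export
pairwise_identity <- function(a, b) {
  p <- p_distance(a, b)
  if (is.na(p)) NA_real_ else 1 - p
}
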