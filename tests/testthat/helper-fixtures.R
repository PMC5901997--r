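# shared fixtures and independent oracles

BASES <- c("A", "C", "G", "T")

# small labeled distance matrix from a lower-triangle vector
dm_from_lower <- function(v, labels) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- v
  m <- m + t(m)
  distance_matrix(m, labels)
}

random_count_table <- function(n_samples, n_taxa, seed, depth = 500L) {
  set.seed(seed)
  m <- t(sapply(seq_len(n_samples), function(i)
    as.numeric(stats::rmultinom(1L, depth,
                                prob = stats::rgamma(n_taxa, 1)))))
  abundance_table(m, paste0("s", seq_len(n_samples)),
                  paste0("t", seq_len(n_taxa)), mode = "count")
}

random_sequences <- function(n, len, seed, rate = 0.05,
                             comp = c(0.25, 0.25, 0.25, 0.25)) {
  set.seed(seed)
  root <- sample(BASES, len, TRUE, prob = comp)
  seqs <- vapply(seq_len(n), function(i)
    paste(mutate_chars(root, rate), collapse = ""), character(1L))
  names(seqs) <- sprintf("q%02d", seq_len(n))
  sequence_collection(seqs)
}

mutate_chars <- function(chars, rate) {
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
  chars
}

# independent adjusted Rand index (contingency-table formula)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# exhaustive k-medoids optimum: scan every medoid subset
exhaustive_pam_cost <- function(d, k) {
  subsets <- utils::combn(nrow(d), k)
  min(apply(subsets, 2L, function(med)
    sum(apply(d[, med, drop = FALSE], 1L, min))))
}

# independent TN93 evaluation, spreadsheet style, for one pair
tn93_oracle <- function(s1, s2, all_seqs) {
  cat1 <- strsplit(s1, "")[[1L]]; cat2 <- strsplit(s2, "")[[1L]]
  pool <- unlist(strsplit(all_seqs, ""))
  pool <- pool[pool %in% BASES]
  f <- table(factor(pool, levels = BASES)) / length(pool)
  piA <- f[["A"]]; piC <- f[["C"]]; piG <- f[["G"]]; piT <- f[["T"]]
  ok <- cat1 %in% BASES & cat2 %in% BASES
  x <- cat1[ok]; y <- cat2[ok]; n <- length(x)
  P1 <- sum((x == "A" & y == "G") | (x == "G" & y == "A")) / n
  P2 <- sum((x == "C" & y == "T") | (x == "T" & y == "C")) / n
  Q <- sum(x != y) / n - P1 - P2
  piR <- piA + piG; piY <- piC + piT
  w1 <- 1 - piR * P1 / (2 * piA * piG) - Q / (2 * piR)
  w2 <- 1 - piY * P2 / (2 * piC * piT) - Q / (2 * piY)
  w3 <- 1 - Q / (2 * piR * piY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(NA_real_)
  -(2 * piA * piG / piR) * log(w1) - (2 * piC * piT / piY) * log(w2) -
    2 * (piR * piY - piA * piG * piY / piR - piC * piT * piR / piY) * log(w3)
}

# enumeration of all permutations (independent of the package's generator)
perms_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms_of(n - 1L))
    for (i in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  out
}
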