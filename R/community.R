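#' Bray-Curtis dissimilarity between samples
#'
#' Computes `d(i,j) = sum|x_ik - x_jk| / sum(x_ik + x_jk)` on relative
#' abundances. Count-mode tables are normalized first, so the result is
#' invariant to rescaling any sample's counts by a positive constant.
#' Values lie in \[0,1\]; 1 means disjoint taxon support.
#'
#' @param t an [abundance_table()].
#' @return a [distance_matrix()] over samples.
#' @export
bray_curtis <- function(t) {
  stopifnot(inherits(t, "abundance_table"))
  if (table_mode(t) == "count") t <- to_relative_abundance(t)
  x <- unclass(t)
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d[i, j] <- d[j, i] <-
      sum(abs(x[i, ] - x[j, ])) / sum(x[i, ] + x[j, ])
  }
  distance_matrix(d, rownames(x))
}

# Kruskal stress-1 of configuration distances e against disparities dhat
stress1 <- function(e, dhat) sqrt(sum((e - dhat)^2) / sum(e^2))

# disparities: least-squares monotone (PAV) fit of e against the rank order
# of the input distances; Kruskal's primary tie approach (within tied d,
# order by e so ties are free to fit).
monotone_disparities <- function(dvec, e) {
  ord <- order(dvec, e)
  dhat <- numeric(length(e))
  dhat[ord] <- stats::isoreg(seq_along(ord), e[ord])$yf
  dhat
}

pair_dist <- function(x) {
  as.matrix(stats::dist(x))[lower.tri(diag(nrow(x)))]
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds a distance matrix in `k` dimensions by minimizing Kruskal's
#' stress-1 with monotone (isotonic) regression of configuration distances
#' on input-distance ranks. The first start is classical metric scaling;
#' remaining starts are seeded random configurations. Iterative refinement
#' uses the Guttman transform with step halving, so accepted steps never
#' increase stress.
#'
#' @param d a [distance_matrix()] (no undefined entries).
#' @param k embedding dimension.
#' @param n_restarts number of starts (first is classical scaling).
#' @param max_iter,tol iteration cap and stress-change convergence tolerance.
#' @param seed RNG seed for the random starts.
#' @return an object of class `nmds_ordination`: list with `coordinates`
#'   (centered, n x k), `stress`, `n_restarts_used`, `converged`, and
#'   `degenerate` (true when all off-diagonal distances are equal, which
#'   voids the stress contract).
#' @export
nmds <- function(d, k = 2L, n_restarts = 20L, max_iter = 300L, tol = 1e-7,
                 seed = 1L) {
  stopifnot(inherits(d, "distance_matrix"))
  n <- nrow(d)
  if (n < k + 1L) stop("need at least k + 1 samples")
  if (anyNA(d)) stop("undefined distances present")
  dvec <- unclass(d)[lower.tri(d)]
  degenerate <- max(dvec) - min(dvec) < 1e-12
  if (degenerate)
    warning("all distances equal: NMDS configuration is arbitrary")

  refine <- function(x) {
    x <- scale(x, scale = FALSE)
    e <- pair_dist(x)
    if (all(e < 1e-12)) x <- x + matrix(stats::rnorm(n * k, sd = 1e-4), n, k)
    e <- pair_dist(x)
    s <- stress1(e, monotone_disparities(dvec, e))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      dhat <- monotone_disparities(dvec, e)
      # Guttman transform toward the disparities
      ratio <- matrix(0, n, n)
      ratio[lower.tri(ratio)] <- ifelse(e > 1e-12, dhat / e, 1)
      ratio <- ratio + t(ratio)
      b <- -ratio
      diag(b) <- rowSums(ratio)
      x_new <- b %*% x / n
      # accept only stress-decreasing steps (halve toward x if needed)
      for (h in 0:10) {
        e_new <- pair_dist(x_new)
        s_new <- stress1(e_new, monotone_disparities(dvec, e_new))
        if (s_new <= s || s < 1e-12) break
        x_new <- (x_new + x) / 2
      }
      if (s_new > s) { converged <- TRUE; break }
      improved <- s - s_new
      x <- x_new; e <- e_new; s <- s_new
      if (improved < tol) { converged <- TRUE; break }
    }
    list(x = scale(x, scale = FALSE), stress = s, converged = converged)
  }

  set.seed(seed)
  starts <- vector("list", n_restarts)
  cmd <- suppressWarnings(stats::cmdscale(unclass(d), k = k))
  if (ncol(cmd) < k)
    cmd <- cbind(cmd, matrix(0, n, k - ncol(cmd)))
  starts[[1L]] <- cmd
  if (n_restarts > 1L)
    for (r in seq.int(2L, n_restarts))
      starts[[r]] <- matrix(stats::runif(n * k, -1, 1), n, k)

  best <- NULL
  for (st in starts) {
    res <- refine(st)
    if (is.null(best) || res$stress < best$stress) best <- res
  }
  coords <- best$x
  dimnames(coords) <- list(rownames(d), paste0("dim", seq_len(k)))
  structure(list(coordinates = coords, stress = best$stress,
                 n_restarts_used = n_restarts, converged = best$converged,
                 degenerate = degenerate),
            class = "nmds_ordination")
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d points in %d dims, stress-1 = %.4g\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress))
  invisible(x)
}

pam_cost <- function(d, medoids) {
  sum(apply(d[, medoids, drop = FALSE], 1L, min))
}

pam_once <- function(d, k, medoids = NULL) {
  n <- nrow(d)
  if (is.null(medoids)) {           # BUILD
    medoids <- which.min(rowSums(d))
    while (length(medoids) < k) {
      nearest <- apply(d[, medoids, drop = FALSE], 1L, min)
      gain <- vapply(seq_len(n), function(cand) {
        if (cand %in% medoids) return(-Inf)
        sum(pmax(nearest - d[, cand], 0))
      }, numeric(1L))
      medoids <- c(medoids, which.max(gain))
    }
  }
  repeat {                          # SWAP
    cost <- pam_cost(d, medoids)
    best <- NULL
    for (m in medoids) for (h in setdiff(seq_len(n), medoids)) {
      cand <- c(setdiff(medoids, m), h)
      cc <- pam_cost(d, cand)
      if (cc < cost - 1e-12 && (is.null(best) || cc < best$cost))
        best <- list(medoids = cand, cost = cc)
    }
    if (is.null(best)) break
    medoids <- best$medoids
  }
  sort(medoids)
}

#' Partition samples into k groups by k-medoids (PAM)
#'
#' Grouping "by Bray-Curtis distance" with a k-means-like objective is only
#' well defined on the distance matrix itself, so the partitioner is
#' PAM-style k-medoids: BUILD initialization then SWAP until no improving
#' swap, with optional random restarts, keeping the solution of minimum
#' total within-cluster distance to medoid.
#'
#' @param d a [distance_matrix()].
#' @param k number of groups (default 3).
#' @param n_restarts restarts; the first uses BUILD, others random medoids.
#' @param seed RNG seed for the restarts.
#' @return a `partition` object: list with `assignment` (named integer,
#'   clusters `0..k-1` ordered by medoid label), `medoids` (labels),
#'   `total_cost`.
#' @export
cluster_k_groups <- function(d, k = 3L, n_restarts = 5L, seed = 1L) {
  stopifnot(inherits(d, "distance_matrix"))
  n <- nrow(d)
  if (k < 1L) stop("k must be at least 1")
  if (k > n) stop(sprintf("k = %d exceeds the number of samples (%d)", k, n))
  if (anyNA(d)) stop("undefined distances present")
  dm <- unclass(d)
  set.seed(seed)
  best <- pam_once(dm, k)
  if (n_restarts > 1L) for (r in seq_len(n_restarts - 1L)) {
    med <- pam_once(dm, k, medoids = sample.int(n, k))
    if (pam_cost(dm, med) < pam_cost(dm, best)) best <- med
  }
  nearest <- apply(dm[, best, drop = FALSE], 1L, which.min)
  assignment <- stats::setNames(as.integer(nearest) - 1L, rownames(d))
  structure(list(assignment = assignment,
                 medoids = rownames(d)[best],
                 total_cost = pam_cost(dm, best)),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d items, %d groups, total cost %.4g\n",
              length(x$assignment), length(x$medoids), x$total_cost))
  invisible(x)
}

# all permutations of 1..n (n! rows); used for exhaustive Mantel-type tests
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

mantel_r <- function(m1, m2) {
  lt <- lower.tri(m1)
  stats::cor(m1[lt], m2[lt])
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the strictly-lower-triangle entries, with
#' significance from joint row/column permutations of one matrix. Two-sided
#' on `|r|`. When the number of samples is 7 or fewer all `n!` permutations
#' are enumerated and the p-value is exact; otherwise `n_permutations`
#' random permutations are drawn and `p = (1 + #{|r*| >= |r|}) /
#' (1 + n_permutations)`.
#'
#' @param d1,d2 [distance_matrix()] objects with identical label sets
#'   (order is reconciled internally).
#' @param n_permutations random permutation count (ignored in exhaustive
#'   mode).
#' @param seed RNG seed.
#' @param exhaustive force (`TRUE`) or forbid (`FALSE`) enumeration;
#'   `NULL` = automatic for n <= 7.
#' @return a `mantel_result`: list with `r`, `r_squared`, `p`,
#'   `n_permutations`, `exhaustive`.
#' @export
mantel <- function(d1, d2, n_permutations = 9999L, seed = 1L,
                   exhaustive = NULL) {
  rec <- reconcile_labels(d1, d2)
  m1 <- unclass(rec$d1); m2 <- unclass(rec$d2)
  n <- nrow(m1)
  if (n < 4L) stop("Mantel test needs at least 4 samples")
  lt <- lower.tri(m1)
  if (stats::sd(m1[lt]) == 0 || stats::sd(m2[lt]) == 0)
    stop("zero variance in a distance triangle")
  r <- mantel_r(m1, m2)
  eps <- 1e-12
  if (is.null(exhaustive)) exhaustive <- n <= 7L
  if (exhaustive) {
    perms <- all_permutations(n)
    rstar <- vapply(seq_len(nrow(perms)), function(i) {
      p <- perms[i, ]
      mantel_r(m1, m2[p, p])
    }, numeric(1L))
    p_val <- mean(abs(rstar) >= abs(r) - eps)
    n_perm <- nrow(perms)
  } else {
    set.seed(seed)
    rstar <- vapply(seq_len(n_permutations), function(i) {
      p <- sample.int(n)
      mantel_r(m1, m2[p, p])
    }, numeric(1L))
    p_val <- (1 + sum(abs(rstar) >= abs(r) - eps)) / (1 + n_permutations)
    n_perm <- n_permutations
  }
  structure(list(r = r, r_squared = r^2, p = p_val,
                 n_permutations = n_perm, exhaustive = exhaustive),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.3f (r^2 = %.1f%%), p = %.4g (%s, %d perms)\n",
              x$r, 100 * x$r_squared, x$p,
              if (x$exhaustive) "exhaustive" else "sampled",
              x$n_permutations))
  invisible(x)
}

#' Compare the pairwise-distance distributions of two channels
#'
#' Answers "which observation channel separates the communities more": a
#' pooled-variance two-sample Student t test on the lower-triangle entries
#' of each matrix (the conventional analysis), plus a permutation p-value
#' obtained by shuffling entries between the two pooled triangles, which
#' does not assume independent pairs.
#'
#' @param d1,d2 [distance_matrix()] objects (label sets may differ; only
#'   the triangles are compared).
#' @param n_permutations permutation count.
#' @param seed RNG seed.
#' @return a `distance_set_comparison`: list with `mean_a`, `mean_b`,
#'   `t_statistic`, `p_parametric`, `p_permutation`, `n_a`, `n_b`.
#' @export
compare_distance_sets <- function(d1, d2, n_permutations = 9999L, seed = 1L) {
  a <- lower_triangle(d1); b <- lower_triangle(d2)
  if (length(a) < 2L || length(b) < 2L)
    stop("each triangle needs at least 2 entries")
  # pooled-variance t computed directly so that zero-variance sets give a
  # +/-Inf statistic (p -> 0) instead of an error
  na <- length(a); nb <- length(b)
  df <- na + nb - 2L
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  delta <- mean(a) - mean(b)
  t_stat <- if (sp2 > 0) delta / sqrt(sp2 * (1 / na + 1 / nb))
            else if (delta == 0) 0 else Inf * sign(delta)
  p_par <- 2 * stats::pt(-abs(t_stat), df)
  obs <- delta
  pooled <- c(a, b)
  set.seed(seed)
  perm <- vapply(seq_len(n_permutations), function(i) {
    idx <- sample.int(length(pooled), na)
    mean(pooled[idx]) - mean(pooled[-idx])
  }, numeric(1L))
  p_perm <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (1 + n_permutations)
  structure(list(mean_a = mean(a), mean_b = mean(b),
                 t_statistic = t_stat,
                 p_parametric = p_par, p_permutation = p_perm,
                 n_a = na, n_b = nb),
            class = "distance_set_comparison")
}

#' @export
print.distance_set_comparison <- function(x, ...) {
  cat(sprintf(
    "distance sets: mean %.3f (n=%d) vs %.3f (n=%d); t = %.3f, p = %.4g (perm p = %.4g)\n",
    x$mean_a, x$n_a, x$mean_b, x$n_b, x$t_statistic, x$p_parametric,
    x$p_permutation))
  invisible(x)
}
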