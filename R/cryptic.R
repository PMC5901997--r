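#' Spearman co-occurrence matrix of taxa across samples
#'
#' Spearman rank correlation (average ranks on ties) between the abundance
#' profiles of every pair of taxa, computed over samples. High positive
#' values mean two OTUs rise and fall together across hosts — the
#' co-occurrence signal used to detect cryptic lineage groups. Taxa with
#' zero variance across samples get `NA` correlations and are flagged.
#'
#' @param t an [abundance_table()] with at least 3 samples.
#' @return a `cooccurrence_matrix`: square matrix (taxa x taxa) of Spearman
#'   rho with unit diagonal, plus attribute `zero_variance` (taxon ids).
#' @export
spearman_cooccurrence <- function(t) {
  stopifnot(inherits(t, "abundance_table"))
  if (nrow(t) < 3L) stop("need at least 3 samples")
  x <- unclass(t)
  flat <- colnames(x)[apply(x, 2L, function(v) stats::sd(v) == 0)]
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  diag(rho) <- 1
  structure(rho, zero_variance = flat,
            class = c("cooccurrence_matrix", "matrix", "array"))
}

# matched lower-triangle pairs of a genetic distance and co-occurrence
# matrix, with undefined entries dropped
matched_pairs <- function(g, c) {
  if (!setequal(rownames(g), rownames(c)))
    stop("label sets differ between distance and co-occurrence matrices")
  ord <- rownames(g)
  cm <- unclass(c)[ord, ord]
  lt <- lower.tri(g)
  keep <- !is.na(g[lt]) & !is.na(cm[lt])
  list(distance = unclass(g)[lt][keep], correlation = cm[lt][keep],
       labels = ord)
}

#' Linear fit of co-occurrence on genetic distance
#'
#' Ordinary least squares of the pairwise Spearman correlations on the
#' pairwise genetic distances (lower triangle, undefined pairs dropped). A
#' negative slope means genetically close OTUs co-occur and distant ones do
#' not. Because pairs sharing an OTU are not independent, significance is
#' assessed Mantel-style: the co-occurrence matrix rows/columns are jointly
#' permuted; two-sided on `|r|`. All `n!` permutations are enumerated when
#' n <= 7 labels.
#'
#' @param g genetic [distance_matrix()].
#' @param c [spearman_cooccurrence()] matrix with the same label set.
#' @param n_permutations random permutation count.
#' @param seed RNG seed.
#' @param exhaustive `NULL` = automatic for n <= 7.
#' @return a `distance_cooccurrence_fit`: list with `slope`, `intercept`,
#'   `r`, `p_permutation`, `p_parametric`, `n_pairs`.
#' @export
fit_distance_cooccurrence <- function(g, c, n_permutations = 999L, seed = 1L,
                                      exhaustive = NULL) {
  mp <- matched_pairs(g, c)
  if (length(mp$distance) < 3L) stop("need at least 3 defined pairs")
  if (stats::sd(mp$distance) == 0) stop("all genetic distances are equal")
  fit <- stats::lm.fit(cbind(1, mp$distance), mp$correlation)
  r_obs <- stats::cor(mp$distance, mp$correlation)
  p_par <- tryCatch(
    suppressWarnings(
      summary(stats::lm(mp$correlation ~ mp$distance))$coefficients[2L, 4L]),
    error = function(e) NA_real_)
  n <- length(mp$labels)
  gm <- unclass(g)[mp$labels, mp$labels]
  cm <- unclass(c)[mp$labels, mp$labels]
  lt <- lower.tri(gm)
  perm_r <- function(p) {
    cp <- cm[p, p]
    keep <- !is.na(gm[lt]) & !is.na(cp[lt])
    suppressWarnings(stats::cor(gm[lt][keep], cp[lt][keep]))
  }
  eps <- 1e-12
  if (is.null(exhaustive)) exhaustive <- n <= 7L
  if (exhaustive) {
    perms <- all_permutations(n)
    rstar <- vapply(seq_len(nrow(perms)), function(i) perm_r(perms[i, ]),
                    numeric(1L))
    p_val <- mean(abs(rstar) >= abs(r_obs) - eps, na.rm = TRUE)
  } else {
    set.seed(seed)
    rstar <- vapply(seq_len(n_permutations), function(i)
      perm_r(sample.int(n)), numeric(1L))
    p_val <- (1 + sum(abs(rstar) >= abs(r_obs) - eps, na.rm = TRUE)) /
      (1 + n_permutations)
  }
  structure(list(slope = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 r = r_obs, p_permutation = p_val, p_parametric = p_par,
                 n_pairs = length(mp$distance)),
            class = "distance_cooccurrence_fit")
}

#' @export
print.distance_cooccurrence_fit <- function(x, ...) {
  cat(sprintf(
    "co-occurrence ~ distance: slope %.3f, r = %.3f, perm p = %.4g (%d pairs)\n",
    x$slope, x$r, x$p_permutation, x$n_pairs))
  invisible(x)
}

#' Estimate the co-occurrence genetic-distance threshold
#'
#' Finds the genetic distance below which OTU pairs co-occur and above
#' which they do not. Candidate thresholds are midpoints between
#' consecutive sorted unique pairwise distances; the returned threshold is
#' the candidate maximizing the pooled two-sample t statistic between the
#' co-occurrence correlations of sub-threshold and supra-threshold pairs
#' (both sides non-empty; ties broken toward the smallest candidate; a
#' candidate with zero pooled variance and distinct means counts as
#' infinite separation).
#'
#' @param g genetic [distance_matrix()].
#' @param c [spearman_cooccurrence()] matrix with the same labels.
#' @return a `threshold_estimate`: list with `threshold`, `t_statistic`,
#'   `mean_below`, `mean_above`, `n_below`, `n_above`, `candidates`
#'   (data.frame of all scanned candidates and their t statistics).
#' @export
estimate_threshold <- function(g, c) {
  mp <- matched_pairs(g, c)
  if (length(mp$distance) < 4L) stop("need at least 4 defined pairs")
  u <- sort(unique(mp$distance))
  if (length(u) < 2L) stop("need at least 2 distinct distances")
  cands <- (u[-length(u)] + u[-1L]) / 2
  t_for <- function(thr) {
    lo <- mp$correlation[mp$distance < thr]
    hi <- mp$correlation[mp$distance >= thr]
    n1 <- length(lo); n2 <- length(hi)
    if (n1 == 0L || n2 == 0L) return(NA_real_)
    sp2 <- (sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) / (n1 + n2 - 2)
    delta <- mean(lo) - mean(hi)
    if (sp2 <= 0) return(if (abs(delta) > 0) Inf * sign(delta) else 0)
    delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  tstats <- vapply(cands, t_for, numeric(1L))
  ok <- !is.na(tstats)
  if (!any(ok)) stop("no candidate threshold splits the pairs")
  best_t <- max(tstats[ok])
  best <- cands[ok][which(tstats[ok] >= best_t - 1e-12)[1L]]
  lo <- mp$correlation[mp$distance < best]
  hi <- mp$correlation[mp$distance >= best]
  structure(list(threshold = best, t_statistic = t_for(best),
                 mean_below = mean(lo), mean_above = mean(hi),
                 n_below = length(lo), n_above = length(hi),
                 candidates = data.frame(threshold = cands,
                                         t_statistic = tstats)),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf(
    "co-occurrence threshold: %.4g subst/site (t = %.3g; mean rho %.2f below vs %.2f above)\n",
    x$threshold, x$t_statistic, x$mean_below, x$mean_above))
  invisible(x)
}

#' Cluster OTUs below a genetic-distance threshold
#'
#' Single linkage: groups are the connected components of the graph whose
#' edges join OTU pairs at distance strictly below `threshold` (undefined
#' pairs contribute no edge). Group indices are ordered by descending size,
#' then by lexicographically smallest member. The group count is
#' non-increasing in `threshold`.
#'
#' @param g genetic [distance_matrix()].
#' @param threshold positive distance (substitutions/site).
#' @param c optional [spearman_cooccurrence()] matrix used to report mean
#'   within- and between-group correlations.
#' @return a `cryptic_groups`: list with `threshold`, `membership` (named
#'   integer, 1-based group index per OTU), `n_groups`,
#'   `mean_within_correlation`, `mean_between_correlation` (NA without `c`).
#' @export
cluster_below_threshold <- function(g, threshold, c = NULL) {
  stopifnot(inherits(g, "distance_matrix"))
  if (threshold <= 0) stop("threshold must be positive")
  n <- nrow(g)
  adj <- !is.na(g) & unclass(g) < threshold
  diag(adj) <- TRUE
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  labels <- rownames(g)
  sizes <- tabulate(comp)
  first_member <- vapply(seq_len(cur), function(k)
    min(labels[comp == k]), character(1L))
  ord <- order(-sizes, first_member)
  remap <- integer(cur); remap[ord] <- seq_len(cur)
  membership <- stats::setNames(remap[comp], labels)
  wi <- bt <- NA_real_
  if (!is.null(c)) {
    cm <- unclass(c)[labels, labels]
    lt <- lower.tri(cm)
    same <- outer(membership, membership, "==")
    wi <- mean(cm[lt & same], na.rm = TRUE)
    bt <- mean(cm[lt & !same], na.rm = TRUE)
  }
  structure(list(threshold = threshold, membership = membership,
                 n_groups = cur, mean_within_correlation = wi,
                 mean_between_correlation = bt),
            class = "cryptic_groups")
}

#' @export
print.cryptic_groups <- function(x, ...) {
  cat(sprintf("cryptic_groups: %d OTUs in %d group(s) below %.4g subst/site\n",
              length(x$membership), x$n_groups, x$threshold))
  invisible(x)
}

#' Test co-exclusion of cryptic groups across hosts
#'
#' If lineage groups occupy different hosts, within-group co-occurrence
#' correlations should exceed between-group ones. The statistic is
#' `mean(within) - mean(between)`; its p-value comes from random
#' relabelings of group membership preserving group sizes (one-sided:
#' permuted difference >= observed).
#'
#' @param groups a [cluster_below_threshold()] result with >= 2 groups.
#' @param c [spearman_cooccurrence()] matrix over the same OTUs.
#' @param n_permutations relabeling count.
#' @param seed RNG seed.
#' @return a `coexclusion_test`: list with `mean_within`, `mean_between`,
#'   `difference`, `p`, `n_permutations`.
#' @export
coexclusion_test <- function(groups, c, n_permutations = 999L, seed = 1L) {
  stopifnot(inherits(groups, "cryptic_groups"))
  if (groups$n_groups < 2L) stop("need at least 2 groups")
  labels <- names(groups$membership)
  cm <- unclass(c)[labels, labels]
  lt <- lower.tri(cm)
  stat <- function(mb) {
    same <- outer(mb, mb, "==")
    wi <- cm[lt & same]; bt <- cm[lt & !same]
    if (!length(wi)) stop("no within-group pairs (all groups of size 1)")
    if (!length(bt)) stop("no between-group pairs")
    mean(wi, na.rm = TRUE) - mean(bt, na.rm = TRUE)
  }
  obs <- stat(groups$membership)
  mw <- {
    same <- outer(groups$membership, groups$membership, "==")
    c(mean(cm[lt & same], na.rm = TRUE), mean(cm[lt & !same], na.rm = TRUE))
  }
  set.seed(seed)
  perm <- vapply(seq_len(n_permutations), function(i)
    stat(stats::setNames(sample(groups$membership), labels)), numeric(1L))
  p <- (1 + sum(perm >= obs - 1e-12)) / (1 + n_permutations)
  structure(list(mean_within = mw[1L], mean_between = mw[2L],
                 difference = obs, p = p, n_permutations = n_permutations),
            class = "coexclusion_test")
}

#' @export
print.coexclusion_test <- function(x, ...) {
  cat(sprintf(
    "co-exclusion: mean rho within %.2f vs between %.2f (diff %.2f), p = %.4g\n",
    x$mean_within, x$mean_between, x$difference, x$p))
  invisible(x)
}
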