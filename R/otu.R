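#' Greedy centroid clustering of sequences into OTUs
#'
#' Classic abundance-ordered greedy clustering: sequences are processed in
#' descending abundance (ties broken by lexicographic id); each sequence
#' joins the first existing centroid to which its identity (fraction of
#' identical effective sites) is at least `similarity`, otherwise it founds
#' a new OTU with itself as centroid. At `similarity = 1` this is exact
#' dereplication. Sequences must be aligned or of equal length so identity
#' is well defined.
#'
#' @param seqs a [sequence_collection()].
#' @param similarity identity threshold in (0, 1\]; 0.95 is the
#'   conventional OTU level for rbcL diatom barcodes.
#' @param abundances optional named numeric vector (e.g., total read
#'   counts); missing or `NULL` means all equal.
#' @return an `otu_clustering`: list with `centroids` (OTU id -> centroid
#'   sequence id), `members` (OTU id -> member sequence ids) and
#'   `assignment` (sequence id -> OTU id). OTU ids are `OTU_0001`... in
#'   founding order.
#' @export
greedy_cluster <- function(seqs, similarity = 0.95, abundances = NULL) {
  stopifnot(inherits(seqs, "sequence_collection"))
  if (similarity <= 0 || similarity > 1) stop("similarity must be in (0, 1]")
  ids <- names(seqs)
  ab <- if (is.null(abundances)) stats::setNames(rep(1, length(ids)), ids)
        else abundances[ids]
  ab[is.na(ab)] <- 0
  ord <- ids[order(-ab, ids)]
  centroid_ids <- character(0L)
  assignment <- stats::setNames(character(length(ids)), ids)
  for (id in ord) {
    placed <- FALSE
    for (c_id in centroid_ids) {
      idn <- pairwise_identity(seqs[[c_id]], seqs[[id]])
      if (!is.na(idn) && idn >= similarity - 1e-12) {
        assignment[id] <- c_id
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroid_ids <- c(centroid_ids, id)
      assignment[id] <- id
    }
  }
  otu_ids <- stats::setNames(sprintf("OTU_%04d", seq_along(centroid_ids)),
                             centroid_ids)
  members <- lapply(centroid_ids, function(c_id)
    names(assignment)[assignment == c_id])
  names(members) <- otu_ids
  structure(list(centroids = stats::setNames(centroid_ids, otu_ids),
                 members = members,
                 assignment = stats::setNames(otu_ids[assignment], ids)),
            class = "otu_clustering")
}

#' @export
print.otu_clustering <- function(x, ...) {
  cat(sprintf("otu_clustering: %d sequences in %d OTUs\n",
              length(x$assignment), length(x$centroids)))
  invisible(x)
}

#' Collapse an abundance table by a sequence-to-cluster assignment
#'
#' Sums abundance columns that map to the same cluster (OTU or
#' morphospecies); taxa without a mapping are dropped with a warning.
#'
#' @param t an [abundance_table()] whose taxa are sequence ids.
#' @param assignment named character vector, sequence id -> cluster id.
#' @return an [abundance_table()] over clusters.
#' @export
collapse_by_assignment <- function(t, assignment) {
  stopifnot(inherits(t, "abundance_table"))
  keep <- colnames(t) %in% names(assignment)
  if (!all(keep)) {
    warning(sum(!keep), " taxa without an assignment were dropped")
    t <- abundance_table(unclass(t)[, keep, drop = FALSE],
                         rownames(t), colnames(t)[keep], mode = table_mode(t))
  }
  groups <- assignment[colnames(t)]
  agg <- t(rowsum(t(unclass(t)), group = groups))
  abundance_table(agg, rownames(t), colnames(agg), mode = "count")
}

default_rank_thresholds <- function() {
  c(species = 0.97, genus = 0.95, family = 0.90, class = 0.80)
}

#' Assign taxonomy to OTUs by nearest reference
#'
#' Each OTU is compared to every reference sequence; the best identity wins
#' and the taxonomic rank granted is set by identity cutoffs (defaults:
#' >= 0.97 species, >= 0.95 genus, >= 0.90 family, >= 0.80 class, else
#' unassigned). Rank is therefore monotone in identity. Reference taxonomy
#' must supply `species`, `genus`, `family`, `class` columns keyed by
#' reference id.
#'
#' @param otus,refs [sequence_collection()] objects. Equal-length sequences
#'   are compared site-wise; unequal lengths fall back to a Needleman-Wunsch
#'   global alignment via Biostrings when installed.
#' @param ref_taxonomy data.frame with columns `id`, `species`, `genus`,
#'   `family`, `class`.
#' @param thresholds named numeric vector of identity cutoffs.
#' @return data.frame with columns `otu`, `best_reference`, `identity`,
#'   `assigned_rank`, `assigned_name`.
#' @export
assign_taxonomy <- function(otus, refs, ref_taxonomy,
                            thresholds = default_rank_thresholds()) {
  stopifnot(inherits(otus, "sequence_collection"),
            inherits(refs, "sequence_collection"))
  need <- c("id", "species", "genus", "family", "class")
  if (!all(need %in% names(ref_taxonomy)))
    stop("ref_taxonomy must have columns: ", paste(need, collapse = ", "))
  missing_tax <- setdiff(names(refs), ref_taxonomy$id)
  if (length(missing_tax))
    stop("references without taxonomy: ", paste(missing_tax, collapse = ", "))
  thresholds <- sort(thresholds, decreasing = TRUE)
  rows <- lapply(names(otus), function(o) {
    idn <- vapply(names(refs), function(r) {
      a <- otus[[o]]; b <- refs[[r]]
      if (nchar(a) == nchar(b)) {
        v <- pairwise_identity(a, b)
        if (is.na(v)) 0 else v
      } else global_identity(a, b)
    }, numeric(1L))
    best <- names(refs)[which.max(idn)]
    bid <- max(idn)
    rank <- "unassigned"
    for (rk in names(thresholds))
      if (bid >= thresholds[[rk]] - 1e-12) { rank <- rk; break }
    name <- if (rank == "unassigned") NA_character_ else
      ref_taxonomy[[rank]][match(best, ref_taxonomy$id)]
    data.frame(otu = o, best_reference = best, identity = bid,
               assigned_rank = rank, assigned_name = name,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

global_identity <- function(a, b) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("sequences of unequal length need Biostrings for global alignment")
  aln <- Biostrings::pairwiseAlignment(gsub("-", "", a), gsub("-", "", b),
                                       type = "global")
  pairwise_identity(as.character(Biostrings::alignedPattern(aln)),
                    as.character(Biostrings::alignedSubject(aln)))
}

#' Percent of OTUs assigned at each taxonomic rank
#' @param assignments output of [assign_taxonomy()].
#' @return data.frame with `rank` and `percent` (1 decimal), ranks ordered
#'   species, genus, family, class, unassigned.
#' @export
rank_summary <- function(assignments) {
  ranks <- c("species", "genus", "family", "class", "unassigned")
  counts <- table(factor(assignments$assigned_rank, levels = ranks))
  data.frame(rank = ranks,
             percent = round(100 * as.numeric(counts) / nrow(assignments), 1L),
             stringsAsFactors = FALSE)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via ape), with negative branch lengths
#' clamped to zero (a warning reports how many). Provided as the in-house
#' visualization substitute for heavyweight likelihood phylogenies.
#'
#' @param d a [distance_matrix()] with at least 3 labels and no undefined
#'   entries.
#' @return Newick string (also invisibly returns the `phylo` object as an
#'   attribute `tree`).
#' @export
nj_tree <- function(d) {
  stopifnot(inherits(d, "distance_matrix"))
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 labels")
  if (anyNA(d)) stop("undefined distances present")
  tree <- ape::nj(stats::as.dist(unclass(d)))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    warning(sum(neg), " negative branch length(s) clamped to 0")
    tree$edge.length[neg] <- 0
  }
  structure(ape::write.tree(tree), tree = tree)
}
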