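test_that("p_distance applies pairwise deletion", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("AC-T", "ACGT"), 0)     # 3 effective sites
  expect_equal(p_distance("ANGT", "A-GA"), 1 / 3) # 3 effective sites
  expect_true(is.na(p_distance("NN--", "ACGT")))
  expect_error(p_distance("ACG", "ACGT"), "equal aligned length")
})

test_that("mcl_distance is zero on identical pairs and reduces to Jukes-Cantor", {
  sc <- sequence_collection(c(a = "ACGTACGT", b = "ACGTACGT",
                              c = "ACGTACGA"))
  d <- mcl_distance(sc)
  expect_equal(d["a", "b"], 0)
  # balanced alignment: pooled frequencies exactly 1/4 each, and the two
  # differing sequences mismatch once in each of the 6 unordered base
  # pairs, so P1 = P2 = p/6 and Q = 2p/3 -> the TN93 form collapses to
  # -(3/4) log(1 - 4p/3)
  ident <- paste(rep("ACGT", 9), collapse = "")   # 36 identical, balanced
  x <- paste0("ACATCT", ident)                    # one mismatch per class:
  y <- paste0("GTCAGG", ident)                    # AG CT AC TA CG TG
  sc2 <- sequence_collection(c(s1 = x, s2 = y))
  comp <- table(factor(strsplit(paste0(x, y), "")[[1]],
                       levels = c("A", "C", "G", "T")))
  expect_true(all(comp == comp[1]))                       # balanced pool
  p <- p_distance(x, y)
  d2 <- mcl_distance(sc2)
  expect_equal(d2["s1", "s2"], -0.75 * log(1 - 4 * p / 3),
               tolerance = 1e-9)
})

test_that("mcl_distance agrees with an independent formula evaluation and with ape", {
  sc <- random_sequences(4, 120, seed = 31, rate = 0.08,
                         comp = c(0.35, 0.15, 0.2, 0.3))
  d <- mcl_distance(sc)
  seqs <- unclass(sc)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(d[i, j], tn93_oracle(seqs[[i]], seqs[[j]], seqs),
                 tolerance = 1e-12)
  }
  bin <- ape::as.DNAbin(t(sapply(strsplit(tolower(seqs), ""), identity)))
  ref <- as.matrix(ape::dist.dna(bin, model = "TN93",
                                 pairwise.deletion = TRUE))
  expect_equal(unclass(d), ref, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("mcl_distance marks saturated pairs and never undercuts p-distance", {
  # near-maximal divergence saturates the correction
  a <- paste(rep("ACGT", 20), collapse = "")
  b <- paste(rep("GTAC", 20), collapse = "")
  c <- paste(rep("ACGA", 20), collapse = "")
  d <- mcl_distance(sequence_collection(c(a = a, b = b, c = c)))
  expect_true(is.na(d["a", "b"]))
  for (seed in 1:3) {
    sc <- random_sequences(5, 150, seed = seed + 40, rate = 0.06)
    g <- mcl_distance(sc)
    seqs <- unclass(sc)
    for (i in 1:4) for (j in (i + 1):5) {
      if (!is.na(g[i, j]))
        expect_gte(g[i, j], p_distance(seqs[[i]], seqs[[j]]) - 1e-12)
    }
  }
})

test_that("greedy_cluster founds and joins OTUs by identity to centroids", {
  same <- sequence_collection(c(a = "ACGTACGT", b = "ACGTACGT",
                                c = "ACGTACGT"))
  expect_equal(length(greedy_cluster(same)$centroids), 1L)
  single <- sequence_collection(c(only = "ACGT"))
  cl1 <- greedy_cluster(single)
  expect_equal(unname(cl1$assignment), "OTU_0001")
  # two families: >= 10% between, <= 2% within
  set.seed(51)
  rootA <- sample(BASES, 200, TRUE)
  rootB <- mutate_chars(rootA, 0.25)
  fam <- c(vapply(1:3, function(i)
             paste(mutate_chars(rootA, 0.01), collapse = ""), character(1)),
           vapply(1:3, function(i)
             paste(mutate_chars(rootB, 0.01), collapse = ""), character(1)))
  names(fam) <- paste0("f", 1:6)
  cl <- greedy_cluster(sequence_collection(fam), similarity = 0.95)
  expect_equal(length(cl$centroids), 2L)
  expect_equal(length(unique(cl$assignment[1:3])), 1L)
  expect_equal(length(unique(cl$assignment[4:6])), 1L)
})

test_that("greedy_cluster honors abundance order and dereplicates at similarity 1", {
  sc <- random_sequences(8, 100, seed = 61, rate = 0.04)
  ab <- setNames(c(5, 40, 1, 8, 2, 9, 3, 7), names(sc))
  cl <- greedy_cluster(sc, similarity = 0.9, abundances = ab)
  # most abundant sequence founds the first OTU
  expect_equal(cl$centroids[["OTU_0001"]], names(which.max(ab)))
  derep <- greedy_cluster(sc, similarity = 1)
  expect_equal(length(derep$centroids),
               length(unique(unclass(sc))))
  # OTU count is non-increasing as similarity decreases
  counts <- sapply(c(1, 0.99, 0.97, 0.95, 0.9, 0.8), function(s)
    length(greedy_cluster(sc, similarity = s)$centroids))
  expect_true(all(diff(counts) <= 0))
})

test_that("assign_taxonomy grants ranks by identity cutoffs, monotonically", {
  set.seed(71)
  ref <- paste(sample(BASES, 100, TRUE), collapse = "")
  refs <- sequence_collection(c(R1 = ref))
  tax <- data.frame(id = "R1", species = "Nitzschia alpha",
                    genus = "Nitzschia", family = "Bacillariaceae",
                    class = "Bacillariophyceae", stringsAsFactors = FALSE)
  mk <- function(n_mut) {
    chars <- strsplit(ref, "")[[1]]
    idx <- seq_len(n_mut)
    for (i in idx) chars[i] <- setdiff(BASES, chars[i])[1]
    paste(chars, collapse = "")
  }
  otus <- sequence_collection(c(o_same = ref, o93 = mk(7), o50 = mk(50)))
  res <- assign_taxonomy(otus, refs, tax)
  res <- res[match(c("o_same", "o93", "o50"), res$otu), ]
  expect_equal(res$assigned_rank, c("species", "family", "unassigned"))
  expect_equal(res$identity[1], 1.0)
  expect_equal(res$assigned_name[1], "Nitzschia alpha")
  # rank is monotone in identity across a ladder of divergences
  ladder <- sequence_collection(
    setNames(vapply(c(0, 2, 4, 7, 12, 25, 60), function(k) mk(k),
                    character(1)),
             paste0("l", 1:7)))
  ranks <- assign_taxonomy(ladder, refs, tax)$assigned_rank
  lvl <- c(unassigned = 0, class = 1, family = 2, genus = 3, species = 4)
  expect_true(all(diff(lvl[ranks]) <= 0))
  expect_error(assign_taxonomy(otus, refs, tax[, 1:2]), "columns")
})

test_that("rank_summary reports percentages over the five ranks", {
  a <- data.frame(assigned_rank = c("species", "genus", "genus",
                                    "unassigned"))
  rs <- rank_summary(a)
  expect_equal(rs$percent[rs$rank == "genus"], 50)
  expect_equal(sum(rs$percent), 100)
})

test_that("nj_tree solves the 3-taxon case and recovers additive trees", {
  # 3 taxa: branch lengths satisfy the three-point equations
  d3 <- dm_from_lower(c(0.3, 0.5, 0.6), c("A", "B", "C"))
  nwk <- nj_tree(d3)
  tree <- attr(nwk, "tree")
  # x+y=0.3, x+z=0.5, y+z=0.6 -> x=0.1, y=0.2, z=0.4
  tip_len <- setNames(tree$edge.length[match(seq_len(3), tree$edge[, 2])],
                      tree$tip.label)
  expect_equal(unname(tip_len[c("A", "B", "C")]), c(0.1, 0.2, 0.4),
               tolerance = 1e-12)
  # additive 4-taxon distances: exact recovery of topology and lengths
  true4 <- ape::read.tree(text = "((A:0.1,B:0.2):0.15,(C:0.3,D:0.05):0.1);")
  d4m <- ape::cophenetic.phylo(true4)
  d4 <- distance_matrix(d4m[LETTERS[1:4], LETTERS[1:4]], LETTERS[1:4])
  rec <- attr(nj_tree(d4), "tree")
  expect_equal(ape::dist.topo(ape::unroot(true4), ape::unroot(rec)), 0,
               ignore_attr = TRUE)
  expect_equal(unclass(ape::cophenetic.phylo(rec))[LETTERS[1:4], LETTERS[1:4]],
               unclass(d4), tolerance = 1e-12, ignore_attr = TRUE)
  # star distances: all internal branch lengths collapse to zero
  star <- dm_from_lower(rep(1, 6), c("A", "B", "C", "D"))
  st <- attr(suppressWarnings(nj_tree(star)), "tree")
  internal <- st$edge.length[st$edge[, 2] > 4]
  expect_true(all(abs(internal) < 1e-12))
  expect_error(nj_tree(dm_from_lower(c(NA, 1, 1), c("A", "B", "C"))),
               "undefined")
})

test_that("nj_tree recovers random additive topologies", {
  for (seed in 1:5) {
    set.seed(seed + 90)
    n <- sample(5:8, 1)
    true <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.5))
    dm <- ape::cophenetic.phylo(true)
    rec <- attr(nj_tree(distance_matrix(dm, rownames(dm))), "tree")
    expect_equal(ape::dist.topo(ape::unroot(true), ape::unroot(rec)), 0,
                 ignore_attr = TRUE)
  }
})
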