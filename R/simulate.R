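#' Parameters of the paired-observation community simulator
#'
#' Defines a latent biofilm world observed through two imperfect channels.
#' `n_morphospecies` morphospecies live on `n_hosts` host individuals; one
#' focal morphospecies hides `n_cryptic_lineages` genetic lineages split
#' into `n_groups` habitat groups (the cryptic diversity to be recovered);
#' the remaining morphospecies carry a single lineage each. Microscopy
#' counts `valves` frustules per host and cannot see below morphospecies;
#' it also counts dead frustules: its sampling probabilities mix the living
#' composition with a static dead-pool composition at weight `phi`.
#' Metabarcoding draws `reads` reads per host over lineages with
#' probabilities proportional to abundance times `biovolume^beta`, because
#' chloroplast gene copy number scales with cell biovolume.
#'
#' @param n_hosts number of host individuals (7, the sampled turtles).
#' @param n_morphospecies total morphospecies (default 15, giving per-host
#'   richness in the observed 15-24 range).
#' @param n_cryptic_lineages lineages of the focal morphospecies
#'   (default 60).
#' @param n_groups habitat groups among the cryptic lineages (default 4).
#' @param seq_length barcode length in bp (default 312, rbcL fragment).
#' @param delta_within,delta_between target pairwise divergence
#'   (substitutions/site) within and between cryptic groups (defaults
#'   0.015 and 0.10; their gap brackets the 0.04 co-occurrence threshold).
#' @param delta_morpho divergence of morphospecies ancestors from the root
#'   (default 0.30; keeps cross-morphospecies distances defined but far
#'   above `delta_between`).
#' @param biovolume_range cell biovolume range in µm³, sampled log-uniform
#'   (default 15-2000, the small-Labellicula to large-Entomoneis span).
#' @param beta copy-number exponent linking reads to biovolume (default 1:
#'   copies proportional to biovolume).
#' @param phi dead-frustule carryover fraction in \[0,1) (default 0.2).
#' @param sigma lognormal co-occurrence noise on lineage abundances
#'   (default 0.1).
#' @param valves microscopy count depth per host (default 400 valves).
#' @param reads metabarcoding read depth per host (default 30000).
#' @param dirichlet_alpha concentration of the per-host morphospecies
#'   composition (default 0.5: uneven, dominance-prone communities).
#' @return a `synthetic_params` list.
#' @export
synthetic_params <- function(n_hosts = 7L, n_morphospecies = 15L,
                             n_cryptic_lineages = 60L, n_groups = 4L,
                             seq_length = 312L,
                             delta_within = 0.015, delta_between = 0.10,
                             delta_morpho = 0.30,
                             biovolume_range = c(15, 2000), beta = 1,
                             phi = 0.2, sigma = 0.1,
                             valves = 400L, reads = 30000L,
                             dirichlet_alpha = 0.5) {
  p <- list(n_hosts = as.integer(n_hosts),
            n_morphospecies = as.integer(n_morphospecies),
            n_cryptic_lineages = as.integer(n_cryptic_lineages),
            n_groups = as.integer(n_groups),
            seq_length = as.integer(seq_length),
            delta_within = delta_within, delta_between = delta_between,
            delta_morpho = delta_morpho,
            biovolume_range = biovolume_range, beta = beta,
            phi = phi, sigma = sigma,
            valves = as.integer(valves), reads = as.integer(reads),
            dirichlet_alpha = dirichlet_alpha)
  if (p$delta_within >= p$delta_between)
    stop("delta_within must be smaller than delta_between")
  if (p$phi < 0 || p$phi >= 1) stop("phi must lie in [0, 1)")
  if (p$n_groups > p$n_cryptic_lineages)
    stop("more groups than cryptic lineages")
  if (p$n_hosts < 2L || p$n_morphospecies < 2L)
    stop("need at least 2 hosts and 2 morphospecies")
  structure(p, class = "synthetic_params")
}

# substitute an exact number of sites, round(rate * length), at random
# positions: divergence targets are hit rather than merely expected, which
# keeps the within/between-group distance gap stable across seeds
mutate_seq <- function(chars, rate) {
  bases <- c("A", "C", "G", "T")
  n_mut <- round(rate * length(chars))
  hit <- sample.int(length(chars), min(n_mut, length(chars)))
  for (i in hit) {
    chars[i] <- sample(setdiff(bases, chars[i]), 1L)
  }
  chars
}

rdirichlet1 <- function(n, alpha) {
  g <- stats::rgamma(n, shape = alpha)
  if (sum(g) == 0) g[sample.int(n, 1L)] <- 1
  g / sum(g)
}

#' Generate a paired microscopy/metabarcoding dataset with ground truth
#'
#' Simulates the latent world described by [synthetic_params()] and
#' observes it through both channels. Steps: (1) sequences — a random root,
#' morphospecies ancestors mutated at `delta_morpho`, group ancestors at
#' `(delta_between - delta_within)/2`, lineage tips at `delta_within/2`, so
#' pairwise divergence is ~`delta_within` within and ~`delta_between`
#' between groups; (2) latent abundances — per host a Dirichlet
#' morphospecies composition; per host and morphospecies one habitat group
#' is active, its lineages receiving Dirichlet sub-weights perturbed by
#' lognormal noise `sigma` (morphospecies whose lineages all belong to one
#' group are always active); (3) microscopy — multinomial(`valves`) over
#' morphospecies with living composition mixed with a uniform dead pool at
#' weight `phi`; (4) metabarcoding — multinomial(`reads`) over lineages
#' with probabilities proportional to abundance x biovolume^`beta`.
#' Identical seed, identical dataset.
#'
#' @param params a [synthetic_params()] list.
#' @param seed integer RNG seed (recorded in the output).
#' @return a `synthetic_dataset`: list with `truth` (lineage metadata
#'   data.frame with columns `lineage`, `morphospecies`, `group`,
#'   `cluster`; `biovolumes`; latent `abundance` host x lineage matrix;
#'   expected per-channel probabilities; `params`; `seed`),
#'   `microscopy` and `metabarcoding` count [abundance_table()]s, and
#'   `sequences` (a [sequence_collection()] of the lineage barcodes).
#' @export
simulate_dataset <- function(params = synthetic_params(), seed = 1L) {
  stopifnot(inherits(params, "synthetic_params"))
  p <- params
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  msp_ids <- sprintf("Msp%02d", seq_len(p$n_morphospecies))
  # genus names cycle through the shipped guild lookup so microscopy
  # profiles feed the guild module; focal morphospecies plays the
  # Nitzschia role
  genera <- c("Nitzschia", "Labellicula", "Navicula", "Halamphora",
              "Amphora", "Entomoneis", "Olifantiella", "Cocconeis",
              "Licmophora", "Mastogloia", "Achnanthes", "Tursicola",
              "Thalassiosira", "Pseudo-nitzschia", "Gomphonema")
  msp_names <- paste(genera[(seq_len(p$n_morphospecies) - 1L) %%
                              length(genera) + 1L],
                     sprintf("sp%02d", seq_len(p$n_morphospecies)))

  # lineage bookkeeping: focal morphospecies 1 carries the cryptic lineages
  n_focal <- p$n_cryptic_lineages
  groups_focal <- rep(seq_len(p$n_groups), length.out = n_focal)
  lineage_msp <- c(rep(1L, n_focal), seq.int(2L, p$n_morphospecies))
  lineage_group <- c(groups_focal,
                     rep(seq_len(p$n_groups),
                         length.out = p$n_morphospecies - 1L))
  lineage_ids <- sprintf("L%03d", seq_along(lineage_msp))
  cluster_id <- paste0("m", lineage_msp, "g", lineage_group)

  # sequences
  root <- sample(bases, p$seq_length, replace = TRUE)
  msp_anc <- lapply(seq_len(p$n_morphospecies), function(m)
    mutate_seq(root, p$delta_morpho))
  r_group <- (p$delta_between - p$delta_within) / 2
  r_tip <- p$delta_within / 2
  grp_anc <- lapply(seq_len(p$n_groups), function(g)
    mutate_seq(msp_anc[[1L]], r_group))
  seqs <- character(length(lineage_ids))
  for (i in seq_along(lineage_ids)) {
    anc <- if (lineage_msp[i] == 1L) grp_anc[[lineage_group[i]]]
           else msp_anc[[lineage_msp[i]]]
    seqs[i] <- paste(mutate_seq(anc, r_tip), collapse = "")
  }
  names(seqs) <- lineage_ids
  sequences <- sequence_collection(seqs)

  # biovolumes per morphospecies, log-uniform
  lo <- log(p$biovolume_range[1L]); hi <- log(p$biovolume_range[2L])
  biovol <- exp(stats::runif(p$n_morphospecies, lo, hi))
  names(biovol) <- msp_ids

  # latent abundances
  hosts <- sprintf("Host%d", seq_len(p$n_hosts))
  abundance <- matrix(0, p$n_hosts, length(lineage_ids),
                      dimnames = list(hosts, lineage_ids))
  for (h in seq_len(p$n_hosts)) {
    w_msp <- rdirichlet1(p$n_morphospecies, p$dirichlet_alpha)
    for (m in seq_len(p$n_morphospecies)) {
      idx <- which(lineage_msp == m)
      gs <- unique(lineage_group[idx])
      g_active <- if (length(gs) == 1L) gs else sample(gs, 1L)
      act <- idx[lineage_group[idx] == g_active]
      w <- rdirichlet1(length(act), 1) *
        exp(stats::rnorm(length(act), 0, p$sigma))
      abundance[h, act] <- w_msp[m] * w / sum(w)
    }
    abundance[h, ] <- abundance[h, ] / sum(abundance[h, ])
  }

  # observation probabilities
  msp_abund <- t(rowsum(t(abundance), group = msp_ids[lineage_msp]))
  msp_abund <- msp_abund[, msp_ids, drop = FALSE]
  micro_prob <- (1 - p$phi) * msp_abund + p$phi / p$n_morphospecies
  copy_weight <- abundance *
    rep(biovol[lineage_msp]^p$beta, each = p$n_hosts)
  meta_prob <- copy_weight / rowSums(copy_weight)

  microscopy <- t(vapply(seq_len(p$n_hosts), function(h)
    as.numeric(stats::rmultinom(1L, p$valves, micro_prob[h, ])),
    numeric(p$n_morphospecies)))
  metabarcoding <- t(vapply(seq_len(p$n_hosts), function(h)
    as.numeric(stats::rmultinom(1L, p$reads, meta_prob[h, ])),
    numeric(length(lineage_ids))))

  micro_tab <- abundance_table(microscopy, hosts, msp_names, mode = "count")
  meta_tab <- abundance_table(metabarcoding, hosts, lineage_ids,
                              mode = "count")
  truth <- list(
    lineages = data.frame(lineage = lineage_ids,
                          morphospecies = msp_ids[lineage_msp],
                          morphospecies_name = msp_names[lineage_msp],
                          group = lineage_group, cluster = cluster_id,
                          stringsAsFactors = FALSE),
    biovolumes = biovol,
    abundance = abundance,
    microscopy_prob = micro_prob,
    metabarcoding_prob = meta_prob,
    params = p, seed = seed)
  structure(list(truth = truth, microscopy = micro_tab,
                 metabarcoding = meta_tab, sequences = sequences),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  p <- x$truth$params
  cat(sprintf(
    "synthetic_dataset: %d hosts, %d morphospecies, %d lineages (%d cryptic in %d groups), seed %d\n",
    p$n_hosts, p$n_morphospecies, nrow(x$truth$lineages),
    p$n_cryptic_lineages, p$n_groups, x$truth$seed))
  invisible(x)
}

#' Closed-form expected channel compositions
#'
#' Per-host expected relative abundances (percent) that each channel would
#' report in the infinite-depth limit, given the latent truth: microscopy
#' mixes the living morphospecies composition with the uniform dead pool
#' at weight `phi`; metabarcoding reweights lineage abundances by
#' `biovolume^beta` and collapses to morphospecies. Used as the oracle for
#' [simulate_dataset()]'s multinomial draws.
#'
#' @param truth the `truth` element of a `synthetic_dataset`, or any list
#'   with `abundance` (host x lineage, rows summing to 1), `biovolumes`
#'   (per morphospecies), `lineages` (with `lineage` and `morphospecies`
#'   columns) and `params` (with `phi`, `beta`, `n_morphospecies`).
#' @return list of two host x morphospecies percent matrices,
#'   `microscopy` and `metabarcoding`.
#' @export
expected_channel_bias <- function(truth) {
  p <- truth$params
  msp <- unique(truth$lineages$morphospecies)
  lineage_msp <- truth$lineages$morphospecies[
    match(colnames(truth$abundance), truth$lineages$lineage)]
  living <- t(rowsum(t(truth$abundance), group = lineage_msp))
  living <- living[, msp, drop = FALSE]
  micro <- (1 - p$phi) * living + p$phi / p$n_morphospecies
  weight <- truth$abundance *
    rep(truth$biovolumes[lineage_msp]^p$beta,
        each = nrow(truth$abundance))
  weight <- weight / rowSums(weight)
  meta <- t(rowsum(t(weight), group = lineage_msp))[, msp, drop = FALSE]
  list(microscopy = 100 * micro, metabarcoding = 100 * meta)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `microscopy.tsv`, `metabarcoding.tsv`, `lineages.fasta`, and
#' `truth.json` (lineage metadata, biovolumes, parameters, seed).
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_abundance_table(dataset$microscopy, file.path(dir, "microscopy.tsv"))
  write_abundance_table(dataset$metabarcoding,
                        file.path(dir, "metabarcoding.tsv"))
  write_fasta(dataset$sequences, file.path(dir, "lineages.fasta"))
  truth <- dataset$truth
  jsonlite::write_json(
    list(lineages = truth$lineages,
         biovolumes = as.list(truth$biovolumes),
         params = unclass(truth$params), seed = truth$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
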