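#' Configuration for the end-to-end pipeline
#'
#' Collects every tunable of the two-channel comparison. Either supply
#' `microscopy_path`/`metabarcoding_path`/`fasta_path` (TSV tables and a
#' FASTA of OTU sequences) or leave them `NULL` to simulate a dataset with
#' `sim_params`. `cryptic_subset` optionally restricts the cryptic chain to
#' a set of OTU ids (the focal-morphospecies neighborhood); with simulated
#' input it defaults to the focal morphospecies' lineages.
#'
#' @param microscopy_path,metabarcoding_path,fasta_path input files, or
#'   `NULL` to simulate.
#' @param sim_params [synthetic_params()] used when simulating.
#' @param k number of sample groups for k-medoids (default 3).
#' @param nmds_dimensions,nmds_restarts NMDS settings.
#' @param n_permutations permutation count for Mantel/permutation tests.
#' @param cryptic_subset optional character vector of OTU ids.
#' @param seed global seed; stage seeds are derived as `seed + stage index`
#'   (simulate +0, NMDS +1/+2, clustering +3/+4, Mantel +5, distance-set
#'   comparison +6, co-occurrence fit +7, co-exclusion +8).
#' @return a `run_config` list.
#' @export
pipeline_config <- function(microscopy_path = NULL,
                            metabarcoding_path = NULL,
                            fasta_path = NULL,
                            sim_params = synthetic_params(),
                            k = 3L, nmds_dimensions = 2L,
                            nmds_restarts = 10L,
                            n_permutations = 999L,
                            cryptic_subset = NULL,
                            seed = 1L) {
  structure(list(microscopy_path = microscopy_path,
                 metabarcoding_path = metabarcoding_path,
                 fasta_path = fasta_path, sim_params = sim_params,
                 k = as.integer(k),
                 nmds_dimensions = as.integer(nmds_dimensions),
                 nmds_restarts = as.integer(nmds_restarts),
                 n_permutations = as.integer(n_permutations),
                 cryptic_subset = cryptic_subset,
                 seed = as.integer(seed)),
            class = "run_config")
}

stage_log <- function(log, stage, detail) {
  message(sprintf("[%s] %s", stage, detail))
  c(log, sprintf("%s\t%s", stage, detail))
}

#' Run the full two-channel comparison pipeline
#'
#' Stages, in order: load or simulate the paired tables; normalize to
#' relative abundance; Bray-Curtis per channel; NMDS per channel; k-medoids
#' per channel; Mantel test between the channel distance matrices;
#' comparison of the two distance distributions; then, on the metabarcoding
#' channel, genetic distances (composite-frequency TN93), Spearman
#' co-occurrence, distance/co-occurrence fit, threshold estimation,
#' sub-threshold grouping and the co-exclusion test; finally the
#' ecological-guild profile of the microscopy channel. Any stage error
#' aborts with the stage name. Identical config and seed give a
#' byte-identical summary.
#'
#' @param cfg a [pipeline_config()].
#' @param outdir optional directory: stage outputs (TSV/FASTA/Newick) and
#'   `summary.json` are written there.
#' @return the summary as a nested list (invisibly written as JSON when
#'   `outdir` is given).
#' @export
run_pipeline <- function(cfg = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  log <- character(0L)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  simulated <- is.null(cfg$microscopy_path)
  if (simulated) {
    ds <- run_stage("simulate",
                    simulate_dataset(cfg$sim_params, seed = cfg$seed))
    micro <- ds$microscopy; meta <- ds$metabarcoding; seqs <- ds$sequences
    if (is.null(cfg$cryptic_subset)) {
      focal <- ds$truth$lineages$morphospecies[1L]
      cfg$cryptic_subset <- ds$truth$lineages$lineage[
        ds$truth$lineages$morphospecies == focal]
    }
    guild_names <- stats::setNames(ds$truth$lineages$morphospecies_name,
                                   ds$truth$lineages$morphospecies)
    log <- stage_log(log, "simulate",
                     sprintf("%d hosts x %d lineages, seed %d",
                             nrow(meta), ncol(meta), cfg$seed))
  } else {
    micro <- run_stage("load", read_abundance_table(cfg$microscopy_path))
    meta <- run_stage("load", read_abundance_table(cfg$metabarcoding_path))
    seqs <- if (!is.null(cfg$fasta_path))
      run_stage("load", read_fasta(cfg$fasta_path)) else NULL
    log <- stage_log(log, "load", sprintf("microscopy %dx%d, metabarcoding %dx%d",
                                          nrow(micro), ncol(micro),
                                          nrow(meta), ncol(meta)))
  }

  micro_rel <- run_stage("normalize", if (table_mode(micro) == "count")
    to_relative_abundance(micro) else micro)
  meta_rel <- run_stage("normalize", if (table_mode(meta) == "count")
    to_relative_abundance(meta) else meta)
  log <- stage_log(log, "normalize", "both channels in percent")

  bc_micro <- run_stage("bray_curtis", bray_curtis(micro_rel))
  bc_meta <- run_stage("bray_curtis", bray_curtis(meta_rel))
  log <- stage_log(log, "bray_curtis",
                   sprintf("mean %0.3f (microscopy) vs %0.3f (metabarcoding)",
                           mean(lower_triangle(bc_micro)),
                           mean(lower_triangle(bc_meta))))

  ord_micro <- run_stage("nmds", nmds(bc_micro, k = cfg$nmds_dimensions,
                                      n_restarts = cfg$nmds_restarts,
                                      seed = cfg$seed + 1L))
  ord_meta <- run_stage("nmds", nmds(bc_meta, k = cfg$nmds_dimensions,
                                     n_restarts = cfg$nmds_restarts,
                                     seed = cfg$seed + 2L))
  log <- stage_log(log, "nmds", sprintf("stress %0.4f / %0.4f",
                                        ord_micro$stress, ord_meta$stress))

  part_micro <- run_stage("cluster",
                          cluster_k_groups(bc_micro, k = cfg$k,
                                           seed = cfg$seed + 3L))
  part_meta <- run_stage("cluster",
                         cluster_k_groups(bc_meta, k = cfg$k,
                                          seed = cfg$seed + 4L))
  log <- stage_log(log, "cluster", sprintf("k = %d per channel", cfg$k))

  mant <- run_stage("mantel", mantel(bc_micro, bc_meta,
                                     n_permutations = cfg$n_permutations,
                                     seed = cfg$seed + 5L))
  comp <- run_stage("compare", compare_distance_sets(
    bc_meta, bc_micro, n_permutations = cfg$n_permutations,
    seed = cfg$seed + 6L))
  log <- stage_log(log, "compare",
                   sprintf("Mantel r^2 = %0.3f (p = %0.3g); t p = %0.3g",
                           mant$r_squared, mant$p, comp$p_parametric))

  cryptic <- NULL
  if (!is.null(seqs)) {
    sub <- if (is.null(cfg$cryptic_subset)) names(seqs) else cfg$cryptic_subset
    sub <- intersect(sub, intersect(names(seqs), colnames(meta)))
    gdist <- run_stage("gendist", mcl_distance(seqs[sub]))
    cooc <- run_stage("cooccurrence", spearman_cooccurrence(
      abundance_table(unclass(meta)[, sub, drop = FALSE], rownames(meta),
                      sub, mode = "count")))
    fit <- run_stage("fit", fit_distance_cooccurrence(
      gdist, cooc, n_permutations = cfg$n_permutations,
      seed = cfg$seed + 7L))
    thr <- run_stage("threshold", estimate_threshold(gdist, cooc))
    grp <- run_stage("groups",
                     cluster_below_threshold(gdist, thr$threshold, cooc))
    coex <- if (grp$n_groups >= 2L)
      run_stage("coexclusion", coexclusion_test(
        grp, cooc, n_permutations = cfg$n_permutations,
        seed = cfg$seed + 8L)) else NULL
    tree <- if (!anyNA(gdist) && nrow(gdist) >= 3L)
      run_stage("njtree", nj_tree(gdist)) else NULL
    cryptic <- list(n_otus = length(sub), fit = unclass(fit),
                    threshold = thr$threshold,
                    t_statistic = thr$t_statistic,
                    n_groups = grp$n_groups,
                    membership = as.list(grp$membership),
                    coexclusion = if (!is.null(coex)) unclass(coex),
                    newick = as.character(tree))
    cryptic$fit$candidates <- NULL
    log <- stage_log(log, "cryptic",
                     sprintf("threshold %0.4f, %d group(s)",
                             thr$threshold, grp$n_groups))
  }

  lookup <- read_guild_lookup()
  taxa <- colnames(micro_rel)
  assignments <- stats::setNames(
    vapply(taxa, function(tx) assign_guild(tx, lookup = lookup),
           character(1L)), taxa)
  guilds <- run_stage("guilds", guild_profile(micro_rel, assignments))
  log <- stage_log(log, "guilds", "microscopy channel profiled")

  summary <- list(
    seed = cfg$seed, simulated = simulated,
    channels = list(
      microscopy = list(n_samples = nrow(micro), n_taxa = ncol(micro),
                        richness = richness_summary(micro)),
      metabarcoding = list(n_samples = nrow(meta), n_taxa = ncol(meta),
                           richness = richness_summary(meta))),
    bray_curtis = list(mean_microscopy = mean(lower_triangle(bc_micro)),
                       mean_metabarcoding = mean(lower_triangle(bc_meta))),
    nmds = list(microscopy = list(stress = ord_micro$stress,
                                  coordinates = as.data.frame(ord_micro$coordinates)),
                metabarcoding = list(stress = ord_meta$stress,
                                     coordinates = as.data.frame(ord_meta$coordinates))),
    partitions = list(microscopy = as.list(part_micro$assignment),
                      metabarcoding = as.list(part_meta$assignment)),
    mantel = unclass(mant),
    distance_comparison = unclass(comp),
    cryptic = cryptic,
    guild_profile = as.data.frame(unclass(guilds)))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_distance_matrix(bc_micro, file.path(outdir, "bc_microscopy.tsv"))
    write_distance_matrix(bc_meta, file.path(outdir, "bc_metabarcoding.tsv"))
    utils::write.table(ord_micro$coordinates,
                       file.path(outdir, "nmds_microscopy.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(ord_meta$coordinates,
                       file.path(outdir, "nmds_metabarcoding.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    if (!is.null(cryptic$newick) && length(cryptic$newick))
      writeLines(cryptic$newick, file.path(outdir, "otu_nj.nwk"))
    writeLines(log, file.path(outdir, "run.log"))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(summary)
}
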