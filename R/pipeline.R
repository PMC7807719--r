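#' Default pipeline configuration
#'
#' All thresholds of the analysis with their standard defaults: tag-cluster
#' distance 5 nt with a 3-TPM singleton floor; consensus aggregation at
#' 1 TPM, 0.05/0.95 trimming quantiles and 20 nt merge reach; assignment
#' tiers 100/1000 bp with 30-bp sliding windows and the 5%/5x TES coverage
#' criteria; twofold/FDR 0.05 significance; dominance ratio 1 for
#' switching; 1/3 expression fraction and 300 nt minimum ORF for stringent
#' internal calls; 80 bp proximal/distal split and 50/50 percentiles for
#' the determinant analysis; (A)20/8-mismatch poly(A) motif with 5 nt
#' priming reach; Spearman r 0.5 / p 0.05 spurious cutoffs.
#'
#' @param ... overrides for individual entries.
#' @return Named list of parameters.
#' @export
default_config <- function(...) {
  cfg <- list(
    max_dist_tag = 5, singleton_floor_tpm = 3,
    tpm_threshold = 1, q_low = 0.05, q_up = 0.95, max_dist_agg = 20,
    assign_near = 100, assign_far = 1000, window = 30,
    tes_median_frac = 0.05, tes_max_mult = 5,
    lfc_threshold = 1, alpha = 0.05, pseudo = 0.5,
    dominance_ratio = 1,
    internal_fraction = 1 / 3, min_orf_len = 300,
    distance_threshold = 80, alt_pct = 50, main_pct = 50,
    polyA_motif_len = 20, polyA_max_mismatch = 8, priming_dist = 5,
    spurious_r = 0.5, spurious_p = 0.05, spurious_flank = 5,
    min_tpm = 1, seed = 1)
  utils::modifyList(cfg, list(...))
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @export
read_config <- function(path) {
  utils::modifyList(default_config(), yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: TPM normalization and per-sample tag-cluster calling;
#' internal-priming filtering of TES tracks (before TES clustering) and
#' consensus aggregation; spurious-TSS filtering against the non-decapping
#' control; gene assignment; main/alternative classification and the usage
#' table; per-cluster differential expression; pairing, main-TSS response
#' classification and switching detection; internal-TSS and truncated-ORF
#' calls; the determinant table and regression (when enough qualifying
#' records exist).
#'
#' @param tss_tracks named list of raw TSS `end_track`s (one per sample).
#' @param sample_info data.frame `sample_id`, `timepoint`, `replicate`.
#' @param transition a `transition_config`.
#' @param genes `gene_models` data.frame.
#' @param rna_coverage `coverage_track`.
#' @param genome named character vector of contig sequences (needed for
#'   the internal-ORF stage and the priming filter).
#' @param tes_tracks optional named list of raw TES `end_track`s.
#' @param nondecapped optional non-decapping control `end_track`; the
#'   spurious filter runs when given, against `reference_sample` (default:
#'   the first sample of the reference timepoint).
#' @param occupancy optional named per-gene occupancy-change covariate.
#' @param reference_sample sample id used as the decapped reference for
#'   the spurious filter.
#' @param config parameter list from [default_config()].
#' @param out_dir optional directory: all result tables are written as TSV.
#' @return List of stage outputs: `tss_clusters`, `tes_clusters`,
#'   `spurious`, `assignments`, `tes_assignments`, `usage`, `diff`,
#'   `pairs`, `events`, `gene_events`, `internal`, `determinants`,
#'   `regression`.
#' @export
run_pipeline <- function(tss_tracks, sample_info, transition, genes,
                         rna_coverage, genome = NULL, tes_tracks = NULL,
                         nondecapped = NULL, occupancy = NULL,
                         reference_sample = NULL, config = default_config(),
                         out_dir = NULL) {
  cfg <- config
  cluster_stage <- function(raw_tracks, kind) {
    tpm_tracks <- lapply(raw_tracks, normalize_tpm)
    per_sample <- lapply(tpm_tracks, call_tag_clusters,
                         max_dist = cfg$max_dist_tag,
                         singleton_floor_tpm = cfg$singleton_floor_tpm)
    pooled <- pool_tpm(tpm_tracks)
    aggregate_clusters(per_sample, pooled, tpm_tracks = tpm_tracks,
                       raw_tracks = raw_tracks,
                       tpm_threshold = cfg$tpm_threshold, q_low = cfg$q_low,
                       q_up = cfg$q_up, max_dist = cfg$max_dist_agg,
                       kind = kind)
  }
  tss_clusters <- cluster_stage(tss_tracks, "TSS")

  spurious <- NULL
  if (!is.null(nondecapped)) {
    if (is.null(reference_sample)) {
      ref_ids <- sample_info$sample_id[sample_info$timepoint ==
                                         transition$reference]
      reference_sample <- ref_ids[1]
    }
    spurious <- flag_spurious_all(tss_clusters, tss_tracks[[reference_sample]],
                                  nondecapped, flank = cfg$spurious_flank,
                                  r_threshold = cfg$spurious_r,
                                  p_threshold = cfg$spurious_p)
    keep <- !spurious$spurious
    tss_clusters$clusters <- tss_clusters$clusters[keep, , drop = FALSE]
    tss_clusters$tpm <- tss_clusters$tpm[keep, , drop = FALSE]
    if (!is.null(tss_clusters$counts))
      tss_clusters$counts <- tss_clusters$counts[keep, , drop = FALSE]
  }

  tes_clusters <- NULL; tes_assignments <- NULL
  if (!is.null(tes_tracks)) {
    if (!is.null(genome)) {
      tracts <- find_polyA_tracts(genome, motif_len = cfg$polyA_motif_len,
                                  max_mismatch = cfg$polyA_max_mismatch)
      tes_tracks <- lapply(tes_tracks, filter_internal_priming,
                           tracts = tracts, max_dist = cfg$priming_dist)
    }
    tes_clusters <- cluster_stage(tes_tracks, "TES")
    tes_assignments <- assign_clusters(tes_clusters, genes, rna_coverage,
                                       max_near = cfg$assign_near,
                                       max_far = cfg$assign_far,
                                       window = cfg$window,
                                       median_frac = cfg$tes_median_frac,
                                       max_mult = cfg$tes_max_mult)
  }

  assignments <- assign_clusters(tss_clusters, genes, rna_coverage,
                                 max_near = cfg$assign_near,
                                 max_far = cfg$assign_far,
                                 window = cfg$window)
  usage <- usage_table(tss_clusters, assignments, sample_info, transition,
                       min_tpm = cfg$min_tpm)
  diff <- diff_expression(tss_clusters, sample_info, transition,
                          lfc_threshold = cfg$lfc_threshold,
                          alpha = cfg$alpha, pseudo = cfg$pseudo)
  pairs <- build_pairs(tss_clusters, assignments, usage)
  ev <- switching_events(pairs, diff, tss_clusters, sample_info, transition,
                         dominance_ratio = cfg$dominance_ratio)
  internal <- NULL
  if (!is.null(genome))
    internal <- internal_tss_calls(tss_clusters, assignments, usage, diff,
                                   sample_info, genes, genome,
                                   fraction = cfg$internal_fraction,
                                   min_orf_len = cfg$min_orf_len)
  tpm_tp <- tpm_by_timepoint(tss_clusters, sample_info)
  determinants <- build_determinant_table(pairs, diff, tpm_tp, transition,
                                          occupancy = occupancy,
                                          pseudo = cfg$pseudo,
                                          seed = cfg$seed)
  regression <- NULL
  if (nrow(determinants) > 10 &&
      sum(stats::complete.cases(determinants[c("main_log2fc", "alt_level",
                                               "pair_distance",
                                               "occupancy_change")])) > 10)
    regression <- tryCatch(fit_multiple_regression(determinants),
                           error = function(e) NULL)
  bundle <- list(tss_clusters = tss_clusters, tes_clusters = tes_clusters,
                 spurious = spurious, assignments = assignments,
                 tes_assignments = tes_assignments, usage = usage,
                 diff = diff, pairs = pairs, events = ev$events,
                 gene_events = ev$genes, internal = internal,
                 determinants = determinants, regression = regression)
  if (!is.null(out_dir)) {
    tabs <- list(tss_clusters = tss_clusters$clusters,
                 assignments = assignments, usage = usage, diff = diff,
                 pairs = pairs, events = ev$events, gene_events = ev$genes,
                 determinants = determinants)
    if (!is.null(spurious)) tabs$spurious <- spurious
    if (!is.null(internal)) tabs$internal <- internal
    if (!is.null(tes_clusters)) tabs$tes_clusters <- tes_clusters$clusters
    if (!is.null(tes_assignments)) tabs$tes_assignments <- tes_assignments
    write_results(tabs, out_dir)
  }
  bundle
}

#' Mutant-versus-control TSS de-repression analysis
#'
#' Calls consensus TSS clusters per genotype, maps mutant clusters onto
#' control clusters by overlap, assigns control clusters to genes, builds
#' per-gene replicate-stratified contingency stacks of raw main versus
#' summed-alternative counts, and applies the CMH test and the
#' de-repression criteria.
#'
#' @param control_tracks,mutant_tracks named lists of raw TSS
#'   `end_track`s (replicates pair by index).
#' @param genes `gene_models` data.frame.
#' @param rna_coverage `coverage_track` for assignment windows.
#' @param control_repressed_genes gene ids repressed by upstream
#'   alternative transcription in control cells (see
#'   [call_derepression()]).
#' @param main_site optional named vector gene_id -> genomic apex of the
#'   gene's pre-meiotic main TSS (defined at the earlier stage); the
#'   gene's cluster containing that position becomes the main. Without
#'   it, the main falls back to the highest mean control TPM.
#' @param config parameter list from [default_config()].
#' @return List: `control_clusters`, `mutant_clusters`, `mapping`,
#'   `assignments`, `results` (the [call_derepression()] table).
#' @export
run_mutant_analysis <- function(control_tracks, mutant_tracks, genes,
                                rna_coverage, control_repressed_genes,
                                main_site = NULL,
                                config = default_config()) {
  cfg <- config
  stage <- function(raw_tracks) {
    tpm_tracks <- lapply(raw_tracks, normalize_tpm)
    per_sample <- lapply(tpm_tracks, call_tag_clusters,
                         max_dist = cfg$max_dist_tag,
                         singleton_floor_tpm = cfg$singleton_floor_tpm)
    aggregate_clusters(per_sample, pool_tpm(tpm_tracks),
                       tpm_tracks = tpm_tracks, raw_tracks = raw_tracks,
                       tpm_threshold = cfg$tpm_threshold, q_low = cfg$q_low,
                       q_up = cfg$q_up, max_dist = cfg$max_dist_agg,
                       kind = "TSS")
  }
  control_clusters <- stage(control_tracks)
  mutant_clusters <- stage(mutant_tracks)
  mapping <- map_clusters(mutant_clusters, control_clusters)
  assignments <- assign_clusters(control_clusters, genes, rna_coverage,
                                 max_near = cfg$assign_near,
                                 max_far = cfg$assign_far,
                                 window = cfg$window)
  # raw counts in both genotypes over the control cluster intervals
  control_counts <- cluster_sample_matrix(control_clusters$clusters,
                                          control_tracks, "count")
  mutant_counts <- cluster_sample_matrix(control_clusters$clusters,
                                         mutant_tracks, "count")
  # main TSS per gene: the cluster holding the pre-meiotic main site when
  # supplied, else the highest mean control TPM (>= min_tpm)
  mean_tpm <- rowMeans(control_clusters$tpm)
  ctab <- merge(control_clusters$clusters, assignments, by = "cluster_id")
  gene_clusters <- lapply(split(ctab, ctab$gene_id), function(gc) {
    tpms <- mean_tpm[gc$cluster_id]
    ok <- tpms >= cfg$min_tpm
    if (!any(ok)) return(list(main = NA_character_, alts = character(0)))
    main <- NA_character_
    site <- if (!is.null(main_site)) main_site[gc$gene_id[1]] else NA
    if (!is.na(site)) {
      hit <- which(gc$start <= site & site < gc$end)
      if (length(hit)) main <- gc$cluster_id[hit[1]]
    }
    if (is.na(main)) {
      cand <- which(ok & tpms == max(tpms[ok]))
      if (length(cand) > 1) {
        key <- if (gc$strand[1] == "+") gc$apex[cand] else -gc$apex[cand]
        cand <- cand[order(key)]
      }
      main <- gc$cluster_id[cand[1]]
    }
    alts <- setdiff(gc$cluster_id[ok], main)
    list(main = main, alts = alts)
  })
  stacks <- contingency_stacks(gene_clusters, control_counts, mutant_counts)
  results <- call_derepression(stacks, control_repressed_genes,
                               alpha = cfg$alpha)
  list(control_clusters = control_clusters, mutant_clusters = mutant_clusters,
       mapping = mapping, assignments = assignments, results = results)
}
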