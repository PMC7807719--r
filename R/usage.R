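#' Transition configuration
#'
#' A cell-fate transition is keyed by timepoint labels: one reference
#' timepoint (the state before the transition, at which the main cluster is
#' defined) and an ordered set of transition timepoints compared against it.
#'
#' @param name transition label (e.g. "T1").
#' @param reference reference timepoint label.
#' @param timepoints character vector of transition timepoint labels.
#' @return A list of class `transition_config`.
#' @export
transition_config <- function(name, reference, timepoints) {
  if (reference %in% timepoints)
    stop("reference timepoint must not be among transition timepoints")
  structure(list(name = name, reference = reference, timepoints = timepoints),
            class = "transition_config")
}

#' Per-timepoint TPM of clusters (replicate means)
#'
#' Collapses a clusters-by-samples TPM matrix to clusters-by-timepoints by
#' averaging replicates, using a sample table mapping sample ids to
#' timepoint labels.
#'
#' @param clusters a `site_clusters` object.
#' @param sample_info data.frame with columns `sample_id`, `timepoint`.
#' @return Matrix clusters x timepoints.
#' @export
tpm_by_timepoint <- function(clusters, sample_info) {
  tps <- unique(sample_info$timepoint)
  m <- sapply(tps, function(tp) {
    s <- sample_info$sample_id[sample_info$timepoint == tp]
    s <- intersect(s, colnames(clusters$tpm))
    rowMeans(clusters$tpm[, s, drop = FALSE])
  })
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(rownames(clusters$tpm), tps))
  m
}

#' Define the main cluster of a gene for a transition
#'
#' The main TSS/TES is the gene's cluster with the highest TPM at the
#' transition's reference timepoint, provided that TPM is at least
#' `min_tpm`; equal TPMs break to the 5'-most apex. When no cluster
#' qualifies the gene has no main for this transition.
#'
#' @param gene_clusters data.frame of the gene's clusters (rows of a
#'   `site_clusters` table, same kind).
#' @param tpm_tp clusters x timepoints TPM matrix (rows named by
#'   cluster_id).
#' @param config a `transition_config`.
#' @param min_tpm reference-timepoint TPM floor (default 1).
#' @return cluster_id of the main cluster, or NA.
#' @export
define_main <- function(gene_clusters, tpm_tp, config, min_tpm = 1) {
  if (!nrow(gene_clusters)) return(NA_character_)
  ref <- tpm_tp[gene_clusters$cluster_id, config$reference]
  ok <- which(ref >= min_tpm)
  if (!length(ok)) return(NA_character_)
  best <- ok[ref[ok] == max(ref[ok])]
  if (length(best) > 1) {
    key <- if (gene_clusters$strand[1] == "+") gene_clusters$apex[best]
           else -gene_clusters$apex[best]
    best <- best[order(key)]
  }
  gene_clusters$cluster_id[best[1]]
}

#' Define the alternative clusters of a gene for a transition
#'
#' Every non-main cluster of the gene that reaches `min_tpm` TPM at one or
#' more of the transition's timepoints (reference included) is alternative.
#'
#' @inheritParams define_main
#' @param main cluster_id of the main cluster (or NA).
#' @return Character vector of alternative cluster_ids.
#' @export
define_alternatives <- function(gene_clusters, main, tpm_tp, config,
                                min_tpm = 1) {
  ids <- setdiff(gene_clusters$cluster_id, main)
  if (!length(ids)) return(character(0))
  tps <- c(config$reference, config$timepoints)
  sub <- tpm_tp[ids, tps, drop = FALSE]
  ids[apply(sub, 1, max) >= min_tpm]
}

#' Alternative-usage ratio
#'
#' The fraction of a gene's main-plus-alternative signal carried by the
#' alternatives: alt / (alt + main). Undefined (NA) when both are zero.
#' When a gene has several alternatives, `alt_tpm_sum` is their TPM sum.
#'
#' @param alt_tpm_sum summed alternative TPM.
#' @param main_tpm main-cluster TPM.
#' @return Numeric in [0, 1], or NA.
#' @export
alt_usage <- function(alt_tpm_sum, main_tpm) {
  tot <- alt_tpm_sum + main_tpm
  ifelse(tot > 0, alt_tpm_sum / tot, NA_real_)
}

#' Change in alternative usage across a transition
#'
#' @param usage_at_transition usage ratio at a transition timepoint.
#' @param usage_prior usage ratio at the reference timepoint.
#' @return Difference in [-1, 1]; NA when either side is undefined.
#' @export
alt_usage_change <- function(usage_at_transition, usage_prior) {
  usage_at_transition - usage_prior
}

#' Build the per-gene usage table for a transition
#'
#' For each gene with an assigned main cluster: the main and alternative
#' cluster ids, per-timepoint TPM, usage ratios and usage changes
#' (transition minus reference). Genes whose main cannot be defined at the
#' reference are excluded.
#'
#' @param clusters a `site_clusters` object.
#' @param assignments assignment table from [assign_clusters()].
#' @param sample_info data.frame `sample_id`, `timepoint`.
#' @param config a `transition_config`.
#' @param min_tpm TPM floor for main/alternative definitions.
#' @return data.frame, one row per gene x timepoint with columns `gene_id`,
#'   `transition`, `timepoint`, `main_cluster`, `alt_clusters`
#'   (comma-joined), `main_tpm`, `alt_tpm`, `alt_usage`,
#'   `alt_usage_change`.
#' @export
usage_table <- function(clusters, assignments, sample_info, config,
                        min_tpm = 1) {
  tpm_tp <- tpm_by_timepoint(clusters, sample_info)
  tab <- merge(clusters$clusters, assignments, by = "cluster_id")
  rows <- lapply(split(tab, tab$gene_id), function(gc) {
    main <- define_main(gc, tpm_tp, config, min_tpm)
    if (is.na(main)) return(NULL)
    alts <- define_alternatives(gc, main, tpm_tp, config, min_tpm)
    tps <- c(config$reference, config$timepoints)
    main_tpm <- tpm_tp[main, tps]
    alt_tpm <- if (length(alts)) colSums(tpm_tp[alts, tps, drop = FALSE])
               else stats::setNames(rep(0, length(tps)), tps)
    usage <- alt_usage(alt_tpm, main_tpm)
    data.frame(gene_id = gc$gene_id[1], transition = config$name,
               timepoint = tps, main_cluster = main,
               alt_clusters = paste(alts, collapse = ","),
               main_tpm = as.numeric(main_tpm), alt_tpm = as.numeric(alt_tpm),
               alt_usage = as.numeric(usage),
               alt_usage_change = as.numeric(usage) -
                 as.numeric(usage[config$reference]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), transition = character(),
                      timepoint = character(), main_cluster = character(),
                      alt_clusters = character(), main_tpm = numeric(),
                      alt_tpm = numeric(), alt_usage = numeric(),
                      alt_usage_change = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
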