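#' Build upstream-alternative / main TSS pairs
#'
#' One pair per (gene, external upstream alternative): the alternative's
#' apex must lie strictly upstream of the main apex on the gene strand and
#' outside the ORF; internal alternatives are excluded here (they are
#' handled by the internal-isoform analyses).
#'
#' @param clusters a TSS `site_clusters` object.
#' @param assignments assignment table from [assign_clusters()].
#' @param usage usage table from [usage_table()] for one transition.
#' @return data.frame: `gene_id`, `transition`, `alt_cluster`,
#'   `main_cluster`, `pair_distance` (apex-to-apex nt, > 0).
#' @export
build_pairs <- function(clusters, assignments, usage) {
  ctab <- clusters$clusters
  apex <- stats::setNames(ctab$apex, ctab$cluster_id)
  strand <- stats::setNames(ctab$strand, ctab$cluster_id)
  cat_by_cl <- stats::setNames(assignments$category, assignments$cluster_id)
  genes <- unique(usage[c("gene_id", "transition", "main_cluster", "alt_clusters")])
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    main <- genes$main_cluster[i]
    alts <- strsplit(genes$alt_clusters[i], ",", fixed = TRUE)[[1]]
    alts <- alts[nzchar(alts)]
    if (!length(alts)) return(NULL)
    alts <- alts[cat_by_cl[alts] == "upstream"]
    if (!length(alts)) return(NULL)
    dist <- if (strand[main] == "+") apex[main] - apex[alts]
            else apex[alts] - apex[main]
    alts <- alts[dist > 0]; dist <- dist[dist > 0]
    if (!length(alts)) return(NULL)
    data.frame(gene_id = genes$gene_id[i], transition = genes$transition[i],
               alt_cluster = alts, main_cluster = main,
               pair_distance = as.integer(dist), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), transition = character(),
                      alt_cluster = character(), main_cluster = character(),
                      pair_distance = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

de_lookup <- function(diff, cluster, timepoint) {
  row <- diff[diff$cluster_id == cluster & diff$timepoint == timepoint, ]
  if (!nrow(row)) return(NULL)
  row[1, ]
}

#' Classify the main-TSS response to alternative upregulation
#'
#' Evaluated only at timepoints where the upstream alternative is
#' significantly upregulated (log2fc >= 1, padj < 0.05). The paired main
#' TSS responds "down" when its own change is significantly twofold down,
#' "up" when significantly twofold up, otherwise "unchanged".
#'
#' @param pair one row of [build_pairs()] output.
#' @param diff DE table from [diff_expression()].
#' @param timepoint transition timepoint label.
#' @return "down", "up", "unchanged", or NA when the alternative is not
#'   significantly up at this timepoint.
#' @export
classify_main_response <- function(pair, diff, timepoint) {
  alt <- de_lookup(diff, pair$alt_cluster, timepoint)
  if (is.null(alt) || !alt$significant_up) return(NA_character_)
  main <- de_lookup(diff, pair$main_cluster, timepoint)
  if (is.null(main)) return("unchanged")
  if (main$significant_down) "down" else if (main$significant_up) "up"
  else "unchanged"
}

#' Detect a TSS switching event
#'
#' A switch is counted at a timepoint when the upstream alternative is
#' upregulated twofold or more (padj < 0.05) and its TPM at that timepoint
#' reaches at least the paired main TSS's TPM.
#'
#' @param pair one row of [build_pairs()] output.
#' @param diff DE table.
#' @param tpm_tp clusters x timepoints TPM matrix.
#' @param timepoint transition timepoint label.
#' @param dominance_ratio alternative must reach `dominance_ratio` x main
#'   TPM (default 1).
#' @return Logical.
#' @export
detect_switch <- function(pair, diff, tpm_tp, timepoint, dominance_ratio = 1) {
  alt <- de_lookup(diff, pair$alt_cluster, timepoint)
  if (is.null(alt) || !alt$significant_up) return(FALSE)
  tpm_tp[pair$alt_cluster, timepoint] >=
    dominance_ratio * tpm_tp[pair$main_cluster, timepoint]
}

#' Detect co-downregulation of an alternative/main pair
#'
#' TRUE when both the alternative and the main TSS are significantly
#' twofold down at the timepoint.
#'
#' @inheritParams detect_switch
#' @export
detect_codownregulation <- function(pair, diff, timepoint) {
  alt <- de_lookup(diff, pair$alt_cluster, timepoint)
  main <- de_lookup(diff, pair$main_cluster, timepoint)
  !is.null(alt) && !is.null(main) && alt$significant_down && main$significant_down
}

#' Internal-to-promoter (and reverse) switching
#'
#' Applies the switching conditions to a gene's dominant internal cluster
#' and a promoter (external upstream) cluster, in either direction: the
#' rising cluster must be significantly twofold up and reach the other's
#' TPM at the timepoint. The direction of the event is recorded.
#'
#' @param internal_cluster,promoter_cluster cluster ids.
#' @param diff DE table.
#' @param tpm_tp clusters x timepoints TPM matrix.
#' @param timepoint transition timepoint label.
#' @return One-row data.frame: `is_switch`, `direction`
#'   ("internal_to_promoter", "promoter_to_internal", or NA).
#' @export
internal_to_promoter_switch <- function(internal_cluster, promoter_cluster,
                                        diff, tpm_tp, timepoint) {
  up_dir <- function(riser, other, direction) {
    de <- de_lookup(diff, riser, timepoint)
    if (!is.null(de) && de$significant_up &&
        tpm_tp[riser, timepoint] >= tpm_tp[other, timepoint])
      direction else NA_character_
  }
  d1 <- up_dir(promoter_cluster, internal_cluster, "internal_to_promoter")
  d2 <- up_dir(internal_cluster, promoter_cluster, "promoter_to_internal")
  dir <- if (!is.na(d1)) d1 else d2
  data.frame(is_switch = !is.na(dir), direction = dir, stringsAsFactors = FALSE)
}

#' Per-pair event table across a transition
#'
#' Evaluates [classify_main_response()], [detect_switch()] and
#' [detect_codownregulation()] for every pair at every transition
#' timepoint, then aggregates to transition level per gene (an event fired
#' if it fired at any timepoint).
#'
#' @param pairs [build_pairs()] output.
#' @param diff DE table from [diff_expression()].
#' @param clusters the TSS `site_clusters`.
#' @param sample_info data.frame `sample_id`, `timepoint`.
#' @param config a `transition_config`.
#' @param dominance_ratio see [detect_switch()].
#' @return List with `events` (pair x timepoint rows) and `genes`
#'   (per-gene transition-level summary: `any_switch`, `any_codown`,
#'   `response` = down > up > unchanged precedence over fired timepoints).
#' @export
switching_events <- function(pairs, diff, clusters, sample_info, config,
                             dominance_ratio = 1) {
  tpm_tp <- tpm_by_timepoint(clusters, sample_info)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    for (tp in config$timepoints) {
      pr <- pairs[i, ]
      resp <- classify_main_response(pr, diff, tp)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = pr$gene_id, transition = pr$transition, timepoint = tp,
        alt_cluster = pr$alt_cluster, main_cluster = pr$main_cluster,
        pair_distance = pr$pair_distance,
        main_response = resp,
        is_switch = detect_switch(pr, diff, tpm_tp, tp, dominance_ratio),
        codown = detect_codownregulation(pr, diff, tp),
        stringsAsFactors = FALSE)
    }
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), transition = character(),
               timepoint = character(), alt_cluster = character(),
               main_cluster = character(), pair_distance = integer(),
               main_response = character(), is_switch = logical(),
               codown = logical(), stringsAsFactors = FALSE)
  genes <- do.call(rbind, lapply(split(events, events$gene_id), function(e) {
    resp <- e$main_response[!is.na(e$main_response)]
    data.frame(gene_id = e$gene_id[1], transition = e$transition[1],
               any_switch = any(e$is_switch), any_codown = any(e$codown),
               response = if (!length(resp)) NA_character_
                          else if (any(resp == "down")) "down"
                          else if (any(resp == "up")) "up" else "unchanged",
               stringsAsFactors = FALSE)
  }))
  if (is.null(genes))
    genes <- data.frame(gene_id = character(), transition = character(),
                        any_switch = logical(), any_codown = logical(),
                        response = character(), stringsAsFactors = FALSE)
  rownames(events) <- rownames(genes) <- NULL
  list(events = events, genes = genes)
}
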