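#' Map mutant clusters onto control clusters
#'
#' A mutant cluster maps to a control cluster when their intervals overlap
#' by at least 1 bp on the same strand and contig; many-to-one overlaps
#' resolve to the control cluster with the largest overlap (ties to the
#' 5'-most control cluster on the strand). Unmapped mutant clusters are
#' retained as mutant-only and can be gene-assigned de novo.
#'
#' @param mutant_clusters,control_clusters `site_clusters` objects.
#' @return data.frame: `mutant_cluster`, `control_cluster` (NA when
#'   mutant-only), `overlap` (bp).
#' @export
map_clusters <- function(mutant_clusters, control_clusters) {
  m <- mutant_clusters$clusters
  ctl <- control_clusters$clusters
  rows <- lapply(seq_len(nrow(m)), function(i) {
    cand <- ctl[ctl$contig == m$contig[i] & ctl$strand == m$strand[i], ,
                drop = FALSE]
    ov <- pmin(cand$end, m$end[i]) - pmax(cand$start, m$start[i])
    hit <- which(ov >= 1L)
    if (!length(hit))
      return(data.frame(mutant_cluster = m$cluster_id[i],
                        control_cluster = NA_character_, overlap = 0L,
                        stringsAsFactors = FALSE))
    best <- hit[ov[hit] == max(ov[hit])]
    if (length(best) > 1) {
      key <- if (m$strand[i] == "+") cand$start[best] else -cand$end[best]
      best <- best[order(key)]
    }
    data.frame(mutant_cluster = m$cluster_id[i],
               control_cluster = cand$cluster_id[best[1]],
               overlap = as.integer(ov[best[1]]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(mutant_cluster = character(),
                      control_cluster = character(), overlap = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Relative main-TSS usage of a gene in one sample
#'
#' The main cluster's TPM divided by the summed TPM of all clusters
#' assigned to the gene; in [0, 1], undefined when the total is zero.
#' Invariant under library rescaling.
#'
#' @param main_tpm main cluster TPM.
#' @param all_tpm vector of all the gene's cluster TPMs (main included).
#' @return Numeric, or NA.
#' @export
relative_main_usage <- function(main_tpm, all_tpm) {
  tot <- sum(all_tpm)
  if (tot <= 0) return(NA_real_)
  main_tpm / tot
}

#' Cochran-Mantel-Haenszel test on a stratified 2x2 stack
#'
#' Strata are replicates; each stratum is a 2x2 table with rows
#' {main reads, summed alternative reads} and columns {control, mutant}.
#' The statistic is (|sum_k (a_k - E_k)| - 1/2 * continuity)^2 / sum_k V_k
#' with a_k the main/control cell and E_k, V_k the mean and variance of
#' the stratum's hypergeometric distribution under its margins; p comes
#' from the chi-square distribution with 1 df. Strata with a zero row or
#' column margin carry no information and are dropped with a warning.
#'
#' @param stack numeric array 2 x 2 x K of raw counts.
#' @param continuity apply the continuity correction (default TRUE,
#'   matching the conventional default).
#' @return List: `statistic`, `p`, `k_used`.
#' @export
cmh_test <- function(stack, continuity = TRUE) {
  stopifnot(length(dim(stack)) == 3, all(dim(stack)[1:2] == 2))
  K <- dim(stack)[3]
  a <- E <- V <- numeric(0)
  dropped <- 0L
  for (k in seq_len(K)) {
    t2 <- stack[, , k]
    n <- sum(t2)
    r1 <- sum(t2[1, ]); r2 <- sum(t2[2, ])
    c1 <- sum(t2[, 1]); c2 <- sum(t2[, 2])
    if (n == 0 || r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
      dropped <- dropped + 1L
      next
    }
    a <- c(a, t2[1, 1])
    E <- c(E, r1 * c1 / n)
    V <- c(V, r1 * r2 * c1 * c2 / (n^2 * (n - 1)))
  }
  if (dropped > 0L)
    warning(sprintf("%d degenerate stratum/strata dropped", dropped))
  if (!length(a) || sum(V) == 0)
    return(list(statistic = NA_real_, p = NA_real_, k_used = length(a)))
  delta <- abs(sum(a) - sum(E))
  # the correction only applies when the deviation can absorb it, matching
  # the conventional implementation
  dev <- delta - if (continuity && delta >= 0.5) 0.5 else 0
  stat <- dev^2 / sum(V)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       k_used = length(a))
}

#' Build per-gene contingency stacks from count matrices
#'
#' For each gene with a defined main cluster and at least one alternative:
#' per replicate, the 2x2 table of raw main vs summed-alternative counts
#' in control and mutant.
#'
#' @param gene_clusters named list gene_id -> list(main = cluster_id,
#'   alts = cluster_ids).
#' @param control_counts,mutant_counts clusters x replicates raw-count
#'   matrices (same replicate order; replicates pair by index).
#' @return Named list gene_id -> 2 x 2 x K array.
#' @export
contingency_stacks <- function(gene_clusters, control_counts, mutant_counts) {
  K <- ncol(control_counts)
  stopifnot(ncol(mutant_counts) == K)
  out <- lapply(gene_clusters, function(g) {
    if (is.na(g$main) || !length(g$alts)) return(NULL)
    arr <- array(0, dim = c(2, 2, K),
                 dimnames = list(c("main", "alt"), c("control", "mutant"), NULL))
    for (k in seq_len(K)) {
      arr[1, 1, k] <- control_counts[g$main, k]
      arr[1, 2, k] <- mutant_counts[g$main, k]
      arr[2, 1, k] <- sum(control_counts[g$alts, k])
      arr[2, 2, k] <- sum(mutant_counts[g$alts, k])
    }
    arr
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Call de-repressed genes in a mutant
#'
#' Per gene: the CMH test across replicate strata, BH adjustment across
#' genes, pooled main-usage proportions in control and mutant, the
#' increased-relative-expression call (padj < alpha and a larger main
#' proportion in the mutant), and the de-repression call (additionally the
#' gene's main TSS was significantly down in control cells while an
#' upstream alternative was significantly up — i.e. the gene appears in
#' `control_repressed_genes`). De-repressed genes form a subset of the
#' increased-relative-expression genes by construction.
#'
#' @param stacks named list of 2 x 2 x K contingency arrays (see
#'   [contingency_stacks()]).
#' @param control_repressed_genes gene ids whose main TSS is repressed by
#'   upstream alternative transcription in control cells (from
#'   [switching_events()] at the same stage: response "down").
#' @param alpha FDR threshold (default 0.05).
#' @param continuity see [cmh_test()].
#' @return data.frame, one row per gene, with `cmh_statistic`, `p`,
#'   `padj`, `main_usage_control`, `main_usage_mutant`,
#'   `increased_relative_expression`, `derepressed`.
#' @export
call_derepression <- function(stacks, control_repressed_genes,
                              alpha = 0.05, continuity = TRUE) {
  rows <- lapply(names(stacks), function(g) {
    st <- stacks[[g]]
    res <- suppressWarnings(cmh_test(st, continuity = continuity))
    ctl_main <- sum(st[1, 1, ]); ctl_tot <- sum(st[, 1, ])
    mut_main <- sum(st[1, 2, ]); mut_tot <- sum(st[, 2, ])
    data.frame(gene_id = g, cmh_statistic = res$statistic, p = res$p,
               main_usage_control = if (ctl_tot > 0) ctl_main / ctl_tot else NA_real_,
               main_usage_mutant = if (mut_tot > 0) mut_main / mut_tot else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- adjust_bh(out$p)
  out$increased_relative_expression <- !is.na(out$padj) & out$padj < alpha &
    !is.na(out$main_usage_mutant) & !is.na(out$main_usage_control) &
    out$main_usage_mutant > out$main_usage_control
  out$derepressed <- out$increased_relative_expression &
    out$gene_id %in% control_repressed_genes
  rownames(out) <- NULL
  out[c("gene_id", "cmh_statistic", "p", "padj", "main_usage_control",
        "main_usage_mutant", "increased_relative_expression", "derepressed")]
}
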