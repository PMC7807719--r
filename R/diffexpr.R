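#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over clusters (those with
#' positive geometric mean across samples) of the cluster's count divided
#' by its across-sample geometric mean.
#'
#' @param count_matrix clusters x samples raw counts.
#' @return Named numeric vector of per-sample factors.
#' @export
size_factors <- function(count_matrix) {
  stopifnot(ncol(count_matrix) >= 2)
  logs <- log(count_matrix)
  geo <- exp(rowMeans(logs))
  ok <- is.finite(geo) & geo > 0
  if (!any(ok))
    stop("no cluster is nonzero in every sample; consider a pseudo-reference fallback")
  apply(count_matrix[ok, , drop = FALSE], 2, function(col) stats::median(col / geo[ok]))
}

#' Differential test for one cluster
#'
#' A simplified per-cluster test: counts are divided by their sample size
#' factors, the log2 fold change is log2 of the ratio of condition means
#' after adding a pseudo-count, and the p-value comes from a two-sided
#' Welch t-test on the log2(normalized + pseudo-count) replicate values.
#' An externally computed DE table (e.g. from a negative-binomial engine)
#' can replace these results downstream via [import_de_table()].
#'
#' @param counts_T,counts_ref raw replicate count vectors for the
#'   transition timepoint and the reference.
#' @param factors_T,factors_ref matching size factors.
#' @param pseudo pseudo-count on the normalized scale (default 0.5).
#' @return One-row data.frame: `log2fc`, `p`.
#' @export
test_cluster <- function(counts_T, counts_ref, factors_T, factors_ref,
                         pseudo = 0.5) {
  nT <- counts_T / factors_T
  nR <- counts_ref / factors_ref
  log2fc <- log2((mean(nT) + pseudo) / (mean(nR) + pseudo))
  p <- NA_real_
  if (length(nT) >= 2 && length(nR) >= 2) {
    lT <- log2(nT + pseudo); lR <- log2(nR + pseudo)
    if (stats::var(lT) + stats::var(lR) == 0) {
      p <- if (isTRUE(all.equal(mean(lT), mean(lR)))) 1 else 0
    } else {
      p <- stats::t.test(lT, lR)$p.value
    }
  }
  data.frame(log2fc = log2fc, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment over the non-missing p-values;
#' missing entries stay missing.
#'
#' @param p_values numeric vector in [0, 1] (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-cluster differential expression for all transition comparisons
#'
#' Each transition timepoint is compared against the transition's reference
#' using [test_cluster()] over replicates, with one BH adjustment per
#' comparison. Significance calls follow a fold-change-and-FDR rule:
#' significantly up means log2fc >= `lfc_threshold` and padj <
#' `alpha`; significantly down is symmetric.
#'
#' @param clusters a `site_clusters` object carrying a raw `counts` matrix.
#' @param sample_info data.frame `sample_id`, `timepoint`.
#' @param config a `transition_config`.
#' @param lfc_threshold log2 fold-change threshold (default 1, i.e.
#'   twofold).
#' @param alpha FDR threshold (default 0.05).
#' @param pseudo pseudo-count for [test_cluster()].
#' @return data.frame: `cluster_id`, `timepoint`, `log2fc`, `p`, `padj`,
#'   `significant_up`, `significant_down`.
#' @export
diff_expression <- function(clusters, sample_info, config, lfc_threshold = 1,
                            alpha = 0.05, pseudo = 0.5) {
  counts <- clusters$counts
  if (is.null(counts)) stop("site_clusters carries no raw count matrix")
  sf <- size_factors(counts)
  ref_s <- sample_info$sample_id[sample_info$timepoint == config$reference]
  out <- lapply(config$timepoints, function(tp) {
    tp_s <- sample_info$sample_id[sample_info$timepoint == tp]
    res <- do.call(rbind, lapply(rownames(counts), function(cl)
      test_cluster(counts[cl, tp_s], counts[cl, ref_s], sf[tp_s], sf[ref_s],
                   pseudo = pseudo)))
    res$cluster_id <- rownames(counts)
    res$timepoint <- tp
    res$padj <- adjust_bh(res$p)
    res
  })
  out <- do.call(rbind, out)
  out$significant_up <- !is.na(out$padj) & out$log2fc >= lfc_threshold &
    out$padj < alpha
  out$significant_down <- !is.na(out$padj) & out$log2fc <= -lfc_threshold &
    out$padj < alpha
  out[c("cluster_id", "timepoint", "log2fc", "p", "padj",
        "significant_up", "significant_down")]
}

#' Import an external differential-expression table
#'
#' Accepts a table produced by an external DE engine (columns `cluster_id`,
#' `timepoint`, `log2fc`, `padj`) and recomputes the significance flags so
#' it can stand in for [diff_expression()] output.
#'
#' @param tab data.frame or TSV path.
#' @param lfc_threshold,alpha thresholds as in [diff_expression()].
#' @export
import_de_table <- function(tab, lfc_threshold = 1, alpha = 0.05) {
  if (is.character(tab)) tab <- read_results_tsv(tab)
  need <- c("cluster_id", "timepoint", "log2fc", "padj")
  if (!all(need %in% names(tab)))
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  tab$significant_up <- !is.na(tab$padj) & tab$log2fc >= lfc_threshold &
    tab$padj < alpha
  tab$significant_down <- !is.na(tab$padj) & tab$log2fc <= -lfc_threshold &
    tab$padj < alpha
  tab
}
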