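#' Flag a spurious TSS cluster with the non-decapping control
#'
#' Genuine capped 5' ends disappear when the decapping step is omitted, so a
#' cluster whose base-wise raw counts correlate with the matched
#' non-decapping control across the cluster window (cluster +/- `flank` bp)
#' is flagged as spurious. Correlation is Spearman's on raw counts with
#' average ranks for ties and a large-sample t approximation for the
#' p-value; a constant vector on either side leaves the correlation
#' undefined and the cluster is kept (a spurious call requires positive
#' evidence).
#'
#' @param cluster one row of a TSS `site_clusters` table.
#' @param decapped the decapped (regular TSS-seq) reference raw `end_track`.
#' @param nondecapped the non-decapping control raw `end_track`.
#' @param flank bp added on each side of the cluster (default 5).
#' @param r_threshold,p_threshold spurious when r > `r_threshold` and
#'   p < `p_threshold`.
#' @return data.frame row: `cluster_id`, `spearman_r`, `p_value`, `spurious`.
#' @export
flag_spurious_tss <- function(cluster, decapped, nondecapped, flank = 5,
                              r_threshold = 0.5, p_threshold = 0.05) {
  win <- seq.int(cluster$start - flank, cluster$end + flank - 1L)
  win <- win[win >= 0]
  x <- track_values_at(decapped, cluster$contig, cluster$strand, win, "count")
  y <- track_values_at(nondecapped, cluster$contig, cluster$strand, win, "count")
  r <- NA_real_; p <- NA_real_
  if (stats::var(x) > 0 && stats::var(y) > 0) {
    r <- stats::cor(x, y, method = "spearman")
    n <- length(x)
    if (abs(r) < 1) {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    } else p <- 0
  }
  data.frame(cluster_id = cluster$cluster_id,
             spearman_r = r, p_value = p,
             spurious = !is.na(r) && r > r_threshold && !is.na(p) && p < p_threshold,
             stringsAsFactors = FALSE)
}

#' Screen all TSS clusters against the non-decapping control
#'
#' @param clusters a TSS `site_clusters` object.
#' @param decapped,nondecapped reference raw tracks (see
#'   [flag_spurious_tss()]).
#' @param ... passed to [flag_spurious_tss()].
#' @return data.frame with one row per cluster.
#' @export
flag_spurious_all <- function(clusters, decapped, nondecapped, ...) {
  tab <- clusters$clusters
  do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
    flag_spurious_tss(tab[i, ], decapped, nondecapped, ...)))
}

#' Find genomic poly(A) tracts
#'
#' Every 20-nt window with at most `max_mismatch` mismatches to the
#' strand-appropriate homopolymer (A-runs on "+", T-runs on "-", as read on
#' the reference) is a priming-prone window; overlapping qualifying windows
#' are merged into maximal tracts. These tracts mark templated A-stretches
#' where oligo-dT priming fabricates 3'-end signal.
#'
#' @param genome named character vector of contig sequences.
#' @param motif_len window length (nt).
#' @param max_mismatch maximum non-A (non-T) bases per window.
#' @return data.frame: `contig`, `strand`, `start`, `end` (0-based
#'   half-open, merged tracts), `mismatches` (minimum over constituent
#'   windows).
#' @export
find_polyA_tracts <- function(genome, motif_len = 20, max_mismatch = 8) {
  if (motif_len <= 0) stop("motif_len must be positive")
  res <- list()
  for (contig in names(genome)) {
    bases <- strsplit(genome[[contig]], "")[[1]]
    n <- length(bases)
    if (n < motif_len) next
    for (strand in c("+", "-")) {
      target <- if (strand == "+") "A" else "T"
      is_mm <- as.integer(bases != target)
      cs <- c(0L, cumsum(is_mm))
      starts <- seq_len(n - motif_len + 1L) - 1L
      mm <- cs[starts + motif_len + 1L] - cs[starts + 1L]
      hit <- mm <= max_mismatch
      if (!any(hit)) next
      hs <- starts[hit]; hm <- mm[hit]
      brk <- c(TRUE, diff(hs) > motif_len - 1L + 1L)
      # windows overlap when next start <= prev start + motif_len - 1
      brk <- c(TRUE, hs[-1] > hs[-length(hs)] + motif_len - 1L)
      g <- cumsum(brk)
      res[[length(res) + 1L]] <- data.frame(
        contig = contig, strand = strand,
        start = as.integer(tapply(hs, g, min)),
        end = as.integer(tapply(hs, g, max)) + motif_len,
        mismatches = as.integer(tapply(hm, g, min)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(contig = character(), strand = character(),
                      start = integer(), end = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Remove 3'-end sites attributable to internal priming
#'
#' A 3'-end site is removed when a same-strand poly(A) tract overlaps it or
#' begins within `max_dist` nucleotides downstream of it (downstream in the
#' transcript's direction: increasing coordinates on "+", decreasing on
#' "-"). Applied to raw TES tracks before any cluster calling.
#'
#' @param track a TES `end_track` (or `tpm_track`).
#' @param tracts poly(A) tracts from [find_polyA_tracts()].
#' @param max_dist maximum gap (nt) between site and tract start.
#' @return The track with offending sites removed and `library_size`
#'   recomputed.
#' @export
filter_internal_priming <- function(track, tracts, max_dist = 5) {
  tab <- track$counts
  if (!nrow(tab) || !nrow(tracts)) return(track)
  drop <- logical(nrow(tab))
  for (k in seq_len(nrow(tracts))) {
    tr <- tracts[k, ]
    sel <- tab$contig == tr$contig & tab$strand == tr$strand
    if (!any(sel)) next
    pos <- tab$pos
    if (tr$strand == "+") {
      hit <- sel & ((pos >= tr$start & pos < tr$end) |
                      (pos < tr$start & tr$start - pos <= max_dist))
    } else {
      hit <- sel & ((pos >= tr$start & pos < tr$end) |
                      (pos >= tr$end & pos - (tr$end - 1L) <= max_dist))
    }
    drop <- drop | hit
  }
  end_track(tab[!drop, , drop = FALSE], sample_id = track$sample_id,
            timepoint = track$timepoint, replicate = track$replicate,
            kind = track$kind)
}
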