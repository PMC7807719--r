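#' Call per-sample tag clusters by distance
#'
#' Single-nucleotide end positions with nonzero TPM on the same contig and
#' strand are grouped whenever consecutive nonzero positions are at most
#' `max_dist` bases apart (p < q cluster together when q - p <= max_dist,
#' transitively). Groups of exactly one position are kept only when that
#' position's TPM reaches `singleton_floor_tpm` (inclusive). Untrimmed
#' boundaries span the group's min..max position, half-open.
#'
#' @param track a `tpm_track`.
#' @param max_dist maximum gap (nt) between neighbouring member positions.
#' @param singleton_floor_tpm minimum TPM for a single-position cluster.
#' @return data.frame with columns `contig`, `strand`, `start`, `end`,
#'   `tpm` (cluster total in this sample), `n_pos`.
#' @export
call_tag_clusters <- function(track, max_dist = 5, singleton_floor_tpm = 3) {
  stopifnot(inherits(track, "tpm_track"))
  if (max_dist < 0) stop("max_dist must be >= 0")
  tab <- track$counts[track$counts$tpm > 0, , drop = FALSE]
  if (!nrow(tab)) {
    return(data.frame(contig = character(), strand = character(),
                      start = integer(), end = integer(), tpm = numeric(),
                      n_pos = integer(), stringsAsFactors = FALSE))
  }
  tab <- tab[order(tab$contig, tab$strand, tab$pos), , drop = FALSE]
  grp_key <- paste(tab$contig, tab$strand, sep = "\r")
  new_grp <- c(TRUE, grp_key[-1] != grp_key[-nrow(tab)] |
                 tab$pos[-1] - tab$pos[-nrow(tab)] > max_dist)
  cl <- cumsum(new_grp)
  first <- !duplicated(cl)
  out <- data.frame(
    contig = tab$contig[first],
    strand = tab$strand[first],
    start = as.integer(tapply(tab$pos, cl, min)),
    end = as.integer(tapply(tab$pos, cl, max)) + 1L,
    tpm = as.numeric(tapply(tab$tpm, cl, sum)),
    n_pos = as.integer(tapply(tab$pos, cl, length)),
    stringsAsFactors = FALSE)
  out <- out[out$n_pos > 1L | out$tpm >= singleton_floor_tpm, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate per-sample tag clusters into consensus clusters
#'
#' Per-sample clusters whose total TPM reaches `tpm_threshold` in at least
#' one sample are merged across samples whenever their untrimmed spans are
#' within `max_dist` of each other (span gap, transitively). Each merged
#' cluster is trimmed to the smallest interval holding the pooled signal's
#' cumulative mass between `q_low` and `q_up` (positions walked 5' to 3' on
#' the cluster strand), its apex set to the position of maximal pooled TPM
#' inside the trimmed interval (ties to the 5'-most position), and
#' per-sample TPM (and raw counts, when the raw tracks are supplied)
#' recomputed over the trimmed interval.
#'
#' @param per_sample named list of per-sample cluster tables from
#'   [call_tag_clusters()].
#' @param pooled position-wise sum of the per-sample TPM tracks
#'   (see [pool_tpm()]).
#' @param tpm_tracks named list of the samples' `tpm_track`s (same names as
#'   `per_sample`) used to fill the per-sample TPM matrix.
#' @param raw_tracks optional named list of the samples' raw `end_track`s;
#'   when given, a per-sample raw-count matrix is attached.
#' @param tpm_threshold per-sample retention threshold (TPM).
#' @param q_low,q_up cumulative-mass quantiles for boundary trimming.
#' @param max_dist maximum span gap (nt) for cross-sample merging.
#' @param kind "TSS" or "TES", recorded on the result.
#' @return An object of class `site_clusters`: list with `clusters`
#'   (data.frame: cluster_id, contig, strand, start, end, apex, kind),
#'   `tpm` (clusters x samples matrix) and `counts` (same shape, or NULL).
#' @export
aggregate_clusters <- function(per_sample, pooled, tpm_tracks = NULL,
                               raw_tracks = NULL, tpm_threshold = 1,
                               q_low = 0.05, q_up = 0.95, max_dist = 20,
                               kind = c("TSS", "TES")) {
  kind <- match.arg(kind)
  if (q_low >= q_up) stop("q_low must be < q_up")
  stopifnot(inherits(pooled, "tpm_track"))
  if (is.null(names(per_sample)))
    names(per_sample) <- paste0("sample", seq_along(per_sample))
  samples <- names(per_sample)
  empty <- structure(list(
    clusters = data.frame(cluster_id = character(), contig = character(),
                          strand = character(), start = integer(),
                          end = integer(), apex = integer(),
                          kind = character(), stringsAsFactors = FALSE),
    tpm = matrix(0, 0, length(samples), dimnames = list(NULL, samples)),
    counts = NULL), class = "site_clusters")
  all_cl <- do.call(rbind, lapply(samples, function(s) per_sample[[s]]))
  if (is.null(all_cl) || !nrow(all_cl)) return(empty)
  all_cl <- all_cl[all_cl$tpm >= tpm_threshold, , drop = FALSE]
  if (!nrow(all_cl)) return(empty)
  # transitive merge on span gap <= max_dist within contig/strand
  all_cl <- all_cl[order(all_cl$contig, all_cl$strand, all_cl$start, all_cl$end), ,
                   drop = FALSE]
  key <- paste(all_cl$contig, all_cl$strand, sep = "\r")
  run_end <- cummax_by_group(all_cl$end, key)
  n <- nrow(all_cl)
  new_grp <- c(TRUE, key[-1] != key[-n] | all_cl$start[-1] - run_end[-n] > max_dist)
  grp <- cumsum(new_grp)
  rows <- lapply(split(seq_len(n), grp), function(idx) {
    sub <- all_cl[idx, , drop = FALSE]
    contig <- sub$contig[1]; strand <- sub$strand[1]
    ptab <- pooled$counts
    sel <- ptab$contig == contig & ptab$strand == strand &
      ptab$pos >= min(sub$start) & ptab$pos < max(sub$end)
    tr <- trim_quantile(ptab$pos[sel], ptab$tpm[sel], q_low, q_up, strand)
    in_tr <- sel & ptab$pos >= tr[1] & ptab$pos < tr[2]
    apex <- apex_position(ptab$pos[in_tr], ptab$tpm[in_tr], strand)
    data.frame(contig = contig, strand = strand, start = tr[1], end = tr[2],
               apex = apex, kind = kind, stringsAsFactors = FALSE)
  })
  clusters <- do.call(rbind, rows)
  clusters <- clusters[order(clusters$contig, clusters$strand, clusters$start), ,
                       drop = FALSE]
  clusters$cluster_id <- sprintf("%s_%s%s_%d", tolower(kind), clusters$contig,
                                 ifelse(clusters$strand == "+", "p", "m"),
                                 clusters$start)
  clusters <- clusters[c("cluster_id", "contig", "strand", "start", "end",
                         "apex", "kind")]
  rownames(clusters) <- NULL
  out <- structure(list(clusters = clusters, tpm = NULL, counts = NULL),
                   class = "site_clusters")
  out$tpm <- if (!is.null(tpm_tracks))
    cluster_sample_matrix(clusters, tpm_tracks, "tpm")
  else matrix(0, nrow(clusters), length(samples),
              dimnames = list(clusters$cluster_id, samples))
  if (!is.null(raw_tracks))
    out$counts <- cluster_sample_matrix(clusters, raw_tracks, "count")
  out
}

# running max within groups of identical consecutive keys
cummax_by_group <- function(x, key) {
  out <- x
  for (i in seq_along(x)[-1]) {
    if (key[i] == key[i - 1] && out[i - 1] > out[i]) out[i] <- out[i - 1]
  }
  out
}

# smallest half-open interval holding pooled cumulative mass q_low..q_up,
# walking positions 5'->3' on the cluster's strand
trim_quantile <- function(pos, val, q_low, q_up, strand) {
  keep <- val > 0
  pos <- pos[keep]; val <- val[keep]
  if (!length(pos)) stop("cluster has no pooled signal")
  ord <- order(pos, decreasing = (strand == "-"))
  pos <- pos[ord]; val <- val[ord]
  cum <- cumsum(val)
  total <- cum[length(cum)]
  i0 <- which(cum > q_low * total)[1]
  i1 <- which(cum >= q_up * total)[1]
  if (is.na(i0) || i0 > i1) i0 <- i1
  kept <- pos[i0:i1]
  c(min(kept), max(kept) + 1L)
}

# argmax with 5'-most tie-break (min pos on "+", max pos on "-")
apex_position <- function(pos, val, strand) {
  if (!length(pos) || all(val <= 0)) stop("apex undefined: zero signal")
  cand <- pos[val == max(val)]
  if (strand == "+") min(cand) else max(cand)
}

#' Apex of a cluster under a pooled signal
#'
#' @param cluster one row of a `site_clusters` table (or any list with
#'   `contig`, `strand`, `start`, `end`).
#' @param pooled pooled `tpm_track`.
#' @return The 0-based position of maximal pooled TPM inside `[start, end)`;
#'   ties break to the 5'-most position on the cluster strand.
#' @export
cluster_apex <- function(cluster, pooled) {
  tab <- pooled$counts
  sel <- tab$contig == cluster$contig & tab$strand == cluster$strand &
    tab$pos >= cluster$start & tab$pos < cluster$end
  apex_position(tab$pos[sel], tab$tpm[sel], cluster$strand)
}

# clusters x samples matrix: track values summed over each trimmed interval.
# Clusters of one kind/strand/contig are non-overlapping, so membership is a
# findInterval lookup per contig/strand, not a per-cluster scan.
cluster_sample_matrix <- function(clusters, tracks, column) {
  samples <- names(tracks)
  m <- matrix(0, nrow(clusters), length(samples),
              dimnames = list(clusters$cluster_id, samples))
  ckey <- paste(clusters$contig, clusters$strand, sep = "\r")
  for (s in samples) {
    tab <- tracks[[s]]$counts
    tkey <- paste(tab$contig, tab$strand, sep = "\r")
    for (k in unique(ckey)) {
      ci <- which(ckey == k)
      ord <- ci[order(clusters$start[ci])]
      ti <- which(tkey == k)
      if (!length(ti)) next
      idx <- findInterval(tab$pos[ti], clusters$start[ord])
      ok <- idx >= 1 & tab$pos[ti] < clusters$end[ord][pmax(idx, 1L)]
      if (!any(ok)) next
      sums <- rowsum(tab[[column]][ti][ok], idx[ok])
      m[ord[as.integer(rownames(sums))], s] <-
        m[ord[as.integer(rownames(sums))], s] + sums[, 1]
    }
  }
  m
}

#' @export
print.site_clusters <- function(x, ...) {
  cat(sprintf("<site_clusters> %d %s consensus clusters, %d samples\n",
              nrow(x$clusters),
              if (nrow(x$clusters)) x$clusters$kind[1] else "?",
              ncol(x$tpm)))
  invisible(x)
}
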