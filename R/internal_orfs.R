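#' @keywords internal
revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "")[[1]]),
        collapse = "")
}

# transcript-sense sequence from the apex to the gene's annotated 3' end
# (the stop codon's last base), plus the window length
sense_window <- function(genome, apex, gene) {
  seqs <- genome[[gene$contig]]
  if (gene$strand == "+") {
    substr(seqs, apex + 1L, gene$orf_end)
  } else {
    revcomp_chr(substr(seqs, gene$orf_start + 1L, apex + 1L))
  }
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Is a cluster internal to its gene's ORF?
#'
#' Internal means the apex falls within the annotated ORF's genomic
#' interval, half-open: an apex at the ORF start is internal, an apex at
#' the ORF end is external.
#'
#' @param cluster one row of a `site_clusters` table.
#' @param gene one row of a `gene_models` data.frame.
#' @return Logical.
#' @export
classify_internal <- function(cluster, gene) {
  cluster$apex >= gene$orf_start & cluster$apex < gene$orf_end
}

#' Relaxed internal-TSS cutoff
#'
#' An internal TSS passes the relaxed cutoff when it is significantly
#' upregulated twofold or more (padj < 0.05) at one or more transition
#' timepoints.
#'
#' @param cluster_id the internal cluster's id.
#' @param diff DE table from [diff_expression()].
#' @return Logical.
#' @export
relaxed_filter <- function(cluster_id, diff) {
  rows <- diff[diff$cluster_id == cluster_id, ]
  nrow(rows) > 0 && any(rows$significant_up)
}

#' Stringent internal-TSS cutoff
#'
#' On top of the relaxed cutoff, the internal cluster's TPM must reach at
#' least `fraction` (default one third) of the full-length (main promoter)
#' cluster's TPM at a timepoint where it is significantly up, and the
#' predicted truncated ORF must be at least `min_orf_len` nt.
#'
#' @param cluster_id internal cluster id.
#' @param main_cluster_id the gene's main promoter cluster id (NA when
#'   undefined, which fails the filter).
#' @param diff DE table.
#' @param tpm_tp clusters x timepoints TPM matrix.
#' @param orf_len predicted ORF length in nt (NA when no ORF).
#' @param fraction TPM fraction of the full-length isoform (default 1/3).
#' @param min_orf_len minimum predicted ORF length (default 300).
#' @return Logical.
#' @export
stringent_filter <- function(cluster_id, main_cluster_id, diff, tpm_tp,
                             orf_len, fraction = 1 / 3, min_orf_len = 300) {
  if (is.na(main_cluster_id) || is.na(orf_len) || orf_len < min_orf_len)
    return(FALSE)
  rows <- diff[diff$cluster_id == cluster_id & diff$significant_up, ]
  if (!nrow(rows)) return(FALSE)
  any(tpm_tp[cluster_id, rows$timepoint] >=
        fraction * tpm_tp[main_cluster_id, rows$timepoint])
}

#' Predict a truncated ORF downstream of an internal TSS
#'
#' Scans the transcript-sense sequence from the apex to the gene's
#' annotated stop codon, in all three frames of the sense strand only, for
#' AUG..stop open reading frames (standard code, stop included in the
#' length) lying entirely within that window, and reports the longest one
#' of at least `min_len` nt (ties to the 5'-most start).
#'
#' @param genome named character vector of contig sequences.
#' @param apex internal TSS apex (0-based genomic).
#' @param gene one row of a `gene_models` data.frame containing the apex.
#' @param min_len minimum ORF length in nt (default 300).
#' @return One-row data.frame `orf_start`, `orf_end` (0-based half-open
#'   genomic), `length` (nt), or NULL when no qualifying ORF exists.
#' @export
predict_orf <- function(genome, apex, gene, min_len = 300) {
  win <- sense_window(genome, apex, gene)
  L <- nchar(win)
  if (L < min_len) return(NULL)
  codon_at <- function(i) substr(win, i + 1L, i + 3L)
  best <- NULL
  for (frame in 0:2) {
    starts <- seq.int(frame, L - 3L, by = 3L)
    codons <- vapply(starts, codon_at, character(1))
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    stop_idx <- which(is_stop)
    for (ai in which(is_atg)) {
      nxt <- stop_idx[stop_idx >= ai]
      if (!length(nxt)) next
      len <- (nxt[1] - ai + 1L) * 3L
      if (len < min_len) next
      w0 <- starts[ai]
      if (is.null(best) || len > best$len ||
          (len == best$len && w0 < best$w0))
        best <- list(w0 = w0, len = len)
    }
  }
  if (is.null(best)) return(NULL)
  w1 <- best$w0 + best$len
  if (gene$strand == "+") {
    gs <- apex + best$w0; ge <- apex + w1
  } else {
    gs <- apex - w1 + 1L; ge <- apex - best$w0 + 1L
  }
  data.frame(orf_start = gs, orf_end = ge, length = best$len)
}

#' Leader length to the first in-frame AUG
#'
#' Approximates the truncated isoform's 5' leader as the distance (nt) from
#' the internal TSS apex to the first downstream AUG that is in frame with
#' the gene's annotated ORF.
#'
#' @inheritParams predict_orf
#' @return Integer nt (0 when the apex sits exactly on an in-frame AUG),
#'   or NA when no in-frame AUG exists downstream.
#' @export
leader_length <- function(genome, apex, gene) {
  win <- sense_window(genome, apex, gene)
  L <- nchar(win)
  if (L < 3L) return(NA_integer_)
  # annotated codon boundaries leave a multiple of 3 to the window's end
  offs <- seq.int(L %% 3, L - 3L, by = 3L)
  for (w in offs) {
    if (substr(win, w + 1L, w + 3L) == "ATG") return(as.integer(w))
  }
  NA_integer_
}

#' Internal-TSS calls for a cluster set
#'
#' For every cluster assigned as internal: the relaxed and stringent
#' cutoffs, the predicted truncated ORF and the leader length.
#'
#' @param clusters a TSS `site_clusters` object.
#' @param assignments assignment table.
#' @param usage usage table for the transition (supplies each gene's main
#'   promoter cluster).
#' @param diff DE table.
#' @param sample_info data.frame `sample_id`, `timepoint`.
#' @param genes `gene_models` data.frame.
#' @param genome named character vector of contig sequences.
#' @param fraction,min_orf_len see [stringent_filter()].
#' @return data.frame, one row per internal cluster.
#' @export
internal_tss_calls <- function(clusters, assignments, usage, diff,
                               sample_info, genes, genome, fraction = 1 / 3,
                               min_orf_len = 300) {
  tpm_tp <- tpm_by_timepoint(clusters, sample_info)
  internal <- assignments[assignments$category == "internal", , drop = FALSE]
  main_by_gene <- stats::setNames(usage$main_cluster, usage$gene_id)
  ctab <- clusters$clusters
  rows <- lapply(seq_len(nrow(internal)), function(i) {
    cl_id <- internal$cluster_id[i]
    gene <- genes[genes$gene_id == internal$gene_id[i], ]
    apex <- ctab$apex[ctab$cluster_id == cl_id]
    orf <- predict_orf(genome, apex, gene, min_len = min_orf_len)
    orf_len <- if (is.null(orf)) NA_integer_ else orf$length
    main_cl <- main_by_gene[internal$gene_id[i]]
    if (is.null(main_cl) || length(main_cl) == 0) main_cl <- NA_character_
    relaxed <- relaxed_filter(cl_id, diff)
    data.frame(cluster_id = cl_id, gene_id = internal$gene_id[i],
               relaxed = relaxed,
               stringent = relaxed && stringent_filter(
                 cl_id, main_cl, diff, tpm_tp, orf_len,
                 fraction = fraction, min_orf_len = min_orf_len),
               orf_start = if (is.null(orf)) NA_integer_ else orf$orf_start,
               orf_end = if (is.null(orf)) NA_integer_ else orf$orf_end,
               orf_length = orf_len,
               leader_length = leader_length(genome, apex, gene),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cluster_id = character(), gene_id = character(),
                      relaxed = logical(), stringent = logical(),
                      orf_start = integer(), orf_end = integer(),
                      orf_length = integer(), leader_length = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
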