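#' End-count track constructor
#'
#' An end-count track stores strand-specific per-base counts of transcript
#' 5' ends (TSS-seq) or 3' ends (TES-seq) for one sample, as a sparse table:
#' only covered bases are materialised. Coordinates are 0-based; a site is
#' the single base of the 5'-most (TSS) or 3'-most templated (TES) nucleotide.
#'
#' @param counts data.frame with columns `contig`, `pos` (0-based), `strand`
#'   ("+"/"-") and `count` (non-negative integer).
#' @param sample_id character scalar naming the sample.
#' @param timepoint timepoint label (character).
#' @param replicate replicate index (integer).
#' @param kind "TSS" or "TES".
#' @return An object of class `end_track`.
#' @export
end_track <- function(counts, sample_id = "sample", timepoint = NA_character_,
                      replicate = NA_integer_, kind = c("TSS", "TES")) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(counts),
            all(c("contig", "pos", "strand", "count") %in% names(counts)))
  if (nrow(counts) && any(counts$count < 0))
    stop("negative end counts are not allowed")
  counts <- counts[counts$count > 0, , drop = FALSE]
  counts <- counts[order(counts$contig, counts$strand, counts$pos), , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(counts = counts,
                 sample_id = sample_id,
                 timepoint = timepoint,
                 replicate = replicate,
                 kind = kind,
                 library_size = sum(as.numeric(counts$count))),
            class = "end_track")
}

#' @export
print.end_track <- function(x, ...) {
  cat(sprintf("<end_track> %s [%s] %d sites, library size %g\n",
              x$sample_id, x$kind, nrow(x$counts), x$library_size))
  invisible(x)
}

#' Normalize an end-count track to tags per million
#'
#' Each per-base count is divided by the track's library size (total counted
#' ends over both strands) and scaled to one million, so the TPM values of a
#' track sum to 1e6.
#'
#' @param track an `end_track`.
#' @return A `tpm_track`: same layout with a `tpm` column replacing `count`.
#' @export
normalize_tpm <- function(track) {
  stopifnot(inherits(track, "end_track"))
  if (track$library_size <= 0) stop("empty library: library_size is zero")
  tab <- track$counts
  tab$tpm <- tab$count / track$library_size * 1e6
  structure(list(counts = tab,
                 sample_id = track$sample_id,
                 timepoint = track$timepoint,
                 replicate = track$replicate,
                 kind = track$kind,
                 library_size = track$library_size),
            class = "tpm_track")
}

#' @export
print.tpm_track <- function(x, ...) {
  cat(sprintf("<tpm_track> %s [%s] %d sites\n", x$sample_id, x$kind,
              nrow(x$counts)))
  invisible(x)
}

#' Position-wise sum of TPM tracks
#'
#' Pools several samples' TPM tracks into one track whose value at each base
#' is the sum of the per-sample TPM there. Used as the reference signal for
#' consensus-cluster boundaries and apexes.
#'
#' @param tracks list of `tpm_track` objects of the same kind.
#' @return A `tpm_track` with `sample_id = "pooled"`.
#' @export
pool_tpm <- function(tracks) {
  stopifnot(length(tracks) >= 1, all(vapply(tracks, inherits, TRUE, "tpm_track")))
  tab <- do.call(rbind, lapply(tracks, function(t) t$counts[c("contig", "pos", "strand", "tpm")]))
  key <- paste(tab$contig, tab$strand, tab$pos, sep = "\r")
  agg <- rowsum(tab$tpm, key)
  parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  out <- data.frame(contig = parts[, 1], pos = as.integer(parts[, 3]),
                    strand = parts[, 2], tpm = agg[, 1],
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$strand, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(counts = out, sample_id = "pooled", timepoint = NA_character_,
                 replicate = NA_integer_, kind = tracks[[1]]$kind,
                 library_size = NA_real_),
            class = "tpm_track")
}

# sparse lookup: values of a track at given contig/strand/positions (0 if absent)
track_values_at <- function(track, contig, strand, positions,
                            column = if (inherits(track, "tpm_track")) "tpm" else "count") {
  tab <- track$counts
  sel <- tab$contig == contig & tab$strand == strand
  idx <- match(positions, tab$pos[sel])
  vals <- tab[[column]][sel][idx]
  vals[is.na(vals)] <- 0
  vals
}
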