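#' mRNA coverage track constructor
#'
#' Dense per-base, strand-specific mRNA coverage used by the sliding-window
#' assignment rules. Stored as one numeric vector per contig and strand,
#' index i holding coverage of 0-based position i - 1.
#'
#' @param cov list: contig -> list("+" = numeric, "-" = numeric).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(cov) {
  structure(list(cov = cov), class = "coverage_track")
}

#' Coverage values over a 0-based half-open interval
#' @param coverage a `coverage_track`.
#' @param contig,strand location.
#' @param from,to 0-based half-open bounds (truncated to the contig).
#' @export
coverage_at <- function(coverage, contig, strand, from, to) {
  v <- coverage$cov[[contig]][[strand]]
  if (is.null(v)) return(numeric(0))
  from <- max(from, 0L); to <- min(to, length(v))
  if (from >= to) return(numeric(0))
  v[(from + 1L):to]
}

# every 30-bp window (step 1 nt, truncated at the region bounds) must
# satisfy pred(window values); region shorter than one window is a single
# truncated window
windows_all <- function(values, window, pred) {
  n <- length(values)
  if (n == 0) return(FALSE)
  if (n <= window) return(pred(values))
  for (s in 1:(n - window + 1L)) {
    if (!pred(values[s:(s + window - 1L)])) return(FALSE)
  }
  TRUE
}

# closest same-strand candidate gene for an external cluster, by distance;
# equidistant ties break to the 5'-most gene start on the cluster strand
closest_candidate <- function(genes, contig, strand, dists) {
  ok <- which(!is.na(dists))
  if (!length(ok)) return(NULL)
  best <- ok[dists[ok] == min(dists[ok])]
  if (length(best) > 1) {
    key <- if (strand == "+") genes$orf_start[best] else -genes$orf_end[best]
    best <- best[order(key)]
  }
  best[1]
}

#' Assign a TSS cluster to a gene model
#'
#' The candidate is the closest non-overlapping downstream gene in the same
#' orientation (or the containing gene for internal clusters). External
#' assignment succeeds when the apex lies within `max_near` bp upstream of
#' the ORF start, or within `max_near`..`max_far` bp provided every
#' `window`-bp sliding window (step 1 nt) of mRNA coverage between apex and
#' ORF start has median coverage > 0. An apex inside a same-strand ORF is
#' an internal assignment to that gene.
#'
#' @param cluster one row of a TSS `site_clusters` table.
#' @param genes a `gene_models` data.frame.
#' @param rna_coverage a `coverage_track`.
#' @param max_near,max_far distance tiers (bp; defaults 100 and 1000).
#' @param window sliding-window width (bp).
#' @return One-row data.frame (`cluster_id`, `gene_id`, `category`,
#'   `distance`, `utr_length`) or NULL when unassignable.
#' @export
assign_tss <- function(cluster, genes, rna_coverage, max_near = 100,
                       max_far = 1000, window = 30) {
  g <- genes[genes$contig == cluster$contig & genes$strand == cluster$strand, ,
             drop = FALSE]
  if (!nrow(g)) return(NULL)
  apex <- cluster$apex
  inside <- apex >= g$orf_start & apex < g$orf_end
  if (any(inside)) {
    gi <- which(inside)[1]
    return(data.frame(cluster_id = cluster$cluster_id, gene_id = g$gene_id[gi],
                      category = "internal", distance = 0L,
                      utr_length = NA_integer_, stringsAsFactors = FALSE))
  }
  dists <- if (cluster$strand == "+") g$orf_start - apex
           else apex - (g$orf_end - 1L)
  dists[dists < 1L] <- NA  # upstream-external candidates only
  gi <- closest_candidate(g, cluster$contig, cluster$strand, dists)
  if (is.null(gi) || dists[gi] > max_far) return(NULL)
  d <- dists[gi]
  if (d > max_near) {
    vals <- if (cluster$strand == "+")
      coverage_at(rna_coverage, cluster$contig, "+", apex, g$orf_start[gi])
    else
      coverage_at(rna_coverage, cluster$contig, "-", g$orf_end[gi], apex + 1L)
    if (!windows_all(vals, window, function(w) stats::median(w) > 0))
      return(NULL)
  }
  data.frame(cluster_id = cluster$cluster_id, gene_id = g$gene_id[gi],
             category = "upstream", distance = d, utr_length = d,
             stringsAsFactors = FALSE)
}

#' Assign a TES cluster to a gene model
#'
#' Mirrors [assign_tss()] on the 3' side: the candidate is the closest
#' non-overlapping upstream gene in the same orientation. Beyond `max_near`
#' bp the sliding windows between ORF end and apex must additionally have
#' median coverage >= 5% of the gene body's median and maximum coverage
#' <= 5x the gene body's maximum, guarding against assignments across
#' expression discontinuities.
#'
#' @inheritParams assign_tss
#' @param median_frac per-window median floor, as a fraction of the gene
#'   body median (default 0.05).
#' @param max_mult per-window maximum ceiling, as a multiple of the gene
#'   body maximum (default 5).
#' @export
assign_tes <- function(cluster, genes, rna_coverage, max_near = 100,
                       max_far = 1000, window = 30, median_frac = 0.05,
                       max_mult = 5) {
  g <- genes[genes$contig == cluster$contig & genes$strand == cluster$strand, ,
             drop = FALSE]
  if (!nrow(g)) return(NULL)
  apex <- cluster$apex
  inside <- apex >= g$orf_start & apex < g$orf_end
  if (any(inside)) {
    gi <- which(inside)[1]
    return(data.frame(cluster_id = cluster$cluster_id, gene_id = g$gene_id[gi],
                      category = "internal", distance = 0L,
                      utr_length = NA_integer_, stringsAsFactors = FALSE))
  }
  dists <- if (cluster$strand == "+") apex - g$orf_end
           else (g$orf_start - 1L) - apex
  dists[dists < 0L] <- NA  # downstream-external candidates only
  gi <- closest_candidate(g, cluster$contig, cluster$strand, dists)
  if (is.null(gi) || dists[gi] > max_far) return(NULL)
  d <- dists[gi]
  if (d > max_near) {
    body <- coverage_at(rna_coverage, cluster$contig, cluster$strand,
                        g$orf_start[gi], g$orf_end[gi])
    body_med <- stats::median(body); body_max <- max(body, 0)
    vals <- if (cluster$strand == "+")
      coverage_at(rna_coverage, cluster$contig, "+", g$orf_end[gi], apex + 1L)
    else
      coverage_at(rna_coverage, cluster$contig, "-", apex, g$orf_start[gi])
    ok <- windows_all(vals, window, function(w)
      stats::median(w) > 0 && stats::median(w) >= median_frac * body_med &&
        max(w) <= max_mult * body_max)
    if (!ok) return(NULL)
  }
  data.frame(cluster_id = cluster$cluster_id, gene_id = g$gene_id[gi],
             category = "downstream", distance = d, utr_length = d,
             stringsAsFactors = FALSE)
}

#' Assign every consensus cluster of a set to genes
#'
#' @param clusters a `site_clusters` object (TSS or TES; dispatches on its
#'   kind).
#' @param genes a `gene_models` data.frame.
#' @param rna_coverage a `coverage_track`.
#' @param ... threshold arguments passed to [assign_tss()]/[assign_tes()].
#' @return data.frame of assignments (unassignable clusters are absent).
#' @export
assign_clusters <- function(clusters, genes, rna_coverage, ...) {
  tab <- clusters$clusters
  f <- if (nrow(tab) && tab$kind[1] == "TES") assign_tes else assign_tss
  out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
    f(tab[i, ], genes, rna_coverage, ...)))
  if (is.null(out))
    out <- data.frame(cluster_id = character(), gene_id = character(),
                      category = character(), distance = integer(),
                      utr_length = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' UTR length of an external assignment
#'
#' 5' UTR length is the nt from the TSS-cluster apex to the first base of
#' the start codon; 3' UTR length the nt from one past the last stop-codon
#' base to the TES-cluster apex. Internal clusters have no UTR length.
#'
#' @param assignment one assignment row.
#' @return Integer nt, or NA for internal assignments.
#' @export
utr_length <- function(assignment) {
  if (assignment$category == "internal") return(NA_integer_)
  as.integer(assignment$utr_length)
}
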