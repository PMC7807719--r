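#' Read a strand's bedGraph file into an end-count track
#'
#' bedGraph records are 0-based half-open runs; every covered base is
#' materialised at its value. Internal coordinates stay 0-based throughout
#' the package; only the GFF3 reader/writer shifts conventions.
#'
#' @param path path to a 4-column bedGraph file (contig, start, end, value).
#' @param strand "+" or "-": the strand this file carries.
#' @param ... metadata passed to [end_track()] (`sample_id`, `timepoint`,
#'   `replicate`, `kind`).
#' @return An `end_track` for this strand only; `library_size` is the sum of
#'   this file's counts (combine strand pairs with [combine_tracks()]).
#' @export
read_bedgraph <- function(path, strand = c("+", "-"), ...) {
  strand <- match.arg(strand)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(end_track(data.frame(contig = character(), pos = integer(),
                                strand = character(), count = numeric()), ...))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 4)) {
    bad <- which(nf != 4)[1]
    stop(sprintf("malformed bedGraph line %d in %s: expected 4 fields, got %d",
                 bad, path, nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  value <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(start) | is.na(end) | is.na(value) | end <= start)
  if (length(bad))
    stop(sprintf("malformed bedGraph line %d in %s: '%s'", bad[1], path, lines[bad[1]]))
  if (any(value < 0)) {
    bad <- which(value < 0)[1]
    stop(sprintf("negative value on bedGraph line %d in %s", bad, path))
  }
  widths <- end - start
  pos <- start[rep.int(seq_along(start), widths)] +
    sequence(widths) - 1L
  count <- value[rep.int(seq_along(value), widths)]
  contig <- m[, 1][rep.int(seq_along(start), widths)]
  end_track(data.frame(contig = contig, pos = pos, strand = strand,
                       count = count, stringsAsFactors = FALSE), ...)
}

#' Write one strand of a track as canonical bedGraph
#'
#' Output is sorted by contig then position, with maximal runs of adjacent
#' equal-valued bases merged, so writing is idempotent: reading the file back
#' and rewriting it reproduces it byte for byte.
#'
#' @param track an `end_track` or `tpm_track`.
#' @param path output path.
#' @param strand which strand of the track to write.
#' @export
write_bedgraph <- function(track, path, strand = c("+", "-")) {
  strand <- match.arg(strand)
  tab <- track$counts
  col <- if (inherits(track, "tpm_track")) "tpm" else "count"
  tab <- tab[tab$strand == strand & tab[[col]] > 0, , drop = FALSE]
  tab <- tab[order(tab$contig, tab$pos), , drop = FALSE]
  out <- character(0)
  if (nrow(tab)) {
    new_run <- c(TRUE, tab$contig[-1] != tab$contig[-nrow(tab)] |
                   tab$pos[-1] != tab$pos[-nrow(tab)] + 1L |
                   tab[[col]][-1] != tab[[col]][-nrow(tab)])
    run <- cumsum(new_run)
    first <- !duplicated(run)
    last <- !duplicated(run, fromLast = TRUE)
    out <- sprintf("%s\t%d\t%d\t%s", tab$contig[first], tab$pos[first],
                   tab$pos[last] + 1L, format(tab[[col]][first], trim = TRUE,
                                              scientific = FALSE))
  }
  writeLines(out, path)
  invisible(path)
}

#' Merge strand-paired tracks into one track
#'
#' The library size of the result is the total over all constituent strands,
#' which is the denominator TPM normalization uses.
#'
#' @param ... `end_track` objects (typically the "+" and "-" files of one
#'   sample).
#' @return A single `end_track`.
#' @export
combine_tracks <- function(...) {
  tracks <- list(...)
  if (length(tracks) == 1 && is.list(tracks[[1]]) && !inherits(tracks[[1]], "end_track"))
    tracks <- tracks[[1]]
  stopifnot(all(vapply(tracks, inherits, TRUE, "end_track")))
  t1 <- tracks[[1]]
  end_track(do.call(rbind, lapply(tracks, `[[`, "counts")),
            sample_id = t1$sample_id, timepoint = t1$timepoint,
            replicate = t1$replicate, kind = t1$kind)
}

#' Read gene models from GFF3
#'
#' Gene features (falling back to CDS when no gene rows exist) become one
#' row per gene with the annotated ORF interval converted from the file's
#' 1-based inclusive coordinates to the package's 0-based half-open
#' convention. Strand is preserved as annotated; no coordinate flip occurs
#' for minus-strand genes.
#'
#' @param path GFF3 file.
#' @return data.frame of class `gene_models` with columns `gene_id`,
#'   `contig`, `strand`, `orf_start`, `orf_end`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% "gene"
  if (!any(keep)) keep <- as.character(gr$type) %in% "CDS"
  gr <- gr[keep]
  ids <- as.character(gr$ID)
  if (any(is.na(ids) | !nzchar(ids)))
    stop("GFF3 gene feature without an ID attribute")
  out <- data.frame(gene_id = ids,
                    contig = as.character(GenomicRanges::seqnames(gr)),
                    strand = as.character(BiocGenerics::strand(gr)),
                    orf_start = BiocGenerics::start(gr) - 1L,
                    orf_end = BiocGenerics::end(gr),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_id)) stop("duplicate gene ids in GFF3")
  if (any(out$orf_end <= out$orf_start)) stop("gene with end <= start in GFF3")
  if (any(!out$strand %in% c("+", "-"))) stop("gene without strand in GFF3")
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Write gene models as GFF3
#' @param genes a `gene_models` data.frame (0-based half-open internally).
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\ttsswitch\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$contig, genes$orf_start + 1L, genes$orf_end,
                     genes$strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file; headers are contig names.
#' @return Named character vector, one uppercase sequence per contig.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) stop("FASTA file contains no records")
  if (any(Biostrings::width(seqs) == 0)) stop("empty FASTA record")
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) stop("duplicate contig name in FASTA")
  out <- toupper(as.character(seqs))
  names(out) <- nm
  out
}

#' Write a genome FASTA
#' @param genome named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Write result tables as TSV
#'
#' Each element of `tables` is written as `<name>.tsv` with a header row,
#' tab separation, no quoting and no row names, so every table reloads with
#' [read_results_tsv()] to identical values.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    p
  }, character(1))
  invisible(paths)
}

#' Read back a TSV written by [write_results()]
#' @param path path to the TSV.
#' @export
read_results_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    na.strings = "NA", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
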