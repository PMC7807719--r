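#' Draw a synthetic gene architecture table
#'
#' Assigns each gene an event class and the planted cluster geometry and
#' per-timepoint expected TPM trajectories that realise it. Classes:
#' \describe{
#'   \item{repressed}{the upstream alternative TSS is induced across the
#'     transition while the main TSS is repressed at least twofold and the
#'     alternative overtakes it (a switching event by construction).}
#'   \item{coactivated}{main and alternative both induced at least
#'     twofold; the alternative never reaches the main's level.}
#'   \item{neutral}{both clusters flat.}
#' }
#' Main TSS offsets are drawn around 75 nt upstream of the ATG and main
#' TES offsets around 170 nt downstream of the stop, the observed genomic
#' medians for this organism; alternative spacings mix proximal (< 80 nt)
#' and distal (>= 80 nt) regimes.
#'
#' @param n_genes number of genes.
#' @param class_fractions named fractions for repressed / coactivated /
#'   neutral (normalised internally).
#' @param timepoints timepoint labels; the first is the reference.
#' @param n_internal how many genes additionally carry an internal TSS.
#' @param seed integer seed.
#' @return data.frame of class `synth_architecture`, one row per gene.
#' @export
synth_architecture <- function(n_genes = 300,
                               class_fractions = c(repressed = 1, coactivated = 1,
                                                   neutral = 1) / 3,
                               timepoints = c("t0", "t1", "t2", "t3"),
                               n_internal = 0, seed = 1) {
  set.seed(seed)
  fr <- class_fractions / sum(class_fractions)
  n_cls <- c(repressed = floor(fr[["repressed"]] * n_genes),
             coactivated = floor(fr[["coactivated"]] * n_genes))
  n_cls <- c(n_cls, neutral = n_genes - sum(n_cls))
  label <- sample(rep(names(n_cls), n_cls))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  orf_len <- 3L * sample(220:400, n_genes, replace = TRUE)
  main_off <- pmax(30L, round(stats::rnorm(n_genes, 75, 12)))
  # proximal spacings stay above the consensus merge reach (span gap > 20 nt
  # given the ~12 nt positional profiles) so planted pairs remain resolvable
  spacing <- ifelse(stats::runif(n_genes) < 0.5,
                    sample(36:79, n_genes, replace = TRUE),
                    sample(80:400, n_genes, replace = TRUE))
  tes_off <- pmin(pmax(60L, round(stats::rnorm(n_genes, 170, 25))), 240L)
  ntp <- length(timepoints)
  ramp <- function(from, to) from * (to / from)^(seq_len(ntp - 1) / (ntp - 1))
  # expected TPM trajectories on the scale of strongly regulated meiotic
  # genes: repression/induction spans geometric ramps to 8-fold
  traj <- function(lbl) {
    switch(lbl,
           repressed = list(main = c(80, ramp(80, 10)), alt = c(10, ramp(10, 80))),
           coactivated = list(main = c(30, ramp(30, 240)), alt = c(10, ramp(10, 80))),
           neutral = list(main = c(40, rep(40, ntp - 1)), alt = c(5, rep(5, ntp - 1))))
  }
  tr <- lapply(label, traj)
  main_tpm <- t(vapply(tr, `[[`, numeric(ntp), "main"))
  alt_tpm <- t(vapply(tr, `[[`, numeric(ntp), "alt"))
  colnames(main_tpm) <- paste0("main_tpm_", timepoints)
  colnames(alt_tpm) <- paste0("alt_tpm_", timepoints)
  has_internal <- rep(FALSE, n_genes)
  if (n_internal > 0) {
    # carriers are flat-main genes, so the 1/3-of-full-length criterion has a
    # stable denominator
    cand <- which(label == "neutral")
    has_internal[sample(cand, min(n_internal, length(cand)))] <- TRUE
  }
  # internal TSS: anchor on a codon boundary far enough from the stop for a
  # >= 300 nt truncated ORF; half the carriers get a sub-threshold level so
  # the stringent cutoff has both outcomes
  internal_codon <- ifelse(has_internal,
                           pmax(10L, (orf_len / 3L) %/% 4L), NA_integer_)
  internal_strong <- has_internal & stats::runif(n_genes) < 0.5
  int_tpm <- matrix(0, n_genes, ntp,
                    dimnames = list(NULL, paste0("int_tpm_", timepoints)))
  int_tpm[has_internal, ] <- outer(rep(6, sum(has_internal)),
                                   c(1, ramp(1, 8)))
  int_tpm[has_internal & !internal_strong, ] <-
    int_tpm[has_internal & !internal_strong, , drop = FALSE] * 0.25
  out <- data.frame(gene_id = sprintf("gene%03d", seq_len(n_genes)),
                    label = label, strand = strand, orf_len = orf_len,
                    main_off = main_off, alt_off = main_off + spacing,
                    spacing = spacing, tes_off = tes_off,
                    has_internal = has_internal,
                    internal_codon = internal_codon,
                    internal_strong = internal_strong,
                    stringsAsFactors = FALSE)
  out <- cbind(out, main_tpm, alt_tpm, int_tpm)
  attr(out, "timepoints") <- timepoints
  class(out) <- c("synth_architecture", "data.frame")
  out
}

# codons without in-frame stops
random_codons <- function(n) {
  sense <- setdiff(apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T")), 1, paste, collapse = ""),
                   STOP_CODONS)
  sample(sense, n, replace = TRUE)
}

#' Generate a genome and annotation realising an architecture
#'
#' Genes are laid out on one contig with 1.1 kb of padding on each side of
#' every ORF (ORF-to-ORF spacing 2.2 kb), so assignment windows never
#' compete. ORFs are ATG + non-stop codons + stop, reverse-complemented in
#' place for minus-strand genes; internal-TSS genes get an ATG planted at
#' the designated in-frame codon. Poly(A) priming-artifact tracts are
#' planted 300 nt downstream of designated genes' stop codons, and any
#' accidental A/T tract arising near a planted TES anchor is disrupted so
#' the planted truth table is exact.
#'
#' @param arch a `synth_architecture` table.
#' @param n_priming how many genes get a planted poly(A) tract plus an
#'   internal-priming 3'-end artifact.
#' @param seed integer seed.
#' @return List: `genome` (named character), `genes` (`gene_models`),
#'   `anchors` (per-gene genomic anchor positions and artifact/tract
#'   coordinates), `tracts` (planted tracts).
#' @export
generate_genome_and_annotation <- function(arch, n_priming = 0, seed = 1) {
  set.seed(seed + 1L)
  n <- nrow(arch)
  pad <- 1100L
  slot_len <- arch$orf_len + 2L * pad
  slot_start <- cumsum(c(0L, slot_len[-n]))
  orf_start <- slot_start + pad
  orf_end <- orf_start + arch$orf_len
  contig_len <- sum(slot_len) + 21000L
  bases <- sample(c("A", "C", "G", "T"), contig_len, replace = TRUE)
  for (i in seq_len(n)) {
    codons <- c("ATG", random_codons(arch$orf_len[i] / 3L - 2L),
                sample(STOP_CODONS, 1))
    if (!is.na(arch$internal_codon[i]))
      codons[arch$internal_codon[i] + 1L] <- "ATG"
    orf_seq <- paste(codons, collapse = "")
    if (arch$strand[i] == "-") orf_seq <- revcomp_chr(orf_seq)
    bases[(orf_start[i] + 1L):orf_end[i]] <- strsplit(orf_seq, "")[[1]]
  }
  plus <- arch$strand == "+"
  anchors <- data.frame(
    gene_id = arch$gene_id,
    main_tss = ifelse(plus, orf_start - arch$main_off, orf_end - 1L + arch$main_off),
    alt_tss = ifelse(plus, orf_start - arch$alt_off, orf_end - 1L + arch$alt_off),
    main_tes = ifelse(plus, orf_end + arch$tes_off, orf_start - 1L - arch$tes_off),
    internal_tss = ifelse(is.na(arch$internal_codon), NA_integer_,
                          ifelse(plus, orf_start + 3L * arch$internal_codon,
                                 orf_end - 1L - 3L * arch$internal_codon)),
    tract_start = NA_integer_, tract_end = NA_integer_,
    artifact_pos = NA_integer_, stringsAsFactors = FALSE)
  if (n_priming > 0) {
    prim <- sample.int(n, min(n_priming, n))
    for (i in prim) {
      if (plus[i]) {
        ts <- orf_end[i] + 300L
        bases[(ts + 1L):(ts + 20L)] <- "A"
        anchors$tract_start[i] <- ts; anchors$tract_end[i] <- ts + 20L
        anchors$artifact_pos[i] <- ts - 3L
      } else {
        te <- orf_start[i] - 300L          # tract end (half-open)
        bases[(te - 19L):te] <- "T"
        anchors$tract_start[i] <- te - 20L; anchors$tract_end[i] <- te
        anchors$artifact_pos[i] <- te - 1L + 3L
      }
    }
  }
  genome <- c(chrS = paste(bases, collapse = ""))
  genes <- data.frame(gene_id = arch$gene_id, contig = "chrS",
                      strand = arch$strand, orf_start = orf_start,
                      orf_end = orf_end, stringsAsFactors = FALSE)
  class(genes) <- c("gene_models", "data.frame")
  # disrupt accidental tracts that could swallow a genuine TES site
  genome <- break_accidental_tracts(genome, anchors)
  tracts <- find_polyA_tracts(genome)
  list(genome = genome, genes = genes, anchors = anchors, tracts = tracts)
}

# mutate accidental A/T tracts lying within reach of a planted TES cluster
# region so only planted priming artifacts are filterable truth
break_accidental_tracts <- function(genome, anchors, reach = 45L) {
  repeat {
    tracts <- find_polyA_tracts(genome)
    planted <- !is.na(anchors$tract_start)
    is_planted <- rep(FALSE, nrow(tracts))
    for (i in which(planted)) {
      is_planted <- is_planted | (tracts$start <= anchors$tract_start[i] &
                                    tracts$end >= anchors$tract_end[i])
    }
    tes <- anchors$main_tes
    danger <- rep(FALSE, nrow(tracts))
    for (k in seq_len(nrow(tracts))) {
      if (is_planted[k]) next
      danger[k] <- any(abs(tes - tracts$start[k]) <= reach |
                         abs(tes - tracts$end[k]) <= reach)
    }
    if (!any(danger)) return(genome)
    bases <- strsplit(genome[[1]], "")[[1]]
    for (k in which(danger)) {
      idx <- seq.int(tracts$start[k] + 1L, tracts$end[k], by = 2L)
      bases[idx] <- "C"
    }
    genome[[1]] <- paste(bases, collapse = "")
  }
}

# spread an expected cluster count over a geometric positional profile and
# draw one replicate (NB total, multinomial positions)
draw_cluster_counts <- function(anchor, strand, mean_total, dispersion,
                                profile_len = 12L, decay = 0.5) {
  w <- decay^(0:(profile_len - 1L)); w <- w / sum(w)
  total <- if (mean_total <= 0) 0L
           else if (dispersion <= 0) stats::rpois(1, mean_total)
           else stats::rnbinom(1, mu = mean_total, size = 1 / dispersion)
  if (total == 0) return(NULL)
  counts <- stats::rmultinom(1, total, w)[, 1]
  offs <- 0:(profile_len - 1L)
  pos <- if (strand == "+") anchor + offs else anchor - offs
  keep <- counts > 0
  data.frame(pos = pos[keep], count = counts[keep])
}

#' Simulate end-count tracks from a planted architecture
#'
#' For every cluster, timepoint and replicate, the expected total count is
#' expected TPM x library_size / 1e6, spread over a geometrically decaying
#' ~12 nt positional profile downstream of the anchor, with the replicate
#' total drawn negative-binomially (variance m + dispersion m^2; Poisson at
#' dispersion 0). A per-timepoint ballast cluster in the 3' spacer region
#' tops each library up to 1e6 expected TPM so realised TPM matches the
#' planted values. Spurious promoter clusters are mirrored into a
#' non-decapping control track; priming-artifact 3' ends are placed
#' adjacent to the planted poly(A) tracts; a dense mRNA-coverage track
#' consistent with the isoform spans and a per-gene occupancy-change
#' covariate (raised on repressed genes) are emitted.
#'
#' @param arch a `synth_architecture` table.
#' @param layout result of [generate_genome_and_annotation()].
#' @param n_replicates replicates per timepoint (default 3).
#' @param library_size expected counted ends per library (default 2e6).
#' @param dispersion negative-binomial dispersion (default 0.05).
#' @param n_spurious how many genes get a planted spurious (non-capped)
#'   TSS cluster inside their ORF.
#' @param make_tes also simulate TES tracks (default TRUE).
#' @param seed integer seed.
#' @return List with `tss_tracks`, `tes_tracks` (named lists of raw
#'   `end_track`s per sample), `nondecapped` (control `end_track`),
#'   `rna_coverage` (`coverage_track`), `occupancy` (named numeric),
#'   `sample_info`, `config` (a `transition_config`), and `truth` (the
#'   architecture plus anchors plus spurious cluster coordinates).
#' @export
simulate_tracks <- function(arch, layout, n_replicates = 3,
                            library_size = 2e6, dispersion = 0.05,
                            n_spurious = 0, make_tes = TRUE, seed = 1) {
  set.seed(seed + 2L)
  timepoints <- attr(arch, "timepoints")
  anchors <- layout$anchors
  n <- nrow(arch)
  contig <- layout$genes$contig[1]
  contig_len <- nchar(layout$genome[[contig]])
  spurious_gene <- rep(FALSE, n)
  if (n_spurious > 0) {
    cand <- which(!arch$has_internal)
    spurious_gene[sample(cand, min(n_spurious, length(cand)))] <- TRUE
  }
  plus <- arch$strand == "+"
  spur_pos <- ifelse(spurious_gene,
                     ifelse(plus, layout$genes$orf_start + arch$orf_len %/% 2L,
                            layout$genes$orf_end - 1L - arch$orf_len %/% 2L),
                     NA_integer_)
  spur_tpm <- 25
  # library ballast: the rest of the transcriptome, emulated as many stable
  # spacer clusters so size-factor estimation sees a mostly-unchanged majority
  # and library-size fluctuation stays at the few-percent scale
  ballast_anchors <- contig_len - 18000L + 50L * (0:299)
  samples <- expand.grid(replicate = seq_len(n_replicates),
                         timepoint = timepoints, stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_r%d", samples$timepoint, samples$replicate)
  one_track <- function(spec_rows, sample_id, timepoint, replicate, kind) {
    parts <- lapply(seq_len(nrow(spec_rows)), function(i) {
      d <- draw_cluster_counts(spec_rows$anchor[i], spec_rows$strand[i],
                               spec_rows$tpm[i] * library_size / 1e6,
                               dispersion)
      if (is.null(d)) return(NULL)
      d$contig <- contig; d$strand <- spec_rows$strand[i]
      d
    })
    tab <- do.call(rbind, parts)
    if (is.null(tab))
      tab <- data.frame(contig = character(), pos = integer(),
                        strand = character(), count = numeric())
    counts <- rowsum(tab$count, paste(tab$strand, tab$pos))
    key <- do.call(rbind, strsplit(rownames(counts), " ", fixed = TRUE))
    end_track(data.frame(contig = contig, pos = as.integer(key[, 2]),
                         strand = key[, 1], count = counts[, 1],
                         stringsAsFactors = FALSE),
              sample_id = sample_id, timepoint = timepoint,
              replicate = replicate, kind = kind)
  }
  tss_tracks <- list(); tes_tracks <- list()
  for (s in seq_len(nrow(samples))) {
    tp <- samples$timepoint[s]
    tss_spec <- rbind(
      data.frame(anchor = anchors$main_tss, strand = arch$strand,
                 tpm = arch[[paste0("main_tpm_", tp)]]),
      data.frame(anchor = anchors$alt_tss, strand = arch$strand,
                 tpm = arch[[paste0("alt_tpm_", tp)]]),
      data.frame(anchor = anchors$internal_tss, strand = arch$strand,
                 tpm = arch[[paste0("int_tpm_", tp)]]),
      data.frame(anchor = spur_pos, strand = arch$strand,
                 tpm = ifelse(spurious_gene, spur_tpm, 0)))
    tss_spec <- tss_spec[!is.na(tss_spec$anchor) & tss_spec$tpm > 0, ]
    tss_spec <- rbind(tss_spec,
                      data.frame(anchor = ballast_anchors, strand = "+",
                                 tpm = max(1e6 - sum(tss_spec$tpm), 0) / 300))
    tss_tracks[[samples$sample_id[s]]] <-
      one_track(tss_spec, samples$sample_id[s], tp, samples$replicate[s], "TSS")
    if (make_tes) {
      tes_tpm <- arch[[paste0("main_tpm_", tp)]] + arch[[paste0("alt_tpm_", tp)]]
      tes_spec <- rbind(
        data.frame(anchor = anchors$main_tes, strand = arch$strand, tpm = tes_tpm),
        data.frame(anchor = anchors$artifact_pos, strand = arch$strand,
                   tpm = ifelse(is.na(anchors$artifact_pos), 0, 8)))
      tes_spec <- tes_spec[!is.na(tes_spec$anchor) & tes_spec$tpm > 0, ]
      tes_spec <- rbind(tes_spec,
                        data.frame(anchor = ballast_anchors, strand = "+",
                                   tpm = max(1e6 - sum(tes_spec$tpm), 0) / 300))
      tes_tracks[[samples$sample_id[s]]] <-
        one_track(tes_spec, samples$sample_id[s], tp, samples$replicate[s], "TES")
    }
  }
  # non-decapping control: only the spurious clusters survive
  nd_spec <- data.frame(anchor = spur_pos[spurious_gene],
                        strand = arch$strand[spurious_gene],
                        tpm = rep(spur_tpm, sum(spurious_gene)))
  nondecapped <- if (nrow(nd_spec))
    one_track(nd_spec, "nondecapped", timepoints[1], 1L, "TSS")
  else end_track(data.frame(contig = character(), pos = integer(),
                            strand = character(), count = numeric()),
                 sample_id = "nondecapped", kind = "TSS")
  # mRNA coverage: constant over each isoform span at its maximal TPM
  cov <- list()
  cov[[contig]] <- list("+" = numeric(contig_len), "-" = numeric(contig_len))
  tp_cols <- function(prefix) paste0(prefix, "_tpm_", timepoints)
  add_span <- function(strand, from, to, value) {
    lo <- max(min(from, to), 0L); hi <- min(max(from, to), contig_len - 1L)
    cov[[contig]][[strand]][(lo + 1L):(hi + 1L)] <<-
      cov[[contig]][[strand]][(lo + 1L):(hi + 1L)] + value
  }
  for (i in seq_len(n)) {
    st <- arch$strand[i]
    main_max <- max(arch[i, tp_cols("main")])
    alt_max <- max(arch[i, tp_cols("alt")])
    add_span(st, anchors$main_tss[i], anchors$main_tes[i], main_max)
    add_span(st, anchors$alt_tss[i], anchors$main_tes[i], alt_max)
    if (arch$has_internal[i])
      add_span(st, anchors$internal_tss[i], anchors$main_tes[i],
               max(arch[i, tp_cols("int")]))
  }
  occupancy <- stats::rnorm(n, ifelse(arch$label == "repressed", 1, 0), 0.5)
  names(occupancy) <- arch$gene_id
  truth <- cbind(arch, anchors[match(arch$gene_id, anchors$gene_id), -1],
                 spurious_pos = spur_pos)
  list(tss_tracks = tss_tracks, tes_tracks = tes_tracks,
       nondecapped = nondecapped, rna_coverage = coverage_track(cov),
       occupancy = occupancy,
       sample_info = samples[c("sample_id", "timepoint", "replicate")],
       config = transition_config("T1", timepoints[1], timepoints[-1]),
       truth = truth)
}

#' One-call synthetic dataset
#'
#' Convenience wrapper chaining [synth_architecture()],
#' [generate_genome_and_annotation()] and [simulate_tracks()].
#'
#' @param n_genes,class_fractions,timepoints,n_internal see
#'   [synth_architecture()].
#' @param n_priming,n_spurious planted artifact counts.
#' @param n_replicates,library_size,dispersion,make_tes see
#'   [simulate_tracks()].
#' @param seed integer seed driving all three stages.
#' @return The [simulate_tracks()] bundle plus `genome`, `genes`,
#'   `tracts`.
#' @export
simulate_dataset <- function(n_genes = 300,
                             class_fractions = c(repressed = 1, coactivated = 1,
                                                 neutral = 1) / 3,
                             timepoints = c("t0", "t1", "t2", "t3"),
                             n_internal = 0, n_priming = 0, n_spurious = 0,
                             n_replicates = 3, library_size = 2e6,
                             dispersion = 0.05, make_tes = TRUE, seed = 1) {
  arch <- synth_architecture(n_genes, class_fractions, timepoints,
                             n_internal = n_internal, seed = seed)
  layout <- generate_genome_and_annotation(arch, n_priming = n_priming,
                                           seed = seed)
  sim <- simulate_tracks(arch, layout, n_replicates = n_replicates,
                         library_size = library_size, dispersion = dispersion,
                         n_spurious = n_spurious, make_tes = make_tes,
                         seed = seed)
  c(sim, list(genome = layout$genome, genes = layout$genes,
              tracts = layout$tracts, anchors = layout$anchors))
}

#' Simulate a control/mutant pair at one stage
#'
#' Planted de-repressed genes sit in the repressed state in control cells
#' (low main TSS, high upstream alternative); in the mutant their main-TSS
#' expected TPM is multiplied by `effect_size` with the alternatives
#' unchanged. All other genes are statistically exchangeable between
#' genotypes.
#'
#' @param n_genes total genes.
#' @param derepressed_fraction fraction planted as de-repressed.
#' @param effect_size main-TSS multiplier in the mutant (1 = null).
#' @param n_replicates,library_size,dispersion see [simulate_tracks()].
#' @param seed integer seed.
#' @return List: `control_tracks`, `mutant_tracks` (named lists of raw
#'   `end_track`s), `genes`, `genome`, `rna_coverage`, `truth` (with
#'   `derepressed` flags), `control_repressed_genes`.
#' @export
simulate_mutant_pair <- function(n_genes = 400, derepressed_fraction = 0.2,
                                 effect_size = 3, n_replicates = 3,
                                 library_size = 2e6, dispersion = 0.05,
                                 seed = 1) {
  n_der <- ceiling(derepressed_fraction * n_genes)
  arch <- synth_architecture(n_genes, timepoints = c("pro", "proX"),
                             seed = seed)
  # stage-specific expected TPM: derepressed genes in the repressed state
  der <- rep(FALSE, n_genes); der[seq_len(n_der)] <- TRUE
  der <- der[sample.int(n_genes)]
  main_ctl <- ifelse(der, 6, 30)
  alt_ctl <- ifelse(der, 24, 4)
  layout <- generate_genome_and_annotation(arch, seed = seed)
  anchors <- layout$anchors
  contig <- layout$genes$contig[1]
  contig_len <- nchar(layout$genome[[contig]])
  ballast_anchors <- contig_len - 18000L + 50L * (0:299)
  set.seed(seed + 3L)
  # replicate noise acts on a gene's total output (negative binomial); the
  # main/alt split within a replicate is read sampling (binomial), so the
  # stratified test's conditional model holds under exchangeability
  gen_tracks <- function(main_tpm, genotype) {
    out <- list()
    for (r in seq_len(n_replicates)) {
      gene_tot_mu <- (main_tpm + alt_ctl) * library_size / 1e6
      tot <- if (dispersion <= 0) stats::rpois(n_genes, gene_tot_mu)
             else stats::rnbinom(n_genes, mu = gene_tot_mu, size = 1 / dispersion)
      main_counts <- stats::rbinom(n_genes, tot,
                                   main_tpm / (main_tpm + alt_ctl))
      alt_counts <- tot - main_counts
      ballast_tpm <- max(1e6 - sum(main_tpm + alt_ctl), 0) / 300
      spec <- rbind(
        data.frame(anchor = anchors$main_tss, strand = arch$strand,
                   total = main_counts),
        data.frame(anchor = anchors$alt_tss, strand = arch$strand,
                   total = alt_counts),
        data.frame(anchor = ballast_anchors, strand = "+",
                   total = stats::rnbinom(300, mu = ballast_tpm *
                                            library_size / 1e6,
                                          size = if (dispersion > 0)
                                            1 / dispersion else Inf)))
      parts <- lapply(seq_len(nrow(spec)), function(i) {
        if (spec$total[i] <= 0) return(NULL)
        w <- 0.5^(0:11); w <- w / sum(w)
        cnt <- stats::rmultinom(1, spec$total[i], w)[, 1]
        offs <- 0:11
        pos <- if (spec$strand[i] == "+") spec$anchor[i] + offs
               else spec$anchor[i] - offs
        keep <- cnt > 0
        if (!any(keep)) return(NULL)
        data.frame(pos = pos[keep], count = cnt[keep], contig = contig,
                   strand = spec$strand[i])
      })
      tab <- do.call(rbind, parts)
      counts <- rowsum(tab$count, paste(tab$strand, tab$pos))
      key <- do.call(rbind, strsplit(rownames(counts), " ", fixed = TRUE))
      sid <- sprintf("%s_r%d", genotype, r)
      out[[sid]] <- end_track(
        data.frame(contig = contig, pos = as.integer(key[, 2]),
                   strand = key[, 1], count = counts[, 1],
                   stringsAsFactors = FALSE),
        sample_id = sid, timepoint = genotype, replicate = r, kind = "TSS")
    }
    out
  }
  control_tracks <- gen_tracks(main_ctl, "control")
  mutant_tracks <- gen_tracks(main_ctl * ifelse(der, effect_size, 1), "mutant")
  # coverage spanning both isoforms for assignment windows
  cov <- list(); cov[[contig]] <- list("+" = numeric(contig_len),
                                       "-" = numeric(contig_len))
  for (i in seq_len(n_genes)) {
    lo <- min(anchors$main_tss[i], anchors$alt_tss[i], anchors$main_tes[i])
    hi <- max(anchors$main_tss[i], anchors$alt_tss[i], anchors$main_tes[i])
    st <- arch$strand[i]
    cov[[contig]][[st]][(lo + 1L):(hi + 1L)] <-
      cov[[contig]][[st]][(lo + 1L):(hi + 1L)] + main_ctl[i] + alt_ctl[i]
  }
  truth <- data.frame(gene_id = arch$gene_id, derepressed = der,
                      stringsAsFactors = FALSE)
  list(control_tracks = control_tracks, mutant_tracks = mutant_tracks,
       genes = layout$genes, genome = layout$genome,
       rna_coverage = coverage_track(cov), truth = truth,
       control_repressed_genes = arch$gene_id[der],
       main_site = stats::setNames(anchors$main_tss, arch$gene_id))
}

#' Simulate determinant records with known coefficients
#'
#' Draws predictor values and a response from a linear model with the
#' given coefficients and noise chosen to hit a target generating R^2.
#' Used to validate the regression machinery by parameter recovery.
#'
#' @param n records.
#' @param beta named coefficients for `alt_level`, `pair_distance`
#'   (applied on the log2 scale) and `occupancy_change`.
#' @param r2 generating coefficient of determination.
#' @param seed integer seed.
#' @return data.frame shaped like [build_determinant_table()] output, with
#'   attributes `beta` and `r2`.
#' @export
simulate_determinant_records <- function(n = 164,
                                         beta = c(alt_level = -0.4,
                                                  pair_distance = -0.3,
                                                  occupancy_change = -0.2),
                                         r2 = 0.27, seed = 1) {
  set.seed(seed)
  alt <- stats::rnorm(n, 3, 1)
  logdist <- stats::rnorm(n, 7, 1)
  occ <- stats::rnorm(n, 0, 1)
  signal <- beta[["alt_level"]] * alt + beta[["pair_distance"]] * logdist +
    beta[["occupancy_change"]] * occ
  # unit-variance independent predictors: var(signal) = sum(beta^2)
  sigma <- sqrt(sum(beta^2) * (1 - r2) / r2)
  y <- signal + stats::rnorm(n, 0, sigma)
  out <- data.frame(gene_id = sprintf("g%04d", seq_len(n)), transition = "T1",
                    pair_distance = 2^logdist, alt_level = alt,
                    main_prior_level = stats::rlnorm(n, 2, 1),
                    main_log2fc = y, occupancy_change = occ,
                    stringsAsFactors = FALSE)
  attr(out, "beta") <- beta
  attr(out, "r2") <- r2
  out
}
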