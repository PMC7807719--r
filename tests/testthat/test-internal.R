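test_that("internal classification is half-open on the ORF interval", {
  g <- list(gene_id = "g", contig = "c", strand = "+", orf_start = 100L,
            orf_end = 400L)
  expect_true(classify_internal(list(apex = 100L), g))
  expect_false(classify_internal(list(apex = 400L), g))
  expect_true(classify_internal(list(apex = 399L), g))
})

test_that("relaxed and stringent cutoffs apply fold, fraction and length floors", {
  d <- data.frame(cluster_id = "i", timepoint = c("t1", "t2"),
                  log2fc = c(1.4, 0.2), p = NA, padj = c(0.01, 0.9),
                  significant_up = c(TRUE, FALSE),
                  significant_down = FALSE, stringsAsFactors = FALSE)
  expect_true(relaxed_filter("i", d))
  d_ns <- d; d_ns$significant_up <- FALSE
  expect_false(relaxed_filter("i", d_ns))

  tpm <- matrix(c(10, 24, 2, 30), 2,
                dimnames = list(c("i", "m"), c("t1", "t2")))
  expect_true(stringent_filter("i", "m", d, tpm, orf_len = 450))   # 10 >= 8
  tpm_low <- matrix(c(7, 24, 2, 30), 2,
                    dimnames = list(c("i", "m"), c("t1", "t2")))
  expect_false(stringent_filter("i", "m", d, tpm_low, orf_len = 450))
  expect_false(stringent_filter("i", "m", d, tpm, orf_len = 297))  # length floor
  expect_false(stringent_filter("i", NA_character_, d, tpm, orf_len = 450))
})

test_that("ORF prediction finds the planted truncated frame on both strands", {
  # plus-strand gene: ATG + 199 non-stop codons + TAA, internal ATG at codon 50
  set.seed(17)
  arch <- synth_architecture(n_genes = 6, n_internal = 6,
                             class_fractions = c(repressed = 0,
                                                 coactivated = 0, neutral = 1),
                             seed = 17)
  layout <- generate_genome_and_annotation(arch, seed = 17)
  for (i in seq_len(6)) {
    g <- layout$genes[i, ]
    apex <- layout$anchors$internal_tss[i]
    orf <- predict_orf(layout$genome, apex, g, min_len = 300)
    expect_false(is.null(orf))
    planted_len <- arch$orf_len[i] - 3L * arch$internal_codon[i]
    expect_equal(orf$length, planted_len)
    expect_equal(leader_length(layout$genome, apex, g), 0L)
  }
})

test_that("ORF and leader computations match brute-force scans", {
  set.seed(19)
  for (i in 1:120) {
    strand <- sample(c("+", "-"), 1)
    orf_len <- 3L * sample(120:250, 1)
    win_len <- sample(200:700, 1)
    g <- list(gene_id = "g", contig = "c", strand = strand,
              orf_start = 1000L, orf_end = 1000L + orf_len)
    contig_len <- 3000L + orf_len
    seqs <- paste(sample(c("A", "C", "G", "T"), contig_len, TRUE), collapse = "")
    genome <- c(c = seqs)
    apex <- if (strand == "+") g$orf_end - win_len else g$orf_start + win_len - 1L
    apex <- max(min(apex, contig_len - 1L), 0L)
    win <- if (strand == "+")
      substr(seqs, apex + 1L, g$orf_end)
    else
      paste(rev(strsplit(chartr("ACGT", "TGCA",
                                substr(seqs, g$orf_start + 1L, apex + 1L)),
                         "")[[1]]), collapse = "")
    got <- predict_orf(genome, apex, g, min_len = 150)
    want <- oracle_orf(win, 150)
    expect_equal(is.null(got), is.null(want))
    if (!is.null(got)) {
      expect_equal(got$length, want$len)
      if (strand == "+") expect_equal(got$orf_start, apex + want$start)
      else expect_equal(got$orf_end, apex - want$start + 1L)
    }
    expect_equal(leader_length(genome, apex, g), oracle_leader(win))
  }
})

test_that("mirrored constructs give identical ORF and leader lengths", {
  set.seed(23)
  for (i in 1:40) {
    L <- 3L * sample(100:200, 1)
    core <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    gp <- list(gene_id = "g", contig = "c", strand = "+",
               orf_start = 10L, orf_end = 10L + L)
    genome_p <- c(c = paste0(strrep("G", 10), core, strrep("G", 10)))
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", core), "")[[1]]),
                collapse = "")
    gm <- list(gene_id = "g", contig = "c", strand = "-",
               orf_start = 10L, orf_end = 10L + L)
    genome_m <- c(c = paste0(strrep("G", 10), rc, strrep("G", 10)))
    off <- sample(0:(L - 10L), 1)
    apex_p <- 10L + off
    apex_m <- 10L + L - 1L - off
    op <- predict_orf(genome_p, apex_p, gp, min_len = 60)
    om <- predict_orf(genome_m, apex_m, gm, min_len = 60)
    expect_equal(is.null(op), is.null(om))
    if (!is.null(op)) expect_equal(op$length, om$length)
    expect_equal(leader_length(genome_p, apex_p, gp),
                 leader_length(genome_m, apex_m, gm))
  }
})

test_that("stringent internal calls are a subset of relaxed calls", {
  sim <- simulate_dataset(n_genes = 40, n_internal = 12, seed = 29,
                          make_tes = FALSE,
                          class_fractions = c(repressed = 0.2,
                                              coactivated = 0.2,
                                              neutral = 0.6))
  bundle <- run_pipeline(sim$tss_tracks, sim$sample_info, sim$config,
                         sim$genes, sim$rna_coverage, genome = sim$genome)
  ic <- bundle$internal
  expect_gt(nrow(ic), 0)
  expect_true(all(!ic$stringent | ic$relaxed))
})
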