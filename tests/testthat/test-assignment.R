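one_gene <- function(strand = "+", orf_start = 2000L, orf_end = 2900L) {
  g <- data.frame(gene_id = "g1", contig = "chr1", strand = strand,
                  orf_start = orf_start, orf_end = orf_end,
                  stringsAsFactors = FALSE)
  class(g) <- c("gene_models", "data.frame")
  g
}

clus <- function(apex, strand = "+", id = "c1")
  data.frame(cluster_id = id, contig = "chr1", strand = strand,
             start = apex, end = apex + 1L, apex = apex, kind = "TSS",
             stringsAsFactors = FALSE)

test_that("TSS rule tiers: near distance, coverage-gated far, internal", {
  g <- one_gene()
  cov <- flat_coverage(4000)
  near <- assign_tss(clus(2000L - 80L), g, cov)
  expect_equal(near$category, "upstream")
  expect_equal(near$utr_length, 80L)

  far <- assign_tss(clus(2000L - 500L), g, cov)
  expect_equal(far$gene_id, "g1")

  # a 40-nt zero-coverage hole in the gap defeats every-window medians
  hole <- flat_coverage(4000)
  hole$cov$chr1[["+"]][1700:1740] <- 0
  expect_null(assign_tss(clus(2000L - 500L), g, hole))

  internal <- assign_tss(clus(2100L), g, cov)
  expect_equal(internal$category, "internal")
  expect_true(is.na(internal$utr_length))

  expect_null(assign_tss(clus(2000L - 1500L), g, cov))  # beyond 1000
})

test_that("TES rules add the 5 percent median and 5x max gene-body criteria", {
  g <- one_gene()
  cov <- flat_coverage(4000, value = 10)
  near <- assign_tes(clus(2900L + 60L, id = "t1"), g, cov)
  expect_equal(near$category, "downstream")
  expect_equal(near$utr_length, 60L)

  ok_far <- assign_tes(clus(2900L + 400L, id = "t1"), g, cov)
  expect_equal(ok_far$gene_id, "g1")

  # one window max exceeding 5x the gene-body max defeats assignment
  spike <- flat_coverage(4000, value = 10)
  spike$cov$chr1[["+"]][3100] <- 61
  expect_null(assign_tes(clus(2900L + 400L, id = "t1"), g, spike))

  # window medians below 5% of the gene-body median defeat assignment
  low <- flat_coverage(4000, value = 10)
  low$cov$chr1[["+"]][3000:3300] <- 0.4
  expect_null(assign_tes(clus(2900L + 400L, id = "t1"), g, low))
})

test_that("UTR lengths follow the apex-to-codon definitions and adjacency", {
  g <- one_gene()
  cov <- flat_coverage(4000)
  a <- assign_tss(clus(2000L - 75L), g, cov)
  expect_equal(utr_length(a), 75L)
  b <- assign_tes(clus(2900L + 1L, id = "t"), g, cov)
  expect_equal(utr_length(b), 1L)
})

test_that("minus-strand assignment mirrors plus-strand lengths exactly", {
  cov <- flat_coverage(5000, value = 4)
  for (d in c(30L, 75L, 99L, 100L, 101L, 400L, 999L, 1000L)) {
    gp <- one_gene("+")
    gm <- one_gene("-")
    ap <- assign_tss(clus(2000L - d), gp, cov)
    am <- assign_tss(clus(2900L - 1L + d, strand = "-"), gm, cov)
    expect_equal(is.null(ap), is.null(am))
    if (!is.null(ap)) expect_equal(ap$utr_length, am$utr_length)
    tp <- assign_tes(clus(2900L + d, id = "t"), gp, cov)
    tm <- assign_tes(clus(2000L - 1L - d, strand = "-", id = "t"), gm, cov)
    expect_equal(is.null(tp), is.null(tm))
    if (!is.null(tp)) expect_equal(tp$utr_length, tm$utr_length)
  }
  expect_null(assign_tss(clus(2000L - 1001L), one_gene("+"), cov))
})

test_that("sliding-window decisions match an independent window-walk oracle", {
  set.seed(13)
  g <- one_gene()
  for (i in 1:250) {
    d <- sample(c(101:1000), 1)
    apex <- 2000L - d
    vals <- rpois(d, lambda = sample(c(0.4, 1, 3), 1))
    if (runif(1) < 0.3) {  # plant a hole
      h0 <- sample(seq_len(max(d - 40, 1)), 1)
      vals[h0:min(h0 + 39, d)] <- 0
    }
    cov <- flat_coverage(4000, 0)
    cov$cov$chr1[["+"]][(apex + 1):2000] <- vals
    got <- assign_tss(clus(apex), g, cov)
    want <- oracle_windows_ok(vals, 30)
    expect_equal(!is.null(got), want)
  }
  # TES side with body criteria
  for (i in 1:250) {
    d <- sample(c(101:1000), 1)
    apex <- 2900L + d
    body <- rpois(900, 8) + 1
    vals <- rpois(d + 1, sample(c(0.3, 2, 8, 30), 1))  # [ORF end .. apex]
    cov <- flat_coverage(4000, 0)
    cov$cov$chr1[["+"]][2001:2900] <- body
    cov$cov$chr1[["+"]][2901:(2901 + d)] <- vals
    got <- assign_tes(clus(apex, id = "t"), g, cov)
    want <- oracle_windows_ok(vals, 30, body = body, median_frac = 0.05,
                              max_mult = 5)
    expect_equal(!is.null(got), want)
  }
})

test_that("each cluster is assigned to at most one closest gene deterministically", {
  g2 <- rbind(one_gene(), one_gene())
  g2$gene_id <- c("gA", "gB")
  g2$orf_start <- c(2000L, 5000L); g2$orf_end <- c(2900L, 5900L)
  class(g2) <- c("gene_models", "data.frame")
  cov <- flat_coverage(7000)
  a <- assign_tss(clus(1950L), g2, cov)
  expect_equal(a$gene_id, "gA")
  b <- assign_tss(clus(4950L), g2, cov)
  expect_equal(b$gene_id, "gB")
  expect_identical(assign_tss(clus(1950L), g2, cov),
                   assign_tss(clus(1950L), g2, cov))
})
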