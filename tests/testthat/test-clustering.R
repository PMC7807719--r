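test_that("TPM normalization follows the definition and conserves mass", {
  tr <- make_track(c(10, 20), c(10, 990))
  tr$library_size <- 1e6
  tp <- normalize_tpm(tr)
  expect_equal(tp$counts$tpm[1], 10)
  set.seed(1)
  tr <- make_track(sample(1:1000, 50), rpois(50, 20) + 1)
  tp <- normalize_tpm(tr)
  expect_equal(sum(tp$counts$tpm), 1e6, tolerance = 1e-9)
  empty <- make_track(integer(0), numeric(0))
  expect_error(normalize_tpm(empty), "empty library")
})

test_that("tag clusters group by gap and apply the singleton floor", {
  tp <- make_tpm(c(100, 103, 120), c(5, 2, 1))
  cl <- call_tag_clusters(tp, max_dist = 5, singleton_floor_tpm = 3)
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$start, cl$end), c(100L, 104L))
  expect_equal(cl$tpm, 7)

  # floor is inclusive
  single <- call_tag_clusters(make_tpm(50, 3.0))
  expect_equal(nrow(single), 1)
  below <- call_tag_clusters(make_tpm(50, 2.999))
  expect_equal(nrow(below), 0)

  empty <- make_tpm(integer(0), numeric(0))
  expect_equal(nrow(call_tag_clusters(empty)), 0)
  expect_error(call_tag_clusters(tp, max_dist = -1))
})

test_that("tag clustering matches the O(n^2) linkage oracle on random tracks", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(1:60, 1)
    pos <- sort(sample(0:300, n))
    tpm <- round(runif(n, 0.5, 8), 3)
    md <- sample(1:8, 1)
    got <- call_tag_clusters(make_tpm(pos, tpm), max_dist = md)
    want <- oracle_clusters(pos, tpm, md)
    want <- want[order(vapply(want, function(w) w$pos[1], numeric(1)))]
    expect_equal(nrow(got), length(want))
    for (k in seq_along(want)) {
      expect_equal(got$start[k], min(want[[k]]$pos))
      expect_equal(got$end[k], max(want[[k]]$pos) + 1L)
      expect_equal(got$tpm[k], want[[k]]$tpm)
    }
  }
})

test_that("aggregation merges retained spans transitively and trims quantiles", {
  s1 <- data.frame(contig = "chr1", strand = "+", start = 100L, end = 110L,
                   tpm = 5, n_pos = 3)
  s2 <- data.frame(contig = "chr1", strand = "+", start = 115L, end = 120L,
                   tpm = 4, n_pos = 2)
  pooled <- make_tpm(c(100, 105, 109, 115, 119), c(2, 3, 1, 2, 1))
  agg <- aggregate_clusters(list(a = s1, b = s2), pooled, max_dist = 20)
  expect_equal(nrow(agg$clusters), 1)

  # worked trim example: 20 unit-TPM positions keep the central 90% of mass
  s <- data.frame(contig = "chr1", strand = "+", start = 100L, end = 120L,
                  tpm = 20, n_pos = 20)
  pooled <- make_tpm(100:119, rep(1, 20))
  agg <- aggregate_clusters(list(a = s), pooled)
  expect_equal(agg$clusters$start, 101L)
  expect_equal(agg$clusters$end, 119L)

  # below-threshold samples leave an empty consensus
  weak <- data.frame(contig = "chr1", strand = "+", start = 5L, end = 6L,
                     tpm = 0.5, n_pos = 1)
  expect_equal(nrow(aggregate_clusters(list(a = weak),
                                       make_tpm(5, 0.5))$clusters), 0)
  expect_error(aggregate_clusters(list(a = s), pooled, q_low = 0.9, q_up = 0.1))
})

test_that("apex is the pooled argmax with a 5'-most tie-break", {
  pooled <- make_tpm(c(100, 105), c(2, 9))
  expect_equal(cluster_apex(list(contig = "chr1", strand = "+", start = 100,
                                 end = 106), pooled), 105)
  tie <- make_tpm(c(100, 101), c(5, 5))
  expect_equal(cluster_apex(list(contig = "chr1", strand = "+", start = 100,
                                 end = 102), tie), 100)
  tie_m <- make_tpm(c(100, 101), c(5, 5), strand = "-")
  expect_equal(cluster_apex(list(contig = "chr1", strand = "-", start = 100,
                                 end = 102), tie_m), 101)
  zero <- make_tpm(100, 0)
  expect_error(cluster_apex(list(contig = "chr1", strand = "+", start = 100,
                                 end = 101), zero))
})

test_that("consensus clusters are disjoint, contain their apex, and never widen", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:80, 1)
    pos <- sort(sample(0:400, n))
    tpm <- round(runif(n, 0.2, 6), 3)
    tp <- make_tpm(pos, tpm)
    per <- call_tag_clusters(tp, max_dist = 5, singleton_floor_tpm = 0)
    agg <- aggregate_clusters(list(a = per), tp, tpm_threshold = 0.5)
    cl <- agg$clusters
    if (nrow(cl) >= 2) {
      expect_true(all(cl$start[-1] >= cl$end[-nrow(cl)]))
    }
    expect_true(all(cl$apex >= cl$start & cl$apex < cl$end))
    # trimmed intervals sit inside the merged untrimmed spans
    expect_true(all(cl$start >= min(per$start) & cl$end <= max(per$end)))
  }
})

test_that("per-sample quantification sums track values over trimmed intervals", {
  t1 <- make_tpm(c(10, 11, 60), c(2, 3, 4), sample_id = "s1")
  t2 <- make_tpm(c(10, 61), c(1, 2), sample_id = "s2")
  per <- lapply(list(s1 = t1, s2 = t2), call_tag_clusters,
                max_dist = 5, singleton_floor_tpm = 0)
  pooled <- pool_tpm(list(t1, t2))
  agg <- aggregate_clusters(per, pooled, tpm_tracks = list(s1 = t1, s2 = t2),
                            tpm_threshold = 1)
  expect_equal(dim(agg$tpm), c(2L, 2L))
  expect_equal(unname(agg$tpm[1, ]), c(5, 1))
  expect_equal(unname(agg$tpm[2, ]), c(4, 2))
})
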