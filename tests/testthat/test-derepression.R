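stack_of <- function(...) {
  tabs <- list(...)
  arr <- array(0, c(2, 2, length(tabs)))
  for (k in seq_along(tabs)) arr[, , k] <- tabs[[k]]
  arr
}

test_that("CMH statistic and p match the textbook formula and stats reference", {
  st <- stack_of(matrix(c(10, 30, 90, 70), 2), matrix(c(10, 30, 90, 70), 2),
                 matrix(c(10, 30, 90, 70), 2))
  got <- cmh_test(st)
  ora <- oracle_cmh(st)
  expect_equal(got$statistic, ora$statistic, tolerance = 1e-12)
  expect_equal(got$p, ora$p, tolerance = 1e-12)
  ref <- mantelhaen.test(st, correct = TRUE)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)
})

test_that("random stacks match the reference implementation everywhere", {
  set.seed(41)
  for (i in 1:1000) {
    st <- array(sample(1:80, 12, TRUE), c(2, 2, 3))
    got <- cmh_test(st)
    ref <- mantelhaen.test(st, correct = TRUE)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(got$p, ref$p.value, tolerance = 1e-6)
  }
})

test_that("identical column proportions give a null statistic", {
  st <- stack_of(matrix(c(20, 80, 10, 40), 2))
  got <- cmh_test(st, continuity = FALSE)
  expect_lt(got$statistic, 1e-20)
  expect_equal(got$p, 1, tolerance = 1e-10)
})

test_that("a single stratum reduces to the Yates chi-square up to (n-1)/n", {
  set.seed(43)
  for (i in 1:50) {
    t2 <- matrix(sample(5:60, 4, TRUE), 2)
    n <- sum(t2)
    # the Pearson correction clamps at |O - E| < 0.5 where the CMH form does
    # not; compare only informative tables
    if (abs(t2[1, 1] - sum(t2[1, ]) * sum(t2[, 1]) / n) < 0.5) next
    got <- cmh_test(array(t2, c(2, 2, 1)))$statistic
    yates <- suppressWarnings(chisq.test(t2, correct = TRUE)$statistic)
    expect_equal(got, unname(yates) * (n - 1) / n, tolerance = 1e-10)
  }
})

test_that("swapping genotype columns preserves the statistic", {
  set.seed(47)
  st <- array(sample(5:50, 12, TRUE), c(2, 2, 3))
  sw <- st[, 2:1, ]
  expect_equal(cmh_test(st)$statistic, cmh_test(sw)$statistic,
               tolerance = 1e-12)
})

test_that("degenerate strata are dropped with a warning", {
  st <- stack_of(matrix(c(0, 0, 0, 0), 2), matrix(c(10, 30, 20, 20), 2))
  expect_warning(r <- cmh_test(st), "degenerate")
  expect_equal(r$k_used, 1)
  all_deg <- stack_of(matrix(0, 2, 2))
  expect_warning(r0 <- cmh_test(all_deg))
  expect_true(is.na(r0$p))
})

test_that("relative main usage is a scale-free proportion", {
  expect_equal(relative_main_usage(10, c(10, 30)), 0.25)
  expect_equal(relative_main_usage(7, 7), 1)
  expect_true(is.na(relative_main_usage(0, c(0, 0))))
  set.seed(49)
  for (i in 1:30) {
    tpms <- runif(4, 0.1, 50); s <- runif(1, 0.1, 9)
    expect_equal(relative_main_usage(tpms[1], tpms),
                 relative_main_usage(s * tpms[1], s * tpms))
  }
})

test_that("cluster mapping picks the maximal-overlap control cluster", {
  mk <- function(df) structure(list(clusters = df, tpm = NULL, counts = NULL),
                               class = "site_clusters")
  ctl <- mk(data.frame(cluster_id = c("c1", "c2"), contig = "chr1",
                       strand = "+", start = c(100L, 130L), end = c(120L, 150L),
                       apex = c(105L, 135L), kind = "TSS",
                       stringsAsFactors = FALSE))
  mut <- mk(data.frame(cluster_id = c("m1", "m2", "m3"), contig = "chr1",
                       strand = "+", start = c(100L, 115L, 300L),
                       end = c(120L, 140L, 310L), apex = c(105L, 133L, 305L),
                       kind = "TSS", stringsAsFactors = FALSE))
  mp <- map_clusters(mut, ctl)
  expect_equal(mp$control_cluster[mp$mutant_cluster == "m1"], "c1")
  expect_equal(mp$control_cluster[mp$mutant_cluster == "m2"], "c2")  # 10 vs 5 bp
  expect_true(is.na(mp$control_cluster[mp$mutant_cluster == "m3"]))
})

test_that("de-repression calls respect the subset and direction rules", {
  stacks <- list(
    gA = stack_of(matrix(c(30, 70, 60, 40), 2), matrix(c(30, 70, 60, 40), 2),
                  matrix(c(30, 70, 60, 40), 2)),   # mutant main proportion up
    gB = stack_of(matrix(c(60, 40, 30, 70), 2), matrix(c(60, 40, 30, 70), 2),
                  matrix(c(60, 40, 30, 70), 2)),   # mutant main proportion down
    gC = stack_of(matrix(c(50, 50, 50, 50), 2), matrix(c(50, 50, 50, 50), 2),
                  matrix(c(50, 50, 50, 50), 2)))   # unchanged
  res <- call_derepression(stacks, control_repressed_genes = c("gA", "gB"))
  expect_true(res$increased_relative_expression[res$gene_id == "gA"])
  expect_true(res$derepressed[res$gene_id == "gA"])
  expect_false(res$increased_relative_expression[res$gene_id == "gB"])
  expect_false(res$derepressed[res$gene_id == "gB"])
  expect_false(res$derepressed[res$gene_id == "gC"])
  expect_true(all(!res$derepressed | res$increased_relative_expression))

  # not listed as repressed in control: increased expression but no de-repression
  res2 <- call_derepression(stacks["gA"], control_repressed_genes = character(0))
  expect_true(res2$increased_relative_expression)
  expect_false(res2$derepressed)
})
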