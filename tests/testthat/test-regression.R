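test_that("distance split and percentile subset use inclusive boundaries", {
  rec <- data.frame(gene_id = paste0("g", 1:5), transition = "T1",
                    pair_distance = c(10L, 79L, 80L, 81L, 200L),
                    alt_level = c(1, 2, 3, 4, 5),
                    main_prior_level = c(5, 4, 3, 2, 1),
                    main_log2fc = rnorm(5), occupancy_change = rnorm(5))
  sp <- split_by_distance(rec, 80)
  expect_equal(sp$proximal$pair_distance, c(10L, 79L))
  expect_equal(sp$distal$pair_distance, c(80L, 81L, 200L))
  expect_equal(nrow(split_by_distance(rec[rec$pair_distance < 80, ])$distal), 0)

  sub <- subset_by_levels(rec, 50, 50)
  # nearest-rank 50th percentiles: alt >= 3 and main <= 3, both inclusive
  expect_equal(sub$gene_id, c("g3", "g4", "g5"))
  expect_equal(nrow(subset_by_levels(rec, 0, 100)), 5)
})

test_that("uniform independent levels retain about a quarter of records", {
  set.seed(31)
  rec <- data.frame(gene_id = seq_len(4000), transition = "T1",
                    pair_distance = 100L, alt_level = runif(4000),
                    main_prior_level = runif(4000),
                    main_log2fc = 0, occupancy_change = 0)
  frac <- nrow(subset_by_levels(rec)) / 4000
  expect_lt(abs(frac - 0.25), 0.03)
})

test_that("correlation and KS behave on degenerate and linear inputs", {
  rec <- data.frame(gene_id = 1:8, transition = "T1",
                    pair_distance = c(10, 20, 30, 40, 100, 150, 200, 250),
                    alt_level = 1, main_prior_level = 1,
                    main_log2fc = log2(c(10, 20, 30, 40, 100, 150, 200, 250)),
                    occupancy_change = 0)
  ct <- correlate_and_test(rec, threshold = 80)
  expect_equal(ct$pearson_r, 1, tolerance = 1e-12)

  # identical groups: D = 0, p = 1
  same <- rbind(rec, rec)
  same$pair_distance <- rep(c(10, 200), each = 8)
  same$main_log2fc <- rep(rec$main_log2fc, 2)
  ct2 <- correlate_and_test(same, threshold = 80)
  expect_equal(ct2$ks_D, 0)
  expect_equal(ct2$ks_p, 1)
})

test_that("Pearson and KS match brute-force small-n oracles", {
  set.seed(33)
  for (i in 1:40) {
    n <- 8
    x <- rnorm(n); y <- rnorm(n)
    rec <- data.frame(gene_id = 1:n, transition = "T1",
                      pair_distance = round(2^x * 100),
                      alt_level = 1, main_prior_level = 1,
                      main_log2fc = y, occupancy_change = 0)
    ct <- correlate_and_test(rec, threshold = 100)
    lx <- log2(rec$pair_distance)
    r_oracle <- sum((lx - mean(lx)) * (y - mean(y))) /
      sqrt(sum((lx - mean(lx))^2) * sum((y - mean(y))^2))
    expect_equal(ct$pearson_r, r_oracle, tolerance = 1e-12)
    g1 <- y[rec$pair_distance < 100]; g2 <- y[rec$pair_distance >= 100]
    if (length(g1) >= 3 && length(g2) >= 3) {
      D_oracle <- max(vapply(c(g1, g2), function(t)
        abs(mean(g1 <= t) - mean(g2 <= t)), numeric(1)))
      expect_equal(ct$ks_D, D_oracle, tolerance = 1e-12)
    }
  }
})

test_that("semi-partial correlations equal simple correlations when orthogonal", {
  set.seed(35)
  n <- 64
  x1 <- rep(c(-1, 1), each = n / 2)
  x2 <- rep(c(-1, 1), times = n / 2)
  x3 <- rep(c(-1, 1, 1, -1), times = n / 4)
  y <- 0.5 * x1 - 0.3 * x2 + rnorm(n, 0, 0.5)
  rec <- data.frame(main_log2fc = y, alt_level = x1, pair_distance = 2^x2,
                    occupancy_change = x3)
  fit <- fit_multiple_regression(rec)
  expect_equal(fit$coefficients$sr, c(cor(y, x1), cor(y, x2), cor(y, x3)),
               tolerance = 1e-10)
})

test_that("sr by residual correlation equals sr by R-squared drop", {
  set.seed(37)
  n <- 50
  rec <- data.frame(main_log2fc = rnorm(n), alt_level = rnorm(n),
                    pair_distance = 2^rnorm(n, 6), occupancy_change = rnorm(n))
  rec$main_log2fc <- -0.4 * rec$alt_level - 0.3 * log2(rec$pair_distance) -
    0.2 * rec$occupancy_change + rnorm(n)
  fit <- fit_multiple_regression(rec)
  dat <- data.frame(y = rec$main_log2fc, a = rec$alt_level,
                    d = log2(rec$pair_distance), o = rec$occupancy_change)
  full <- summary(lm(y ~ a + d + o, dat))$r.squared
  for (k in 1:3) {
    drop_form <- list(y ~ d + o, y ~ a + o, y ~ a + d)[[k]]
    reduced <- summary(lm(drop_form, dat))$r.squared
    expect_equal(fit$coefficients$sr[k]^2, full - reduced, tolerance = 1e-10)
  }
  expect_equal(fit$adj_r_squared,
               1 - (1 - full) * (n - 1) / (n - 3 - 1), tolerance = 1e-12)
})

test_that("planted negative determinants are recovered across seeds", {
  ok_signs <- 0; adj <- numeric(100)
  for (s in 1:100) {
    rec <- simulate_determinant_records(n = 164, seed = s)
    fit <- fit_multiple_regression(rec)
    if (all(fit$coefficients$estimate < 0)) ok_signs <- ok_signs + 1
    adj[s] <- fit$adj_r_squared
  }
  expect_gte(ok_signs, 95)
  expect_lt(abs(mean(adj) - 0.27), 0.1)
})

test_that("collinear predictors are rejected by name", {
  rec <- data.frame(main_log2fc = rnorm(20), alt_level = 1:20,
                    pair_distance = 2^(1:20), occupancy_change = rnorm(20))
  expect_error(fit_multiple_regression(rec), "collinear")
})

test_that("the determinant table picks one alternative deterministically", {
  pairs <- data.frame(gene_id = "g1", transition = "T1",
                      alt_cluster = c("a1", "a2"), main_cluster = "m",
                      pair_distance = c(50L, 150L), stringsAsFactors = FALSE)
  diff <- data.frame(cluster_id = c("a1", "a2", "m"), timepoint = "t1",
                     log2fc = c(2, 2, -1.5), p = NA, padj = 0.001,
                     significant_up = c(TRUE, TRUE, FALSE),
                     significant_down = c(FALSE, FALSE, TRUE),
                     stringsAsFactors = FALSE)
  tpm <- matrix(c(5, 8, 3, 20, 30, 2), 3,
                dimnames = list(c("a1", "a2", "m"), c("t0", "t1")))
  cfg <- transition_config("T1", "t0", "t1")
  r1 <- build_determinant_table(pairs, diff, tpm, cfg, seed = 42)
  r2 <- build_determinant_table(pairs, diff, tpm, cfg, seed = 42)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 1)
  # a gene with no qualifying alternative is absent
  diff_ns <- diff; diff_ns$significant_up <- FALSE
  expect_equal(nrow(build_determinant_table(pairs, diff_ns, tpm, cfg)), 0)
})
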