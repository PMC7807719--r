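# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles deliberately avoid the package's own code paths.

make_track <- function(pos, count, strand = "+", contig = "chr1", ...) {
  end_track(data.frame(contig = rep(contig, length(pos)),
                       pos = as.integer(pos),
                       strand = rep(strand, length(pos)), count = count,
                       stringsAsFactors = FALSE), ...)
}

make_tpm <- function(pos, tpm, strand = "+", contig = "chr1",
                     sample_id = "s") {
  tab <- data.frame(contig = rep(contig, length(pos)),
                    pos = as.integer(pos), strand = rep(strand, length(pos)),
                    tpm = tpm, stringsAsFactors = FALSE)
  structure(list(counts = tab[order(tab$contig, tab$strand, tab$pos), ],
                 sample_id = sample_id, timepoint = NA_character_,
                 replicate = NA_integer_, kind = "TSS", library_size = 1e6),
            class = "tpm_track")
}

# O(n^2) pairwise-linkage clustering oracle: positions belong together iff
# connected through gaps <= max_dist
oracle_clusters <- function(pos, tpm, max_dist, floor_tpm = 3) {
  n <- length(pos)
  if (n == 0) return(list())
  adj <- abs(outer(pos, pos, "-")) <= max_dist
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- lapply(unique(comp), function(cc) {
    idx <- which(comp == cc)
    list(pos = sort(pos[idx]), tpm = sum(tpm[idx]))
  })
  keep <- vapply(out, function(cl)
    length(cl$pos) > 1 || cl$tpm >= floor_tpm, logical(1))
  out[keep]
}

# cumulative-quantile trim oracle on a 5'->3' walk, written as a plain loop
oracle_trim <- function(pos, val, q_low, q_up, strand) {
  ord <- order(pos, decreasing = (strand == "-"))
  pos <- pos[ord]; val <- val[ord]
  total <- sum(val)
  cum <- 0; i0 <- NA; i1 <- NA
  for (i in seq_along(pos)) {
    cum <- cum + val[i]
    if (is.na(i0) && cum > q_low * total) i0 <- i
    if (is.na(i1) && cum >= q_up * total) i1 <- i
  }
  kept <- pos[i0:i1]
  c(min(kept), max(kept) + 1L)
}

# average ranks computed by hand (no rank()), then the Pearson product-moment
# formula from raw sums, then the t-approximation p-value
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  if (den == 0) return(list(r = NA_real_, p = NA_real_))
  r <- num / den
  if (abs(r) >= 1) return(list(r = r, p = 0))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

# sliding-window walk oracle (median via sort, explicit loop)
oracle_windows_ok <- function(vals, window, body = NULL,
                              median_frac = NULL, max_mult = NULL) {
  med <- function(v) {
    s <- sort(v); m <- length(s)
    if (m %% 2 == 1) s[(m + 1) / 2] else (s[m / 2] + s[m / 2 + 1]) / 2
  }
  n <- length(vals)
  if (n == 0) return(FALSE)
  starts <- if (n <= window) 1 else 1:(n - window + 1)
  for (s in starts) {
    w <- vals[s:min(s + window - 1, n)]
    if (!(med(w) > 0)) return(FALSE)
    if (!is.null(body)) {
      if (!(med(w) >= median_frac * med(body))) return(FALSE)
      if (!(max(w) <= max_mult * max(body))) return(FALSE)
    }
  }
  TRUE
}

# 3-frame AUG..stop scan oracle walking every start position
oracle_orf <- function(win, min_len) {
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(win)
  best_len <- 0; best_start <- NA
  for (i in 0:(L - 3)) {
    if (substr(win, i + 1, i + 3) != "ATG") next
    j <- i
    found <- FALSE
    while (j + 3 <= L) {
      if (substr(win, j + 1, j + 3) %in% stops) { found <- TRUE; break }
      j <- j + 3
    }
    if (!found) next
    len <- j + 3 - i
    if (len >= min_len && (len > best_len ||
                           (len == best_len && i < best_start))) {
      best_len <- len; best_start <- i
    }
  }
  if (best_len == 0) NULL else list(start = best_start, len = best_len)
}

oracle_leader <- function(win) {
  L <- nchar(win)
  if (L < 3) return(NA_integer_)
  for (w in 0:(L - 3)) {
    if ((L - w) %% 3 == 0 && substr(win, w + 1, w + 3) == "ATG")
      return(w)
  }
  NA_integer_
}

# textbook CMH statistic straight from the formula, one term at a time
oracle_cmh <- function(stack, continuity = TRUE) {
  K <- dim(stack)[3]
  sa <- se <- sv <- 0
  for (k in 1:K) {
    t2 <- stack[, , k]
    n <- sum(t2)
    sa <- sa + t2[1, 1]
    se <- se + sum(t2[1, ]) * sum(t2[, 1]) / n
    sv <- sv + sum(t2[1, ]) * sum(t2[2, ]) * sum(t2[, 1]) * sum(t2[, 2]) /
      (n^2 * (n - 1))
  }
  delta <- abs(sa - se)
  dev <- delta - if (continuity && delta >= 0.5) 0.5 else 0
  stat <- dev^2 / sv
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# tiny deterministic coverage fixture
flat_coverage <- function(len, value = 1, contig = "chr1") {
  coverage_track(stats::setNames(list(list("+" = rep(value, len),
                                           "-" = rep(value, len))), contig))
}
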