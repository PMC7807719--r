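#' Build the determinant table for the regression analysis
#'
#' One record per gene whose upstream-external alternative TSS is
#' significantly upregulated twofold or more in the aggregated comparison
#' (one transition timepoint vs the reference). When several alternatives
#' of a gene qualify, one is chosen at random under the supplied seed.
#' Covariates: apex-to-apex pair distance, the alternative's
#' log2(TPM + pseudo) after the transition, the main cluster's TPM before
#' the transition, the main cluster's log2 fold change (the response), and
#' an externally supplied per-gene nucleosome occupancy change.
#'
#' @param pairs [build_pairs()] output.
#' @param diff DE table from [diff_expression()].
#' @param tpm_tp clusters x timepoints TPM matrix.
#' @param config a `transition_config`.
#' @param aggregate_timepoint the transition timepoint representing the
#'   aggregated comparison (default: the last configured timepoint).
#' @param occupancy named numeric vector gene_id -> occupancy change
#'   (missing genes get NA).
#' @param pseudo pseudo-count inside the log2 for the alternative level.
#' @param seed integer seed for the random single-alternative choice.
#' @return data.frame: `gene_id`, `transition`, `pair_distance`,
#'   `alt_level`, `main_prior_level`, `main_log2fc`, `occupancy_change`.
#' @export
build_determinant_table <- function(pairs, diff, tpm_tp, config,
                                    aggregate_timepoint = NULL,
                                    occupancy = NULL, pseudo = 0.5,
                                    seed = 1L) {
  tp <- if (is.null(aggregate_timepoint))
    config$timepoints[length(config$timepoints)] else aggregate_timepoint
  rows <- lapply(split(pairs, pairs$gene_id), function(pp) {
    up <- vapply(seq_len(nrow(pp)), function(i) {
      de <- de_lookup(diff, pp$alt_cluster[i], tp)
      !is.null(de) && de$significant_up
    }, logical(1))
    pp <- pp[up, , drop = FALSE]
    if (!nrow(pp)) return(NULL)
    i <- if (nrow(pp) == 1) 1L else {
      rng <- local({set.seed(seed + sum(utf8ToInt(pp$gene_id[1])))
                    sample.int(nrow(pp), 1L)})
      rng
    }
    pr <- pp[i, ]
    main_de <- de_lookup(diff, pr$main_cluster, tp)
    data.frame(gene_id = pr$gene_id, transition = pr$transition,
               pair_distance = pr$pair_distance,
               alt_level = log2(tpm_tp[pr$alt_cluster, tp] + pseudo),
               main_prior_level = tpm_tp[pr$main_cluster, config$reference],
               main_log2fc = if (is.null(main_de)) NA_real_ else main_de$log2fc,
               occupancy_change = if (is.null(occupancy)) NA_real_
                                  else unname(occupancy[pr$gene_id]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), transition = character(),
                      pair_distance = integer(), alt_level = numeric(),
                      main_prior_level = numeric(), main_log2fc = numeric(),
                      occupancy_change = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Split determinant records at a pair-distance threshold
#'
#' @param records determinant table.
#' @param threshold nt (default 80): proximal means distance < threshold,
#'   distal means distance >= threshold.
#' @return List with `proximal` and `distal` data.frames.
#' @export
split_by_distance <- function(records, threshold = 80) {
  list(proximal = records[records$pair_distance < threshold, , drop = FALSE],
       distal = records[records$pair_distance >= threshold, , drop = FALSE])
}

#' Pearson correlation and proximal/distal distribution comparison
#'
#' Pearson r (with its t-based p-value) between a covariate and the main
#' log2 fold change over all records, and a two-sample Kolmogorov-Smirnov
#' test comparing the main log2 fold-change distributions of the proximal
#' and distal groups.
#'
#' @param records determinant table.
#' @param covariate column name correlated with `main_log2fc` (default
#'   "pair_distance", on the log2 scale).
#' @param threshold distance threshold for the KS split.
#' @param log2_distance correlate log2(distance) rather than raw nt.
#' @return List: `pearson_r`, `pearson_p`, `ks_D`, `ks_p`, `n_proximal`,
#'   `n_distal`.
#' @export
correlate_and_test <- function(records, covariate = "pair_distance",
                               threshold = 80, log2_distance = TRUE) {
  x <- records[[covariate]]
  if (covariate == "pair_distance" && log2_distance) x <- log2(x)
  y <- records$main_log2fc
  ok <- is.finite(x) & is.finite(y)
  r <- NA_real_; rp <- NA_real_
  if (sum(ok) >= 3 && stats::var(x[ok]) > 0 && stats::var(y[ok]) > 0) {
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    r <- unname(ct$estimate); rp <- ct$p.value
  }
  sp <- split_by_distance(records, threshold)
  ksD <- NA_real_; ksp <- NA_real_
  if (nrow(sp$proximal) >= 3 && nrow(sp$distal) >= 3) {
    ks <- suppressWarnings(stats::ks.test(sp$proximal$main_log2fc,
                                          sp$distal$main_log2fc))
    ksD <- unname(ks$statistic); ksp <- ks$p.value
  }
  list(pearson_r = r, pearson_p = rp, ks_D = ksD, ks_p = ksp,
       n_proximal = nrow(sp$proximal), n_distal = nrow(sp$distal))
}

#' Subset records by expression-level percentiles
#'
#' Retains records whose alternative level after the transition is at or
#' above its `alt_pct`-th percentile and whose main level prior to the
#' transition is at or below its `main_pct`-th percentile (nearest-rank
#' percentiles over the current record set; both comparisons inclusive).
#'
#' @param records determinant table.
#' @param alt_pct,main_pct percentile thresholds (default 50/50).
#' @return Subset data.frame.
#' @export
subset_by_levels <- function(records, alt_pct = 50, main_pct = 50) {
  if (!nrow(records)) return(records)
  alt_thr <- stats::quantile(records$alt_level, alt_pct / 100, type = 1,
                             names = FALSE)
  main_thr <- stats::quantile(records$main_prior_level, main_pct / 100,
                              type = 1, names = FALSE)
  keep <- records$alt_level >= alt_thr & records$main_prior_level <= main_thr
  records[keep, , drop = FALSE]
}

#' Multiple regression with semi-partial correlations
#'
#' Ordinary least squares of the response on the predictors, reporting per
#' predictor the coefficient, its t-based p-value, and the semi-partial
#' (part) correlation sr: the correlation between the response and the
#' residual of that predictor regressed on the remaining predictors — the
#' unique linear contribution of the predictor.
#'
#' @param records determinant table (or any data.frame).
#' @param response response column (default "main_log2fc").
#' @param predictors predictor columns; pair distance enters as
#'   log2(distance) by default.
#' @param log2_distance transform `pair_distance` to log2 before fitting.
#' @return Object of class `determinant_fit`: list with `coefficients`
#'   (data.frame: term, estimate, sr, p), `r_squared`, `adj_r_squared`,
#'   `n`, and the underlying `lm` fit.
#' @export
fit_multiple_regression <- function(records, response = "main_log2fc",
                                    predictors = c("alt_level",
                                                   "pair_distance",
                                                   "occupancy_change"),
                                    log2_distance = TRUE) {
  dat <- records[c(response, predictors)]
  if (log2_distance && "pair_distance" %in% predictors)
    dat$pair_distance <- log2(dat$pair_distance)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  k <- length(predictors)
  n <- nrow(dat)
  if (n <= k + 2) stop("not enough complete records to fit the regression")
  X <- as.matrix(dat[predictors])
  cn <- kappa(stats::cor(X), exact = TRUE)
  if (!is.finite(cn) || cn > 1e8)
    stop("collinear predictors: ", paste(predictors, collapse = ", "))
  form <- stats::as.formula(paste(response, "~",
                                  paste(predictors, collapse = " + ")))
  fit <- stats::lm(form, data = dat)
  sm <- summary(fit)
  y <- dat[[response]]
  sr <- vapply(predictors, function(p) {
    others <- setdiff(predictors, p)
    res_x <- if (length(others)) {
      stats::resid(stats::lm(stats::as.formula(
        paste(p, "~", paste(others, collapse = " + "))), data = dat))
    } else dat[[p]] - mean(dat[[p]])
    stats::cor(y, res_x)
  }, numeric(1))
  coefs <- data.frame(term = predictors,
                      estimate = stats::coef(fit)[predictors],
                      sr = sr,
                      p = sm$coefficients[predictors, "Pr(>|t|)"],
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs,
                 r_squared = sm$r.squared,
                 adj_r_squared = 1 - (1 - sm$r.squared) * (n - 1) / (n - k - 1),
                 n = n, fit = fit),
            class = "determinant_fit")
}

#' @export
print.determinant_fit <- function(x, ...) {
  cat(sprintf("Determinant regression (n = %d)\n", x$n))
  cat(sprintf("R^2 = %.4f, adjusted R^2 = %.4f\n", x$r_squared,
              x$adj_r_squared))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
summary.determinant_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.determinant_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}
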