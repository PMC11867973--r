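# Dose-response fitting and drug sensitivity scoring. Five-point viability
# curves over a 10,000-fold concentration range are fitted with a
# four-parameter logistic (4PL); the drug sensitivity score (DSS) is the
# normalized area of the fitted percent-inhibition curve above an activity
# threshold over the log10-concentration range; screen-wide cutoffs are
# percentiles of the DSS distribution; group differences are assessed with
# an exact two-sided Wilcoxon rank-sum test.

#' DSS configuration
#' @param activity_threshold Percent inhibition that must be exceeded to
#'   accrue area (default 10).
#' @param response_cap Responses are capped here before integration
#'   (default 100).
#' @param grid_size Trapezoid integration grid points (default 1001).
#' @param percentile Percentile used by screen-wide cutoffs (default 75).
#' @return list of class `dss_config`.
#' @export
dss_config <- function(activity_threshold = 10, response_cap = 100,
                       grid_size = 1001, percentile = 75) {
  if (activity_threshold < 0 || activity_threshold >= 100)
    plex_stop("plex_config_error", "activity_threshold must be in [0, 100)")
  structure(as.list(environment()), class = "dss_config")
}

#' Fit a four-parameter logistic dose-response curve
#'
#' `y(x) = bottom + (top - bottom) / (1 + 10^(hill * (log10EC50 - x)))` in
#' `x = log10(concentration)`, fitted by bounded least squares
#' (`bottom` in [-10, 30], `top` in [0, 110], midpoint within the
#' concentration grid +/- 1 log10 unit) with a deterministic multi-start.
#' All-identical responses yield the degenerate flat fit (`hill = 0`).
#'
#' @param concentration Strictly increasing concentrations (>= 4 points).
#' @param response Percent inhibition at each concentration.
#' @return list of class `fourpl`: bottom, top, log10_ec50, hill, rss, flat.
#' @export
fit_4pl <- function(concentration, response) {
  if (length(concentration) < 4)
    plex_stop("plex_validation_error", "need >= 4 dose-response points")
  if (is.unsorted(concentration, strictly = TRUE))
    plex_stop("plex_validation_error", "concentrations must be strictly increasing")
  if (length(response) != length(concentration) || any(!is.finite(response)))
    plex_stop("plex_validation_error", "responses must be finite and match concentrations")
  x <- log10(concentration)
  if (length(unique(response)) == 1) {
    warning("all responses identical; returning degenerate flat fit")
    return(structure(list(bottom = response[1], top = response[1],
                          log10_ec50 = mean(range(x)), hill = 0, rss = 0,
                          flat = TRUE), class = "fourpl"))
  }
  lower <- c(-10, 0, min(x) - 1, 0.05)
  upper <- c(30, 110, max(x) + 1, 20)
  obj <- function(p) sum((fourpl_curve(x, p[1], p[2], p[3], p[4]) - response)^2)
  b0 <- min(max(min(response), -10), 30)
  t0 <- min(max(max(response), 0), 110)
  best <- NULL
  for (m0 in seq(min(x) - 1, max(x) + 1, length.out = 5)) {
    for (s0 in c(0.5, 1, 2)) {
      fit <- stats::optim(c(b0, t0, m0, s0), obj, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = 500, factr = 1e4))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }
  structure(list(bottom = best$par[1], top = best$par[2],
                 log10_ec50 = best$par[3], hill = best$par[4],
                 rss = best$value, flat = FALSE), class = "fourpl")
}

#' Predict from a 4PL fit
#' @param object A `fourpl` fit.
#' @param x log10 concentrations.
#' @param ... Unused.
#' @return Percent inhibition at `x`.
#' @export
predict.fourpl <- function(object, x, ...) {
  if (object$hill == 0) rep(object$top, length(x))
  else fourpl_curve(x, object$bottom, object$top, object$log10_ec50, object$hill)
}

#' Drug sensitivity score of a fitted curve
#'
#' Normalized area of the capped response above the activity threshold over
#' the log10-concentration range:
#' `DSS = 100 * integral(max(0, min(y, cap) - t)) /
#'  ((100 - t) * (x_max - x_min))`, a score in [0, 100] that is 0 when the
#' curve never exceeds the threshold.
#'
#' @param fit A `fourpl` fit.
#' @param range `c(x_min, x_max)` in log10 concentration units.
#' @param config A [dss_config()].
#' @return A numeric score in [0, 100].
#' @export
dss <- function(fit, range, config = dss_config()) {
  if (range[2] <= range[1]) plex_stop("plex_config_error", "x_max must exceed x_min")
  t <- config$activity_threshold
  xs <- seq(range[1], range[2], length.out = config$grid_size)
  yy <- pmax(0, pmin(predict.fourpl(fit, xs), config$response_cap) - t)
  h <- diff(xs[1:2])
  area <- h * (sum(yy) - (yy[1] + yy[length(yy)]) / 2)
  100 * area / ((100 - t) * (range[2] - range[1]))
}

#' DSS matrix for a dose-response panel
#'
#' Fits a 4PL per (sample, drug) and integrates it into a DSS over the
#' panel's log10 range.
#'
#' @param panel data.frame (sample, drug, concentration, response).
#' @param config A [dss_config()].
#' @return A drugs x samples numeric matrix.
#' @export
dss_matrix <- function(panel, config = dss_config()) {
  drugs <- unique(panel$drug); samples <- unique(panel$sample)
  out <- matrix(NA_real_, length(drugs), length(samples),
                dimnames = list(drugs, samples))
  for (s in samples) for (d in drugs) {
    sub <- panel[panel$sample == s & panel$drug == d, ]
    if (!nrow(sub)) next
    sub <- sub[order(sub$concentration), ]
    fit <- fit_4pl(sub$concentration, sub$response)
    out[d, s] <- dss(fit, log10(range(sub$concentration)), config)
  }
  out
}

#' Percentile cutoff of a DSS distribution
#'
#' Linear-interpolation percentile with the `h = (n - 1) p + 1` convention
#' (R's default quantile type 7).
#'
#' @param scores Numeric DSS values (>= 2).
#' @param percentile Percentile in [0, 100] (default 75).
#' @return The cutoff value.
#' @export
dss_cutoff <- function(scores, percentile = 75) {
  scores <- scores[!is.na(scores)]
  if (length(scores) < 2) plex_stop("plex_validation_error", "need >= 2 scores")
  unname(stats::quantile(scores, percentile / 100, type = 7))
}

#' Exact two-sided Wilcoxon rank-sum test
#'
#' For total sample sizes up to 25 the full null distribution of the
#' rank-sum of group A over all `choose(n, n_a)` equiprobable rank
#' assignments is computed (ties handled with mid-ranks, enumerated exactly
#' via a dynamic program over doubled ranks); the two-sided p-value is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`. Larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return list(p, statistic = rank-sum of `a`, method).
#' @export
exact_wilcoxon <- function(a, b) {
  if (!length(a) || !length(b))
    plex_stop("plex_validation_error", "both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])
  if (n <= 25) {
    d <- as.integer(round(2 * r))            # doubled mid-ranks are integers
    w2 <- as.integer(round(2 * w))
    smax <- sum(sort(d, decreasing = TRUE)[seq_len(na)])
    # dp[k + 1, s + 1] = number of k-subsets of the ranks with doubled sum s
    dp <- matrix(0, na + 1, smax + 1)
    dp[1, 1] <- 1
    for (v in d) {
      for (k in min(na, na):1) {             # descending to avoid reuse
        src <- dp[k, ]
        nz <- which(src > 0)
        if (length(nz)) {
          tgt <- nz + v
          ok <- tgt <= smax + 1
          dp[k + 1, tgt[ok]] <- dp[k + 1, tgt[ok]] + src[nz[ok]]
        }
      }
    }
    cnt <- dp[na + 1, ]
    tot <- sum(cnt)
    lo <- sum(cnt[seq_len(w2 + 1)]) / tot    # P(W <= w)
    hi <- sum(cnt[(w2 + 1):(smax + 1)]) / tot
    p <- min(1, 2 * min(lo, hi))
    return(list(p = p, statistic = w, method = "exact enumeration"))
  }
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  mu <- na * (n + 1) / 2
  sig2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sig2 <= 0) return(list(p = 1, statistic = w, method = "normal approximation"))
  z <- (abs(w - mu) - 0.5) / sqrt(sig2)
  list(p = min(1, 2 * stats::pnorm(z, lower.tail = FALSE)),
       statistic = w, method = "normal approximation")
}

#' Compare mean DSS over a drug subset between two sample groups
#'
#' Computes each sample's mean DSS over `drug_subset` and tests the two
#' label groups with [exact_wilcoxon()].
#'
#' @param dss_mat Drugs x samples DSS matrix ([dss_matrix()]).
#' @param labels Named (by sample) vector with exactly two distinct values.
#' @param drug_subset Drugs averaged per sample (non-empty).
#' @return list(sample_means, groups, p).
#' @export
group_dss_comparison <- function(dss_mat, labels, drug_subset) {
  if (!length(drug_subset)) plex_stop("plex_validation_error", "empty drug subset")
  miss <- setdiff(drug_subset, rownames(dss_mat))
  if (length(miss)) plex_stop("plex_validation_error",
                              "drugs not in matrix: %s", paste(miss, collapse = ", "))
  labels <- labels[colnames(dss_mat)]
  if (anyNA(labels)) plex_stop("plex_validation_error", "every sample needs a label")
  lv <- unique(labels)
  if (length(lv) != 2) plex_stop("plex_validation_error", "need exactly two groups")
  means <- colMeans(dss_mat[drug_subset, , drop = FALSE])
  g1 <- means[labels == lv[1]]; g2 <- means[labels == lv[2]]
  if (!length(g1) || !length(g2))
    plex_stop("plex_validation_error", "a group has no samples")
  list(sample_means = means,
       groups = split(means, labels),
       p = exact_wilcoxon(g1, g2)$p)
}
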