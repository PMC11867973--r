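# Combinatorial dual-HTO demultiplexing. The two tag families (row tags,
# column tags) are classified completely independently: counts are CLR
# transformed within the family, cells are k-means clustered in CLR space,
# each tag's background is the cluster with the lowest mean CLR for that tag,
# a negative binomial is fitted to the background's raw counts and a cell is
# called positive for a tag when its raw count exceeds the fitted
# `positive_quantile`. Cells that are singlets in both families and whose
# (row tag, column tag) pair exists in the plate map are mapped to a well and
# treatment; everything else is discarded with a reason.

#' Demultiplexing configuration
#'
#' @param positive_quantile Quantile of the fitted background distribution
#'   above which a raw tag count is called positive (default 0.99, the
#'   conventional hashing default).
#' @param k Number of k-means clusters in CLR space; default
#'   `n_tags_in_family + 1` (one cluster per tag plus one for negatives).
#' @param clr_pseudocount Pseudocount inside the CLR log.
#' @param min_background_size Minimum number of cells used for a background
#'   fit; smaller background clusters are augmented with the next-lowest
#'   clusters.
#' @param background_trim Fraction of the largest background counts dropped
#'   before the NB fit, protecting it from tag-positive cells that leak into
#'   the background cluster.
#' @param seed RNG seed for k-means.
#' @return A list of class `demux_config`.
#' @export
demux_config <- function(positive_quantile = 0.99, k = NULL,
                         clr_pseudocount = 1, min_background_size = 20,
                         background_trim = 0.005, seed = 1) {
  if (positive_quantile <= 0 || positive_quantile >= 1)
    plex_stop("plex_config_error", "positive_quantile must be in (0, 1)")
  if (!is.null(k) && k < 2) plex_stop("plex_config_error", "k must be >= 2")
  structure(as.list(environment()), class = "demux_config")
}

#' Centered log-ratio transform of tag counts
#'
#' For cell i and family tag t, `clr_it = ln(x_it + 1) - mean_t' ln(x_it' + 1)`
#' with the mean over the tags of the family, so each cell's CLR values sum
#' to zero over the family (the family is the compositional unit).
#'
#' @param tag_counts Tags x cells count matrix.
#' @param family Character vector of tag ids forming the family.
#' @param pseudocount Added inside the log (default 1).
#' @return A cells x family-tags numeric matrix.
#' @export
clr_transform <- function(tag_counts, family, pseudocount = 1) {
  if (!length(family)) plex_stop("plex_validation_error", "empty tag family")
  miss <- setdiff(family, rownames(tag_counts))
  if (length(miss)) plex_stop("plex_validation_error",
                              "tags not in matrix: %s", paste(miss, collapse = ", "))
  x <- t(as.matrix(tag_counts[family, , drop = FALSE]))
  lx <- log(x + pseudocount)
  lx - rowMeans(lx)
}

# NB maximum-likelihood fit (mean = sample mean; size by profile likelihood
# with method-of-moments initialisation). Falls back to Poisson when the
# sample is underdispersed or degenerate.
fit_background_nb <- function(x) {
  mu <- mean(x); v <- stats::var(x)
  if (!is.finite(v) || v <= mu || mu == 0) {
    return(list(mu = mu, size = Inf, poisson = TRUE))
  }
  size0 <- mu^2 / (v - mu)
  opt <- stats::optimize(function(ls) -sum(stats::dnbinom(x, size = exp(ls),
                                                          mu = mu, log = TRUE)),
                         interval = log(size0) + c(-5, 5))
  list(mu = mu, size = exp(opt$minimum), poisson = FALSE)
}

#' Classify cells against one tag family
#'
#' k-means on the family CLR matrix partitions cells into `k` clusters; for
#' each tag the cluster with the lowest mean CLR of that tag provides
#' background counts, to which a negative binomial is fitted; the positive
#' threshold `c_t` is the `positive_quantile` of the fitted distribution and
#' a cell is positive for the tag iff its raw count exceeds `c_t`. Cells are
#' then negatives (0 positive tags), singlets (exactly 1) or doublets (>= 2).
#'
#' @param tag_counts Tags x cells count matrix.
#' @param family Tag ids of the family to classify.
#' @param config A [demux_config()].
#' @return A list of class `family_call`: `class` (factor
#'   negative/singlet/doublet per cell), `tag` (the singlet tag or `NA`),
#'   `positive` (cells x tags logical matrix) and `fits` (per-tag background
#'   mu, size, threshold, Poisson-fallback flag).
#' @export
classify_family <- function(tag_counts, family, config = demux_config()) {
  k <- config$k %||% (length(family) + 1L)
  clr <- clr_transform(tag_counts, family, config$clr_pseudocount)
  n <- nrow(clr)
  if (n < k) plex_stop("plex_validation_error",
                       "too few cells (%d) for k = %d clusters", n, k)
  km <- with_seed(config$seed, stats::kmeans(clr, centers = k, nstart = 5,
                                             iter.max = 50))
  cl <- km$cluster
  sizes <- tabulate(cl, k)
  raw <- t(as.matrix(tag_counts[family, , drop = FALSE]))
  fits <- data.frame(tag = family, mu = NA_real_, size = NA_real_,
                     threshold = NA_real_, poisson = FALSE,
                     stringsAsFactors = FALSE)
  positive <- matrix(FALSE, n, length(family),
                     dimnames = list(rownames(clr), family))
  for (j in seq_along(family)) {
    cm <- vapply(seq_len(k), function(c) mean(clr[cl == c, j]), 0)
    # lowest mean CLR cluster is the tag's background; ties to the larger one
    ord <- order(cm, -sizes)
    bg_cl <- ord[1]
    bg <- which(cl == bg_cl)
    i <- 2
    while (length(bg) < config$min_background_size && i <= k) {
      bg <- c(bg, which(cl == ord[i])); i <- i + 1
    }
    if (length(bg) < 2)
      plex_stop("plex_validation_error", "background for tag %s has < 2 cells", family[j])
    x <- sort(raw[bg, j])
    drop_n <- floor(config$background_trim * length(x))
    if (drop_n > 0) x <- x[seq_len(length(x) - drop_n)]
    fit <- fit_background_nb(x)
    thr <- if (fit$poisson) {
      stats::qpois(config$positive_quantile, lambda = fit$mu)
    } else {
      stats::qnbinom(config$positive_quantile, size = fit$size, mu = fit$mu)
    }
    if (fit$poisson && stats::var(x) == 0)
      warning(sprintf("degenerate background for tag %s; Poisson fallback", family[j]))
    fits$mu[j] <- fit$mu; fits$size[j] <- fit$size
    fits$threshold[j] <- thr; fits$poisson[j] <- fit$poisson
    positive[, j] <- raw[, j] > thr
  }
  npos <- rowSums(positive)
  cls <- factor(ifelse(npos == 0, "negative",
                       ifelse(npos == 1, "singlet", "doublet")),
                levels = c("negative", "singlet", "doublet"))
  tag <- rep(NA_character_, n)
  one <- npos == 1
  tag[one] <- family[max.col(positive[one, , drop = FALSE], ties.method = "first")]
  plex_log("hashdemux", "family %s..: %d cells -> %d singlets, %d doublets, %d negatives",
           family[1], n, sum(one), sum(npos >= 2), sum(npos == 0))
  structure(list(class = cls, tag = tag, positive = positive, fits = fits,
                 cells = rownames(clr)),
            class = "family_call")
}

#' Map dual-family calls to wells and treatments
#'
#' A cell is retained iff it is a singlet in both the row and the column
#' family and its (row tag, column tag) pair addresses a well in the plate
#' map; all other cells are discarded with reason `row_not_singlet`,
#' `col_not_singlet` or `pair_not_in_map`.
#'
#' @param row_call,col_call [classify_family()] results over the same cells.
#' @param plate_map A `plate_map`.
#' @return A list of class `demux_result`: `assignments` (per-cell
#'   data.frame: barcode, row/col class and tag, status, reason, well, drug,
#'   moa, is_control) and `summary` (cell counts by outcome and the retained
#'   fraction, `NA` for empty input).
#' @export
demultiplex <- function(row_call, col_call, plate_map) {
  if (!identical(row_call$cells, col_call$cells))
    plex_stop("plex_validation_error", "row and column calls cover different cells")
  fam_tags <- c(colnames(row_call$positive), colnames(col_call$positive))
  miss <- setdiff(fam_tags, c(plate_map$row_tag, plate_map$col_tag))
  if (length(miss))
    plex_stop("plex_validation_error",
              "plate map missing tags present in calls: %s", paste(miss, collapse = ", "))
  n <- length(row_call$class)
  a <- data.frame(barcode = row_call$cells %||% paste0("cell", seq_len(n)),
                  row_class = as.character(row_call$class), row_tag = row_call$tag,
                  col_class = as.character(col_call$class), col_tag = col_call$tag,
                  stringsAsFactors = FALSE)
  key <- paste(a$row_tag, a$col_tag, sep = "\r")
  map_key <- paste(plate_map$row_tag, plate_map$col_tag, sep = "\r")
  hit <- match(key, map_key)
  reason <- ifelse(a$row_class != "singlet", "row_not_singlet",
                   ifelse(a$col_class != "singlet", "col_not_singlet",
                          ifelse(is.na(hit), "pair_not_in_map", NA)))
  retained <- is.na(reason)
  a$status <- ifelse(retained, "retained", "discarded")
  a$reason <- reason
  a$well <- ifelse(retained, plate_map$well[hit], NA)
  a$drug <- ifelse(retained, plate_map$drug[hit], NA)
  a$moa <- ifelse(retained, plate_map$moa[hit], NA)
  a$is_control <- ifelse(retained, plate_map$is_control[hit], NA)
  summ <- list(n_cells = n, n_retained = sum(retained),
               n_discarded = sum(!retained),
               reasons = table(factor(reason, levels = c("row_not_singlet",
                                                         "col_not_singlet",
                                                         "pair_not_in_map"))),
               retained_fraction = if (n > 0) sum(retained) / n else NA_real_)
  plex_log("hashdemux", "demultiplex: %d cells -> %d retained (%.1f%%)",
           n, summ$n_retained, 100 * (summ$retained_fraction %||% NA))
  structure(list(assignments = a, summary = summ), class = "demux_result")
}
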