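# Cluster-level signature activity scoring: each cluster is represented by
# the average expression of its top up- and downregulated marker genes (the
# marker panel); a gene set's score in a cluster is the mean panel expression
# of the overlapping genes minus the mean over the whole panel. Significance
# comes from bootstrapping genes within the panel; across clusters, the most
# variable sets (largest coefficient of variation) are selected.

#' Signature scoring configuration
#' @param top_k Markers per direction in the panel (default 50).
#' @param n_bootstrap Bootstrap resamples (default 1000).
#' @param cv_top_fraction Fraction of sets selected by coefficient of
#'   variation (default 0.05).
#' @param min_set_size,max_set_size Inclusive gene-set size bounds
#'   (default 10 and 500).
#' @param seed RNG seed for the bootstrap.
#' @return list of class `signature_config`.
#' @export
signature_config <- function(top_k = 50, n_bootstrap = 1000,
                             cv_top_fraction = 0.05,
                             min_set_size = 10, max_set_size = 500, seed = 1) {
  if (top_k < 1 || n_bootstrap < 1)
    plex_stop("plex_config_error", "top_k and n_bootstrap must be >= 1")
  if (cv_top_fraction <= 0 || cv_top_fraction > 1)
    plex_stop("plex_config_error", "cv_top_fraction must be in (0, 1]")
  structure(as.list(environment()), class = "signature_config")
}

#' Filter gene sets by size
#' @param collection A `gene_set_collection`.
#' @param min_size,max_size Inclusive bounds (defaults 10 and 500).
#' @return The filtered collection.
#' @export
filter_gene_sets <- function(collection, min_size = 10, max_size = 500) {
  keep <- lengths(collection) >= min_size & lengths(collection) <= max_size
  out <- collection[keep]
  attr(out, "description") <- (attr(collection, "description") %||%
                                 rep("", length(collection)))[keep]
  class(out) <- "gene_set_collection"
  out
}

#' Per-cluster marker panel expression profiles
#'
#' For each cluster, the `top_k` most upregulated and `top_k` most
#' downregulated marker genes (ranked by log2FC) form the panel; the profile
#' is the average normalized expression of each panel gene within the
#' cluster.
#'
#' @param normalized Genes x cells matrix from [normalize_log()].
#' @param clusters `cluster_assignment` or label vector.
#' @param markers [find_markers()] table.
#' @param top_k Markers per direction.
#' @return Named list (per cluster) of named numeric profiles.
#' @export
marker_profiles <- function(normalized, clusters, markers, top_k = 50) {
  cl <- if (inherits(clusters, "cluster_assignment")) clusters$cluster else clusters
  labs <- sort(unique(cl))
  X <- as.matrix(normalized)
  out <- lapply(labs, function(c) {
    m <- markers[markers$cluster == c, ]
    m <- m[order(-m$log2fc), ]
    panel <- unique(c(utils::head(m$gene, top_k), utils::tail(m$gene, top_k)))
    rowMeans(X[panel, cl == c, drop = FALSE])
  })
  names(out) <- as.character(labs)
  out
}

#' Score gene sets against cluster marker profiles
#'
#' `score(set, cluster) = mean(profile[set intersect panel]) - mean(profile)`;
#' sets with no overlap with the panel get `NA`.
#'
#' @param profiles List of per-cluster panel profiles
#'   ([marker_profiles()]).
#' @param gene_sets A `gene_set_collection`.
#' @return A sets x clusters numeric matrix (possibly with `NA`s).
#' @export
score_signatures <- function(profiles, gene_sets) {
  out <- sapply(profiles, function(pr) {
    panel <- toupper(names(pr))
    vapply(gene_sets, function(s) {
      ov <- panel %in% s
      if (!any(ov)) return(NA_real_)
      mean(pr[ov]) - mean(pr)
    }, 0)
  })
  out <- matrix(out, nrow = length(gene_sets),
                dimnames = list(names(gene_sets), names(profiles)))
  out
}

#' Bootstrap significance of signature scores
#'
#' For each (set, cluster) the null rebuilds the score from genes resampled
#' with replacement within the panel (same overlap size); the p-value is the
#' smoothed two-sided tail `(1 + #{|null| >= |observed|}) / (B + 1)`.
#'
#' @param scores [score_signatures()] matrix.
#' @param profiles The profiles used for scoring.
#' @param gene_sets The scored collection.
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed RNG seed.
#' @return Matrix of p-values shaped like `scores` (`NA` where the score is
#'   `NA`).
#' @export
bootstrap_significance <- function(scores, profiles, gene_sets, B = 1000,
                                   seed = 1) {
  if (B < 100) plex_stop("plex_config_error", "B must be >= 100")
  with_seed(seed, {
    p <- scores
    for (cn in colnames(scores)) {
      pr <- profiles[[cn]]
      m <- mean(pr)
      for (sn in rownames(scores)) {
        obs <- scores[sn, cn]
        if (is.na(obs)) next
        nov <- sum(toupper(names(pr)) %in% gene_sets[[sn]])
        null <- rowMeans(matrix(sample(pr, nov * B, replace = TRUE), B)) - m
        p[sn, cn] <- (1 + sum(abs(null) >= abs(obs))) / (B + 1)
      }
    }
    p
  })
}

#' Select the most variable gene sets across clusters
#'
#' Coefficient of variation `sd / |mean|` of each set's scores across
#' clusters; the `ceiling(fraction * n_sets)` largest CVs are selected. A set
#' with mean 0 gets CV `Inf` (ranked first) and is flagged.
#'
#' @param scores [score_signatures()] matrix.
#' @param fraction Fraction selected (default 0.05).
#' @return list(selected = set names, cv = named CVs (decreasing),
#'   flagged = sets with zero mean).
#' @export
cv_select <- function(scores, fraction = 0.05) {
  if (!nrow(scores)) plex_stop("plex_validation_error", "no sets to select from")
  mu <- rowMeans(scores, na.rm = TRUE)
  sd_ <- apply(scores, 1, stats::sd, na.rm = TRUE)
  cv <- ifelse(mu == 0, Inf, sd_ / abs(mu))
  names(cv) <- rownames(scores)
  ord <- order(-cv)
  n_sel <- ceiling(fraction * nrow(scores))
  list(selected = rownames(scores)[ord[seq_len(n_sel)]],
       cv = cv[ord],
       flagged = rownames(scores)[mu == 0])
}
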