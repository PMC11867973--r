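# Post-demultiplexing cell QC, log-normalization, shared-nearest-neighbour
# graph clustering (Leiden) and one-vs-rest marker detection.

#' QC thresholds
#'
#' Cells are kept iff `umi_min < total UMIs < umi_max` (both strict) and
#' their mitochondrial UMI percentage is strictly below the model-specific
#' maximum.
#'
#' @param umi_min,umi_max Exclusive bounds on per-cell total UMIs.
#' @param mito_pct_max Named numeric vector of exclusive per-model
#'   mitochondrial-percentage maxima.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(umi_min = 2500, umi_max = 80000,
                          mito_pct_max = c(JHOS2 = 25, PDC2 = 30, PDC3 = 20)) {
  if (!(umi_min > 0 && umi_min < umi_max))
    plex_stop("plex_config_error", "need 0 < umi_min < umi_max")
  if (any(mito_pct_max <= 0 | mito_pct_max > 100))
    plex_stop("plex_config_error", "mito_pct_max must be in (0, 100]")
  structure(list(umi_min = umi_min, umi_max = umi_max,
                 mito_pct_max = mito_pct_max), class = "qc_thresholds")
}

#' Filter cells on UMI count and mitochondrial content
#'
#' @param gene_counts Genes x cells count matrix.
#' @param mito_gene_ids Feature ids counted as mitochondrial (must be a
#'   subset of the rownames).
#' @param thresholds A [qc_thresholds()].
#' @param model Model name selecting the mitochondrial threshold.
#' @return list(counts = filtered matrix, report = entity counts per removal
#'   reason with `kept + removed = input`).
#' @export
qc_filter <- function(gene_counts, mito_gene_ids, thresholds = qc_thresholds(),
                      model) {
  if (!model %in% names(thresholds$mito_pct_max))
    plex_stop("plex_config_error", "no mitochondrial threshold configured for model '%s'", model)
  miss <- setdiff(mito_gene_ids, rownames(gene_counts))
  if (length(miss)) plex_stop("plex_validation_error",
                              "mito genes not in matrix: %s", paste(miss, collapse = ", "))
  total <- Matrix::colSums(gene_counts)
  mito <- Matrix::colSums(gene_counts[mito_gene_ids, , drop = FALSE])
  mito_pct <- ifelse(total > 0, 100 * mito / total, 0)
  ok_lo <- total > thresholds$umi_min
  ok_hi <- total < thresholds$umi_max
  ok_mt <- mito_pct < thresholds$mito_pct_max[[model]]
  keep <- ok_lo & ok_hi & ok_mt
  report <- list(n_input = ncol(gene_counts), n_kept = sum(keep),
                 n_removed = sum(!keep),
                 n_umi_low = sum(!ok_lo), n_umi_high = sum(!ok_hi),
                 n_mito = sum(!ok_mt))
  plex_log("cellqc", "qc %s: %d cells -> %d kept", model, report$n_input, report$n_kept)
  list(counts = gene_counts[, keep, drop = FALSE], report = report)
}

#' Library-size log-normalization
#'
#' `value = ln(1 + count / libsize * scale)`; the simple global-scaling
#' stand-in used in place of variance-stabilizing transforms.
#'
#' @param gene_counts Genes x cells count matrix (no zero-library cells).
#' @param scale Scale factor (default 1e4).
#' @return A genes x cells `dgCMatrix` of normalized values.
#' @export
normalize_log <- function(gene_counts, scale = 1e4) {
  m <- methods::as(Matrix::Matrix(gene_counts, sparse = TRUE), "CsparseMatrix")
  lib <- Matrix::colSums(m)
  if (any(lib == 0)) plex_stop("plex_validation_error",
                               "cell with zero library size (run QC first)")
  fac <- rep.int(scale / lib, diff(m@p))
  m@x <- log1p(m@x * fac)
  m
}

# Blocked brute-force k-nearest-neighbour search (euclidean) on a cells x dims
# matrix; returns an n x k index matrix (self excluded).
knn_index <- function(emb, k, block = 512L) {
  n <- nrow(emb)
  sq <- rowSums(emb^2)
  idx <- matrix(0L, n, k)
  for (s in seq(1, n, by = block)) {
    e <- min(s + block - 1, n)
    d2 <- outer(sq[s:e], sq, "+") - 2 * tcrossprod(emb[s:e, , drop = FALSE], emb)
    for (r in seq_len(e - s + 1)) {
      d2[r, s + r - 1] <- Inf
      idx[s + r - 1, ] <- order(d2[r, ])[seq_len(k)]
    }
  }
  idx
}

#' Cluster cells on a shared-nearest-neighbour graph
#'
#' PCA on the normalized matrix, k-nearest-neighbour graph, SNN edge weights
#' as the Jaccard overlap of neighbour sets (pruned below 1/15), and Leiden
#' community detection at the given resolution (modularity objective).
#'
#' @param normalized Genes x cells matrix from [normalize_log()].
#' @param n_neighbors Neighbourhood size (default 20).
#' @param resolution Leiden resolution (default 0.3).
#' @param seed RNG seed (clustering is deterministic for a fixed seed).
#' @param n_pcs Number of principal components (default up to 30).
#' @param prune SNN Jaccard pruning threshold (default 1/15).
#' @return A list of class `cluster_assignment`: `cluster` (integer labels,
#'   contiguous from 1, ordered by decreasing cluster size, named by cell)
#'   and the parameters used.
#' @export
cluster_cells <- function(normalized, n_neighbors = 20, resolution = 0.3,
                          seed = 1, n_pcs = 30, prune = 1 / 15) {
  n <- ncol(normalized)
  if (n < n_neighbors + 1)
    plex_stop("plex_validation_error", "fewer cells (%d) than n_neighbors + 1", n)
  x <- t(as.matrix(normalized))
  n_pcs <- min(n_pcs, ncol(x) - 1, n - 1)
  emb <- if (n_pcs >= 2) {
    stats::prcomp(x, rank. = n_pcs, center = TRUE, scale. = FALSE)$x
  } else x
  idx <- knn_index(emb, n_neighbors)
  # SNN: neighbour sets include the cell itself
  S <- Matrix::sparseMatrix(i = rep(seq_len(n), each = n_neighbors + 1),
                            j = as.vector(t(cbind(seq_len(n), idx))),
                            x = 1, dims = c(n, n))
  inter <- Matrix::tcrossprod(S)
  ksz <- n_neighbors + 1
  snn <- inter
  snn@x <- snn@x / (2 * ksz - snn@x)       # Jaccard
  snn@x[snn@x < prune] <- 0
  snn <- Matrix::drop0(snn)
  Matrix::diag(snn) <- 0
  g <- igraph::graph_from_adjacency_matrix(snn, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  memb <- with_seed(seed, igraph::cluster_leiden(
    g, objective_function = "modularity", resolution = resolution,
    n_iterations = 5)$membership)
  # contiguous labels from 1, largest cluster first
  sz <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sz), names(sz))
  cl <- unname(relab[as.character(memb)])
  names(cl) <- colnames(normalized)
  plex_log("cellqc", "clustered %d cells into %d clusters (resolution %.2f)",
           n, length(sz), resolution)
  structure(list(cluster = cl,
                 params = list(n_neighbors = n_neighbors, resolution = resolution,
                               seed = seed, n_pcs = n_pcs, prune = prune)),
            class = "cluster_assignment")
}

# Vectorized one-vs-rest Wilcoxon rank-sum p-values for all genes: mid-ranks,
# normal approximation with tie correction and continuity correction; exact
# null (via the exact rank-sum machinery) when both sides are small and the
# gene has no ties.
ranksum_p <- function(values, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group); N <- n1 + n2
  r <- rank(values)
  W <- sum(r[in_group])
  if (n1 <= 25 && n2 <= 25) {
    return(exact_wilcoxon(values[in_group], values[!in_group])$p)
  }
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  mu <- n1 * (N + 1) / 2
  sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sig2 <= 0) return(1)
  z <- (abs(W - mu) - 0.5) / sqrt(sig2)
  min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
}

#' One-vs-rest cluster markers (Wilcoxon rank-sum)
#'
#' For every cluster and gene, a rank-sum test of the cluster's cells against
#' all others with Bonferroni adjustment over all features in the dataset,
#' and the log2 fold change of mean normalized expression (pseudocount 1).
#'
#' @param normalized Genes x cells matrix from [normalize_log()].
#' @param clusters A `cluster_assignment` or an integer vector of labels.
#' @return A `data.frame` (cluster, gene, log2fc, p, p_adj) sorted within
#'   cluster by adjusted p then decreasing |log2FC|;
#'   `p_adj = min(1, p * n_features)`.
#' @export
find_markers <- function(normalized, clusters) {
  cl <- if (inherits(clusters, "cluster_assignment")) clusters$cluster else clusters
  if (length(cl) != ncol(normalized))
    plex_stop("plex_validation_error", "labels do not match cells")
  labs <- sort(unique(cl))
  if (length(labs) < 2) plex_stop("plex_validation_error", "need >= 2 clusters")
  if (any(table(cl) < 3)) plex_stop("plex_validation_error",
                                    "every cluster needs >= 3 cells")
  X <- as.matrix(normalized)
  G <- nrow(X)
  out <- lapply(labs, function(c) {
    ing <- cl == c
    p <- apply(X, 1, ranksum_p, in_group = ing)
    lfc <- log2((rowMeans(X[, ing, drop = FALSE]) + 1) /
                  (rowMeans(X[, !ing, drop = FALSE]) + 1))
    d <- data.frame(cluster = c, gene = rownames(X), log2fc = lfc,
                    p = p, p_adj = pmin(1, p * G), stringsAsFactors = FALSE)
    d[order(d$p_adj, -abs(d$log2fc)), ]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
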