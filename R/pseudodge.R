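# Subsample-pseudobulk differential expression: each (model, treatment)
# group of cells is shuffled and cut into chunks of ten, short remainders
# below five cells are dropped, groups retaining fewer than two subsets are
# excluded; chunk counts are summed into pseudobulk columns; genes below
# average log2 CPM of 1 are removed; TMM scaling factors are computed; and
# treatment vs control is tested per gene with a negative binomial
# quasi-likelihood F-test (grid adjusted-profile-likelihood dispersion with
# empirical-Bayes shrinkage, quasi-dispersion moderated with limma's
# squeezeVar), followed by Benjamini-Hochberg adjustment.

#' Subsampling configuration
#' @param chunk_size Cells per subset (default 10).
#' @param min_remainder Minimum size of a retained final short chunk
#'   (default 5).
#' @param min_subsets Minimum retained subsets per group (default 2);
#'   groups below this are excluded.
#' @param seed Stage seed; each group derives an independent stream from
#'   `seed` XOR a hash of its group key.
#' @return list of class `subsample_config`.
#' @export
subsample_config <- function(chunk_size = 10, min_remainder = 5,
                             min_subsets = 2, seed = 1) {
  if (min_remainder > chunk_size)
    plex_stop("plex_config_error", "min_remainder must be <= chunk_size")
  if (min_subsets < 2) plex_stop("plex_config_error", "min_subsets must be >= 2")
  structure(as.list(environment()), class = "subsample_config")
}

#' DGE thresholds
#' @param deg_lfc |log2FC| above which a gene is counted differentially
#'   expressed (strict; default 0.5).
#' @param ora_lfc |log2FC| above which a gene enters the per-MOA union for
#'   over-representation analysis (strict; default 0.25).
#' @param deg_fdr FDR below which a gene is significant (strict; default 0.01).
#' @param low_expr_avg_log2cpm Genes with average log2 CPM strictly below
#'   this are filtered out (default 1).
#' @param cpm_prior_count Prior count used in average log2 CPM (default 2).
#' @return list of class `dge_thresholds`.
#' @export
dge_thresholds <- function(deg_lfc = 0.5, ora_lfc = 0.25, deg_fdr = 0.01,
                           low_expr_avg_log2cpm = 1, cpm_prior_count = 2) {
  if (any(c(deg_lfc, ora_lfc, deg_fdr, cpm_prior_count) <= 0))
    plex_stop("plex_config_error", "thresholds must be positive")
  structure(as.list(environment()), class = "dge_thresholds")
}

#' Partition a cell group into subsamples
#'
#' Seeded shuffle, consecutive chunks of `chunk_size`, final short chunk kept
#' iff it has at least `min_remainder` cells; the group is excluded when
#' fewer than `min_subsets` subsets remain (under the defaults, exactly the
#' groups of 14 or fewer cells).
#'
#' @param cell_ids Character vector of cell ids.
#' @param config A [subsample_config()].
#' @param group_key Optional character key (e.g. `c(model, treatment)`) that
#'   is hashed into the group's RNG stream.
#' @return list(subsets = list of id vectors, excluded = logical,
#'   n_cells = length(cell_ids)).
#' @export
partition_group <- function(cell_ids, config = subsample_config(),
                            group_key = NULL) {
  if (!length(cell_ids)) plex_stop("plex_validation_error", "empty cell group")
  seed <- config$seed
  if (!is.null(group_key)) seed <- bitwXor(as.integer(seed), string_hash31(group_key))
  perm <- with_seed(seed, sample(cell_ids))
  n <- length(perm)
  starts <- seq(1, n, by = config$chunk_size)
  subsets <- lapply(starts, function(s) perm[s:min(s + config$chunk_size - 1, n)])
  last <- lengths(subsets)[length(subsets)]
  if (last < config$min_remainder) subsets <- subsets[-length(subsets)]
  excluded <- length(subsets) < config$min_subsets
  if (excluded) subsets <- list()
  list(subsets = subsets, excluded = excluded, n_cells = n)
}

#' Sum cell counts into pseudobulk columns
#' @param gene_counts Genes x cells count matrix.
#' @param subsets Named list of disjoint cell-id vectors.
#' @return A dense genes x subsets matrix of summed raw counts.
#' @export
aggregate_pseudobulk <- function(gene_counts, subsets) {
  ids <- unlist(subsets, use.names = FALSE)
  if (anyDuplicated(ids)) plex_stop("plex_validation_error", "subsets overlap")
  miss <- setdiff(ids, colnames(gene_counts))
  if (length(miss)) plex_stop("plex_validation_error",
                              "unknown cells in subsets: %s", paste(utils::head(miss, 3), collapse = ", "))
  if (is.null(names(subsets)) || !all(nzchar(names(subsets))))
    names(subsets) <- sprintf("subset%03d", seq_along(subsets))
  ind <- Matrix::sparseMatrix(i = match(ids, colnames(gene_counts)),
                              j = rep(seq_along(subsets), lengths(subsets)),
                              x = 1, dims = c(ncol(gene_counts), length(subsets)))
  pb <- as.matrix(gene_counts %*% ind)
  dimnames(pb) <- list(rownames(gene_counts), names(subsets))
  pb
}

# Average log2 CPM with a prior count scaled per column in the standard way:
# prior_j = prior * lib_j / mean(lib); aveLog2CPM_g = mean_j log2(
#   (y_gj + prior_j) / (lib_j + 2 * prior_j) * 1e6 ).
ave_log2_cpm <- function(pb, prior_count = 2) {
  lib <- colSums(pb)
  pr <- prior_count * lib / mean(lib)
  rowMeans(log2(sweep(sweep(pb, 2, pr, "+"), 2, lib + 2 * pr, "/") * 1e6))
}

#' Remove lowly expressed genes
#'
#' Keeps genes whose average log2 CPM (prior count
#' `thresholds$cpm_prior_count`) over the compared subsets is at least
#' `thresholds$low_expr_avg_log2cpm`; strictly smaller values are removed.
#'
#' Genes observed in no subset at all are always removed (at shallow
#' pseudobulk depths the prior count alone can otherwise keep an all-zero
#' gene above the threshold).
#'
#' @param pb Genes x subsets pseudobulk matrix.
#' @param thresholds A [dge_thresholds()].
#' @return Filtered matrix with an `ave_log2cpm` attribute.
#' @export
filter_low_expression <- function(pb, thresholds = dge_thresholds()) {
  if (any(colSums(pb) == 0))
    plex_stop("plex_validation_error", "pseudobulk column with zero library size")
  ave <- ave_log2_cpm(pb, thresholds$cpm_prior_count)
  keep <- ave >= thresholds$low_expr_avg_log2cpm & rowSums(pb) > 0
  out <- pb[keep, , drop = FALSE]
  attr(out, "ave_log2cpm") <- ave[keep]
  plex_log("pseudodge", "low-expression filter: %d -> %d genes", nrow(pb), nrow(out))
  out
}

#' Trimmed mean of M-values scaling factors
#'
#' Reference column: the one whose 75th percentile of count/library is
#' closest to the mean such percentile. Per column, the factor is the
#' weighted mean (precision weights from the delta-method binomial variance)
#' of gene-wise log2 ratios M against the reference after trimming the top
#' and bottom 30% of M and 5% of A; factors are rescaled so their geometric
#' mean is 1.
#'
#' @param pb Genes x subsets pseudobulk matrix (>= 2 columns, no all-zero
#'   column).
#' @return Named positive numeric factors with geometric mean 1.
#' @export
tmm_factors <- function(pb) {
  if (ncol(pb) < 2) plex_stop("plex_validation_error", "need >= 2 columns")
  lib <- colSums(pb)
  if (any(lib == 0)) plex_stop("plex_validation_error", "column with all-zero counts")
  f75 <- apply(pb, 2, function(y) stats::quantile(y / sum(y), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  yr <- pb[, ref]; nr <- lib[ref]
  fac <- vapply(seq_len(ncol(pb)), function(j) {
    if (j == ref) return(1)
    yj <- pb[, j]; nj <- lib[j]
    ok <- yj > 0 & yr > 0
    if (!any(ok)) return(1)
    M <- log2((yj[ok] / nj) / (yr[ok] / nr))
    A <- 0.5 * log2((yj[ok] / nj) * (yr[ok] / nr))
    w <- 1 / ((nj - yj[ok]) / (nj * yj[ok]) + (nr - yr[ok]) / (nr * yr[ok]))
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    rM <- rank(M, ties.method = "first"); rA <- rank(A, ties.method = "first")
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep) || sum(w[keep]) == 0) return(1)
    2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }, 0)
  fac <- fac / exp(mean(log(fac)))
  stats::setNames(fac, colnames(pb))
}

# --- NB GLM internals -------------------------------------------------------

# Newton fit of a single intercept (log link) for a block of genes sharing
# offsets: maximises the NB log-likelihood in beta where mu = exp(beta + o_j).
# y: genes x n matrix, offs: length-n, phi: per-gene dispersion vector.
# Returns list(beta, mu).
nb_fit_intercept <- function(y, offs, phi) {
  N <- sum(exp(offs))
  tot <- rowSums(y)
  beta <- log(pmax(tot, 0.5) / N)
  for (it in 1:50) {
    mu <- exp(outer(beta, offs, "+"))
    denom <- 1 + sweep(mu, 1, phi, "*")
    score <- rowSums((y - mu) / denom)
    info <- rowSums(mu * (1 + sweep(y, 1, phi, "*")) / denom^2)
    step <- score / pmax(info, 1e-10)
    step <- pmax(pmin(step, 3), -3)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  mu <- exp(outer(beta, offs, "+"))
  list(beta = beta, mu = mu)
}

# NB log-likelihood (per gene, summed over samples), phi vector per gene.
nb_loglik <- function(y, mu, phi) {
  size <- 1 / phi
  ll <- matrix(0, nrow(y), ncol(y))
  for (j in seq_len(ncol(y)))
    ll[, j] <- stats::dnbinom(y[, j], size = size, mu = mu[, j], log = TRUE)
  rowSums(ll)
}

#' Negative binomial quasi-likelihood test (treatment vs control)
#'
#' Genewise NB generalized linear models with log(library x TMM factor)
#' offsets. Dispersions are estimated on a log-spaced grid by Cox-Reid
#' adjusted profile likelihood, with empirical-Bayes shrinkage of each gene
#' towards the abundance-binned trend; quasi-dispersions (residual deviance /
#' residual df) are moderated with [limma::squeezeVar()] and the treatment
#' effect is assessed with a quasi-likelihood F-statistic on 1 and
#' (residual + prior) df, followed by Benjamini-Hochberg adjustment.
#'
#' @param pb Genes x subsets pseudobulk matrix (already filtered).
#' @param group Factor with exactly two levels; the first level is the
#'   control/reference, the second the treatment.
#' @param factors Optional TMM factors (default [tmm_factors()]).
#' @param prior_n Weight of the trend in the dispersion shrinkage
#'   (default 10).
#' @param grid_length Number of dispersion grid points (default 25 over
#'   1e-4..10).
#' @return data.frame (gene, logCPM, log2fc, p, fdr) with `fdr >= p`.
#' @export
nbql_test <- function(pb, group, factors = NULL, prior_n = 10,
                      grid_length = 25) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2)
    plex_stop("plex_validation_error", "need exactly two groups")
  if (any(table(group) < 2))
    plex_stop("plex_validation_error", "each group needs >= 2 pseudobulk columns")
  if (ncol(pb) != length(group))
    plex_stop("plex_validation_error", "group labels do not match columns")
  factors <- factors %||% tmm_factors(pb)
  offs <- log(colSums(pb) * factors)
  y <- as.matrix(pb)
  G <- nrow(y); n <- ncol(y)
  ctl <- group == levels(group)[1]
  ave <- ave_log2_cpm(pb)

  # --- dispersion grid: Cox-Reid adjusted profile likelihood ---------------
  grid <- 10^seq(-4, 1, length.out = grid_length)
  apl <- matrix(0, G, grid_length)
  for (gidx in seq_along(grid)) {
    phi <- rep(grid[gidx], G)
    f1 <- nb_fit_intercept(y[, ctl, drop = FALSE], offs[ctl], phi)
    f2 <- nb_fit_intercept(y[, !ctl, drop = FALSE], offs[!ctl], phi)
    ll <- nb_loglik(y[, ctl, drop = FALSE], f1$mu, phi) +
      nb_loglik(y[, !ctl, drop = FALSE], f2$mu, phi)
    w1 <- rowSums(f1$mu / (1 + phi * f1$mu))
    w2 <- rowSums(f2$mu / (1 + phi * f2$mu))
    apl[, gidx] <- ll - 0.5 * (log(pmax(w1, 1e-300)) + log(pmax(w2, 1e-300)))
  }
  # abundance-binned trend of the APL, then per-gene EB shrinkage towards it
  nbins <- max(1, min(10, floor(G / 50)))
  bins <- if (nbins > 1) cut(rank(ave, ties.method = "first"), nbins, labels = FALSE)
  else rep(1, G)
  trend <- rowsum(apl, bins) / as.vector(table(bins))
  score <- apl + prior_n * trend[bins, , drop = FALSE]
  best <- max.col(score, ties.method = "first")
  # parabolic interpolation on log10(phi) around the grid maximum
  lphi <- log10(grid)
  phi_hat <- vapply(seq_len(G), function(g) {
    b <- best[g]
    if (b == 1 || b == grid_length) return(grid[b])
    s <- score[g, (b - 1):(b + 1)]
    den <- s[1] - 2 * s[2] + s[3]
    if (den >= 0) return(grid[b])
    10^(lphi[b] - 0.5 * (lphi[b + 1] - lphi[b]) * (s[3] - s[1]) / den)
  }, 0)

  # --- fits at the shrunk dispersions --------------------------------------
  f1 <- nb_fit_intercept(y[, ctl, drop = FALSE], offs[ctl], phi_hat)
  f2 <- nb_fit_intercept(y[, !ctl, drop = FALSE], offs[!ctl], phi_hat)
  f0 <- nb_fit_intercept(y, offs, phi_hat)
  dev_gene <- function(yy, mu, phi) {
    size <- 1 / phi
    t1 <- ifelse(yy > 0, yy * log(yy / pmax(mu, 1e-300)), 0)
    t2 <- (yy + size) * log((yy + size) / (mu + size))
    2 * rowSums(t1 - t2)
  }
  d_full <- dev_gene(y[, ctl, drop = FALSE], f1$mu, phi_hat) +
    dev_gene(y[, !ctl, drop = FALSE], f2$mu, phi_hat)
  d_red <- dev_gene(y, f0$mu, phi_hat)
  df_res <- n - 2
  s2 <- pmax(d_full / df_res, 1e-10)
  sq <- limma::squeezeVar(s2, df = df_res, covariate = ave)
  df_total <- df_res + sq$df.prior
  Fstat <- pmax(d_red - d_full, 0) / sq$var.post
  p <- stats::pf(Fstat, 1, df_total, lower.tail = FALSE)
  log2fc <- (f2$beta - f1$beta) / log(2)
  data.frame(gene = rownames(pb) %||% sprintf("g%d", seq_len(G)),
             logCPM = ave, log2fc = log2fc, p = p,
             fdr = stats::p.adjust(p, "BH"),
             dispersion = phi_hat, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Count differentially expressed protein-coding genes
#'
#' Strict thresholds: FDR < `deg_fdr` and log2FC > `deg_lfc` (up) or
#' < -`deg_lfc` (down), restricted to `protein_coding` biotype.
#'
#' @param dge A [nbql_test()] result.
#' @param annotation data.frame with `symbol` and `biotype` covering the
#'   tested genes.
#' @param thresholds A [dge_thresholds()].
#' @return c(n_up, n_down).
#' @export
count_degs <- function(dge, annotation, thresholds = dge_thresholds()) {
  bio <- annotation$biotype[match(toupper(dge$gene), toupper(annotation$symbol))]
  pc <- !is.na(bio) & bio == "protein_coding"
  sig <- pc & dge$fdr < thresholds$deg_fdr
  c(n_up = sum(sig & dge$log2fc > thresholds$deg_lfc),
    n_down = sum(sig & dge$log2fc < -thresholds$deg_lfc))
}

#' Union of regulated protein-coding genes across the drugs of one MOA
#'
#' @param dge_list List of [nbql_test()] results (one per drug of the MOA).
#' @param direction `"up"` or `"down"`.
#' @param annotation Gene annotation (`symbol`, `biotype`).
#' @param thresholds A [dge_thresholds()]; genes qualify with
#'   FDR < `deg_fdr` and log2FC strictly beyond `ora_lfc` in the stated
#'   direction.
#' @return Character vector (upper-cased symbols).
#' @export
moa_union_genes <- function(dge_list, direction = c("up", "down"), annotation,
                            thresholds = dge_thresholds()) {
  direction <- match.arg(direction)
  if (!length(dge_list)) plex_stop("plex_validation_error", "no DGE results given")
  sets <- lapply(dge_list, function(d) {
    bio <- annotation$biotype[match(toupper(d$gene), toupper(annotation$symbol))]
    pc <- !is.na(bio) & bio == "protein_coding"
    hit <- pc & d$fdr < thresholds$deg_fdr &
      (if (direction == "up") d$log2fc > thresholds$ora_lfc
       else d$log2fc < -thresholds$ora_lfc)
    toupper(d$gene[hit])
  })
  sort(unique(unlist(sets)))
}

#' ORA configuration
#' @param fdr_cutoff BH FDR cutoff for reported sets (default 0.05).
#' @param max_terms Maximum number of reported pathways (default 20).
#' @param allow_list Optional character vector of pathway names the report is
#'   intersected with (a custom cancer-pathway list, say).
#' @return list of class `ora_config`.
#' @export
ora_config <- function(fdr_cutoff = 0.05, max_terms = 20, allow_list = NULL) {
  if (fdr_cutoff <= 0 || fdr_cutoff >= 1)
    plex_stop("plex_config_error", "fdr_cutoff must be in (0, 1)")
  structure(list(fdr_cutoff = fdr_cutoff, max_terms = max_terms,
                 allow_list = allow_list), class = "ora_config")
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p-value of the overlap between the query and
#' each gene set (both intersected with the background), BH adjustment over
#' all tested sets, FDR filtering, optional allow-list intersection, capping
#' at the `max_terms` most significant pathways, and de-duplication of
#' repeated term names keeping the most significant instance.
#'
#' @param query Character vector of genes (subset of `background`).
#' @param collection A `gene_set_collection`.
#' @param background Character vector defining the gene universe.
#' @param config An [ora_config()].
#' @return data.frame (set, n_set, n_query, n_overlap, p, fdr), ordered by p.
#' @export
ora <- function(query, collection, background, config = ora_config()) {
  query <- unique(toupper(query)); background <- unique(toupper(background))
  if (!all(query %in% background))
    plex_stop("plex_validation_error", "query genes must be a subset of the background")
  empty <- data.frame(set = character(), n_set = integer(), n_query = integer(),
                      n_overlap = integer(), p = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(query)) return(empty)
  B <- length(background); q <- length(query)
  tab <- do.call(rbind, lapply(names(collection), function(nm) {
    s <- intersect(collection[[nm]], background)
    ov <- length(intersect(s, query))
    data.frame(set = nm, n_set = length(s), n_query = q, n_overlap = ov,
               p = stats::phyper(ov - 1, length(s), B - length(s), q,
                                 lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  tab <- tab[tab$n_set > 0, , drop = FALSE]
  if (!nrow(tab)) return(empty)
  tab$fdr <- stats::p.adjust(tab$p, "BH")
  tab <- tab[tab$fdr < config$fdr_cutoff, , drop = FALSE]
  if (!is.null(config$allow_list))
    tab <- tab[toupper(tab$set) %in% toupper(config$allow_list), , drop = FALSE]
  tab <- tab[order(tab$p), , drop = FALSE]
  tab <- tab[!duplicated(toupper(tab$set)), , drop = FALSE]
  utils::head(`rownames<-`(tab, NULL), config$max_terms)
}
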