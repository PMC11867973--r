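# Perturbation-signature corpus counting: filter experiments by MOA, tissue
# and timepoint, then count per-gene occurrences in the experiments' top-up
# and top-down gene sets, restricted to pathway signature genes (waterfall
# plot input: up counts positive, down counts negative).

#' Experiment filter
#' @param moas Allowed MOA labels (exact match after case-folding;
#'   default AKT/PI3K inhibitors).
#' @param tissues Allowed tissues (default ovary, breast).
#' @param timepoints Allowed timepoints in hours (default 24-120 h).
#' @return list of class `lincs_filter`.
#' @export
lincs_filter <- function(moas = c("AKT inhibitor", "PI3K inhibitor"),
                         tissues = c("ovary", "breast"),
                         timepoints = c(24, 48, 72, 96, 120)) {
  if (!length(moas) || !length(tissues) || !length(timepoints))
    plex_stop("plex_config_error", "filter sets must be non-empty")
  structure(list(moas = moas, tissues = tissues, timepoints = timepoints),
            class = "lincs_filter")
}

#' Filter perturbation experiments
#'
#' Keeps experiment ids satisfying all three criteria: MOA and tissue by
#' exact string match after case-folding, timepoint numerically.
#'
#' @param metadata data.frame with columns `experiment_id`, `moa`, `tissue`,
#'   `timepoint`.
#' @param filter A [lincs_filter()].
#' @return Character vector of experiment ids.
#' @export
filter_experiments <- function(metadata, filter = lincs_filter()) {
  need <- c("experiment_id", "moa", "tissue", "timepoint")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) plex_stop("plex_format_error",
                              "metadata missing columns: %s", paste(miss, collapse = ", "))
  keep <- tolower(metadata$moa) %in% tolower(filter$moas) &
    tolower(metadata$tissue) %in% tolower(filter$tissues) &
    as.numeric(metadata$timepoint) %in% filter$timepoints
  metadata$experiment_id[keep]
}

#' Per-gene occurrence counts in up/down signature sets
#'
#' For each signature gene, counts in how many filtered experiments it
#' occurs in the up set and in the down set (directions counted
#' independently); genes absent everywhere get 0/0. The output is in
#' waterfall order (decreasing `up_count - down_count`), with the plotted
#' signed values `up_count` and `-down_count`.
#'
#' @param experiment_ids Filtered experiment ids.
#' @param up_sets,down_sets `gene_set_collection`s keyed by experiment id.
#' @param signature_genes Gene universe of interest (e.g. RTK / PI3K-AKT
#'   pathway members).
#' @return data.frame (gene, up_count, down_count, signed_up, signed_down).
#' @export
occurrence_counts <- function(experiment_ids, up_sets, down_sets,
                              signature_genes) {
  miss_u <- setdiff(experiment_ids, names(up_sets))
  miss_d <- setdiff(experiment_ids, names(down_sets))
  if (length(miss_u) || length(miss_d))
    plex_stop("plex_validation_error",
              "experiments missing up/down sets: %s",
              paste(unique(c(miss_u, miss_d)), collapse = ", "))
  genes <- unique(toupper(signature_genes))
  up <- integer(length(genes)); down <- integer(length(genes))
  names(up) <- names(down) <- genes
  for (id in experiment_ids) {
    u <- intersect(up_sets[[id]], genes)
    d <- intersect(down_sets[[id]], genes)
    up[u] <- up[u] + 1L
    down[d] <- down[d] + 1L
  }
  out <- data.frame(gene = genes, up_count = up, down_count = down,
                    signed_up = up, signed_down = -down,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-(out$up_count - out$down_count), out$gene), , drop = FALSE]
}
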