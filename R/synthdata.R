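# Fully labelled synthetic inputs with the statistical structure the analysis
# assumes: negative binomial UMI counts with MOA-specific planted log-fold
#-change modules, dual-HTO signal/background structure with doublet and
# negative cells, mitochondrial content, 4PL dose-response truths, and a
# perturbation-signature corpus. Every generated cell carries a truth record
# so downstream stages can be scored against known labels.

#' Simulation configuration
#'
#' Defaults describe one 96-well hashed plate per model: ~130 cells per well,
#' 2,000 genes with log-normal baseline means, per-gene negative binomial
#' dispersion, 13 MOA effect modules of 40 genes planted at |log2FC| = 2 in
#' treated wells, hashtag (HTO) counts with strong on-target signal
#' (`hto_mu_signal`) over a weak background (`hto_mu_background`) plus a
#' constant ambient Poisson add-on, 5% doublets and 5% unlabelled (negative)
#' cells, and ~8% mitochondrial UMI content.
#'
#' @param n_models Number of models (= plates); models are named JHOS2, PDC2,
#'   PDC3 in order.
#' @param cells_per_well,cells_per_well_size Mean and NB size of the per-well
#'   cell count.
#' @param n_genes Number of genes simulated.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   per-gene mean counts.
#' @param libsize_sdlog Log-normal sd of per-cell library-size factors.
#' @param gene_nb_size NB size (inverse dispersion) shared across genes.
#' @param n_moas,module_size,module_lfc MOA effect modules: `n_moas` disjoint
#'   modules of `module_size` genes; in wells treated with a drug of that MOA
#'   the first half is planted at `+module_lfc` and the second half at
#'   `-module_lfc` log2 units.
#' @param hto_mu_signal,hto_mu_background,hto_size NB means of the assigned
#'   (signal) and unassigned (background) tag counts, and their shared size.
#' @param ambient_lambda Constant Poisson ambient contamination added to all
#'   tags (mimics variable surface-marker labelling).
#' @param doublet_rate,negative_rate Fractions of emitted cells that are
#'   merged two-cell doublets / unlabelled negatives.
#' @param mito_gene_fraction Fraction of genes flagged mitochondrial
#'   (`MT-` prefix).
#' @param mito_pct_mean Named per-model mean mitochondrial UMI percentage.
#' @param mito_cell_sdlog Log-normal spread of per-cell mitochondrial load.
#' @param seed Integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_models = 1,
                       cells_per_well = 130, cells_per_well_size = 20,
                       n_genes = 2000,
                       baseline_meanlog = 0.9, baseline_sdlog = 1.2,
                       libsize_sdlog = 0.35,
                       gene_nb_size = 2,
                       n_moas = 13, module_size = 40, module_lfc = 2,
                       hto_mu_signal = 200, hto_mu_background = 5,
                       hto_size = 10, ambient_lambda = 0.5,
                       doublet_rate = 0.05, negative_rate = 0.05,
                       mito_gene_fraction = 0.05,
                       mito_pct_mean = c(JHOS2 = 8, PDC2 = 9, PDC3 = 7),
                       mito_cell_sdlog = 0.5,
                       seed = 1) {
  cfg <- as.list(environment())
  rates <- c(doublet_rate, negative_rate)
  if (any(rates < 0 | rates > 1))
    plex_stop("plex_config_error", "rates must lie in [0, 1]")
  if (!(hto_mu_signal > hto_mu_background && hto_mu_background >= 0))
    plex_stop("plex_config_error", "need hto_mu_signal > hto_mu_background >= 0")
  n_mito <- round(mito_gene_fraction * n_genes)
  if (n_genes < n_mito + n_moas * module_size)
    plex_stop("plex_config_error",
              "n_genes too small for %d mito genes + %d MOA modules of %d genes",
              n_mito, n_moas, module_size)
  if (n_models < 1 || n_models > 3)
    plex_stop("plex_config_error", "n_models must be 1..3 (one plate per model)")
  cfg$model_names <- c("JHOS2", "PDC2", "PDC3")[seq_len(n_models)]
  class(cfg) <- "sim_config"
  cfg
}

# Gene identifiers: mitochondrial genes first (MT- prefix), then the rest.
sim_gene_ids <- function(config) {
  n_mito <- round(config$mito_gene_fraction * config$n_genes)
  c(sprintf("MT-G%04d", seq_len(n_mito)),
    sprintf("G%04d", seq_len(config$n_genes - n_mito) + n_mito))
}

# Planted effect modules: disjoint gene blocks directly after the mito genes.
sim_moa_modules <- function(config) {
  ids <- sim_gene_ids(config)
  n_mito <- round(config$mito_gene_fraction * config$n_genes)
  half <- config$module_size %/% 2
  do.call(rbind, lapply(seq_len(config$n_moas), function(k) {
    idx <- n_mito + (k - 1) * config$module_size + seq_len(config$module_size)
    data.frame(moa = sprintf("moa%02d", k), gene = ids[idx],
               log2fc = rep(c(config$module_lfc, -config$module_lfc),
                            c(half, config$module_size - half)),
               stringsAsFactors = FALSE)
  }))
}

#' Example 96-well plate layout
#'
#' The packaged design: 45 drugs from `n_moas` MOA classes plus DMSO control,
#' every treatment in duplicate (92 wells) and four extra DMSO wells to fill
#' the plate, addressed combinatorially by 8 row tags (R1..R8) and 12 column
#' tags (C1..C12).
#'
#' @param model Model (sample) name plated.
#' @param n_drugs Number of distinct drugs.
#' @param n_moas Number of MOA classes the drugs cycle through.
#' @param concentration,unit Placeholder treatment concentration.
#' @return A `plate_map` with 96 wells.
#' @export
make_plate_map <- function(model = "JHOS2", n_drugs = 45, n_moas = 13,
                           concentration = 1000, unit = "nM") {
  rows <- LETTERS[1:8]; cols <- sprintf("%02d", 1:12)
  wells <- as.vector(t(outer(rows, cols, paste0)))   # A01, A02, ..., H12
  drug <- c(rep(sprintf("drug%02d", seq_len(n_drugs)), each = 2),
            rep("DMSO", 96 - 2 * n_drugs))
  moa <- ifelse(drug == "DMSO", "control",
                sprintf("moa%02d", (match(drug, sprintf("drug%02d", seq_len(n_drugs))) - 1) %% n_moas + 1))
  replicate <- stats::ave(seq_along(drug), drug, FUN = seq_along)
  pm <- data.frame(well = wells,
                   row_tag = paste0("R", match(substr(wells, 1, 1), rows)),
                   col_tag = paste0("C", as.integer(substr(wells, 2, 3))),
                   model = model, drug = drug, moa = moa,
                   concentration = ifelse(drug == "DMSO", 0, concentration),
                   unit = unit, replicate = replicate,
                   is_control = drug == "DMSO", stringsAsFactors = FALSE)
  validate_plate_map(pm)
}

#' Generate a hashed multiplexed drug-screen experiment
#'
#' Simulates, for each model, one 96-well plate pooled into a single
#' single-cell run: UMI counts are NB(mean = baseline x library factor x
#' 2^planted-log2FC) with MOA modules active only in treated wells of the
#' matching MOA; HTO counts give each cell's assigned row and column tag a
#' strong NB signal over NB background on all other tags plus constant
#' ambient Poisson contamination; a fraction of cells are merged two-cell
#' doublets or background-only negatives. Every emitted cell has exactly one
#' truth record.
#'
#' @param config A [sim_config()].
#' @param include_genes If `FALSE`, skip the gene count matrix (tag counts and
#'   truth only), which is much cheaper when only demultiplexing is exercised.
#' @return A list of class `hashed_experiment` with elements `genes`
#'   (genes x cells sparse matrix or `NULL`), `tags` (20 x cells sparse
#'   matrix with a `families` attribute), `plate_maps` (one `plate_map` per
#'   model), `truth` (per-cell data.frame: barcode, model, well, drug, moa,
#'   is_control, class in singlet/doublet/negative), `gene_truth` (planted
#'   per-gene x MOA log2FC), and `mito_genes`.
#' @export
generate_hashed_experiment <- function(config = sim_config(), include_genes = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    gene_ids <- sim_gene_ids(config)
    n_mito <- round(config$mito_gene_fraction * config$n_genes)
    mito_genes <- gene_ids[seq_len(n_mito)]
    modules <- sim_moa_modules(config)
    base <- stats::rlnorm(config$n_genes, config$baseline_meanlog, config$baseline_sdlog)
    names(base) <- gene_ids
    tag_ids <- c(paste0("R", 1:8), paste0("C", 1:12))
    # per-MOA multiplicative effect vectors
    moa_mult <- lapply(split(modules, modules$moa), function(m) {
      v <- rep(1, config$n_genes); names(v) <- gene_ids
      v[m$gene] <- 2^m$log2fc
      v
    })

    plate_maps <- list(); genes_l <- list(); tags_l <- list(); truth_l <- list()
    for (mi in seq_len(config$n_models)) {
      model <- config$model_names[mi]
      pm <- make_plate_map(model = model, n_moas = config$n_moas)
      plate_maps[[model]] <- pm
      p_mito <- unname(config$mito_pct_mean[model] %||% 8)
      if (is.na(p_mito)) p_mito <- 8
      s_mito <- sum(base[mito_genes]); s_rest <- sum(base) - s_mito
      alpha <- (p_mito / (100 - p_mito)) * s_rest / s_mito
      mito_norm <- exp(config$mito_cell_sdlog^2 / 2)

      n_w <- pmax(1L, stats::rnbinom(nrow(pm), mu = config$cells_per_well,
                                     size = config$cells_per_well_size))
      N0 <- sum(n_w)
      col_ends <- cumsum(n_w)
      # dense plate-level matrices filled well by well; converted to sparse
      # once per plate (fast and memory-bounded at study scale)
      genes <- if (include_genes) matrix(0L, config$n_genes, N0) else NULL
      tags <- matrix(0L, 20L, N0)
      trw <- vector("list", nrow(pm))
      for (w in seq_len(nrow(pm))) {
        n <- n_w[w]
        cols <- (col_ends[w] - n + 1):col_ends[w]
        negative <- stats::runif(n) < config$negative_rate
        if (include_genes) {
          f <- stats::rlnorm(n, 0, config$libsize_sdlog)
          b <- stats::rlnorm(n, 0, config$mito_cell_sdlog) / mito_norm
          gmean <- if (!pm$is_control[w] && pm$moa[w] %in% names(moa_mult))
            base * moa_mult[[pm$moa[w]]] else base
          mu <- outer(gmean, f)
          mu[seq_len(n_mito), ] <- mu[seq_len(n_mito), ] * alpha *
            rep(b, each = n_mito)
          genes[, cols] <- stats::rnbinom(length(mu), mu = mu,
                                          size = config$gene_nb_size)
        }
        tg <- matrix(stats::rnbinom(20L * n, mu = config$hto_mu_background,
                                    size = config$hto_size), nrow = 20L)
        if (config$ambient_lambda > 0)
          tg <- tg + matrix(stats::rpois(20L * n, config$ambient_lambda), nrow = 20L)
        sig_rows <- c(match(pm$row_tag[w], tag_ids), match(pm$col_tag[w], tag_ids))
        keep <- which(!negative)
        if (length(keep)) {
          tg[sig_rows[1], keep] <- tg[sig_rows[1], keep] +
            stats::rnbinom(length(keep), mu = config$hto_mu_signal, size = config$hto_size)
          tg[sig_rows[2], keep] <- tg[sig_rows[2], keep] +
            stats::rnbinom(length(keep), mu = config$hto_mu_signal, size = config$hto_size)
        }
        tags[, cols] <- tg
        trw[[w]] <- data.frame(model = model, well = pm$well[w], drug = pm$drug[w],
                               moa = pm$moa[w], is_control = pm$is_control[w],
                               class = ifelse(negative, "negative", "singlet"),
                               stringsAsFactors = FALSE)
      }
      truth <- do.call(rbind, trw)
      # doublets: merge sampled pairs (usually across wells) into single cells
      N <- nrow(truth)
      d <- round(config$doublet_rate * N / (1 + config$doublet_rate))
      if (d > 0) {
        pair <- matrix(sample.int(N, 2 * d), nrow = 2)
        tags[, pair[1, ]] <- tags[, pair[1, ]] + tags[, pair[2, ]]
        if (include_genes)
          genes[, pair[1, ]] <- genes[, pair[1, ]] + genes[, pair[2, ]]
        truth$class[pair[1, ]] <- "doublet"
        truth$well[pair[1, ]] <- NA; truth$drug[pair[1, ]] <- NA
        truth$moa[pair[1, ]] <- NA
        keep <- setdiff(seq_len(N), pair[2, ])
        tags <- tags[, keep, drop = FALSE]
        if (include_genes) genes <- genes[, keep, drop = FALSE]
        truth <- truth[keep, , drop = FALSE]
      }
      bc <- sprintf("%s-C%06d", model, seq_len(nrow(truth)))
      truth <- cbind(data.frame(barcode = bc, stringsAsFactors = FALSE), truth)
      rownames(truth) <- NULL
      dimnames(tags) <- list(tag_ids, bc)
      tags_l[[mi]] <- methods::as(Matrix::Matrix(tags, sparse = TRUE), "CsparseMatrix")
      if (include_genes) {
        dimnames(genes) <- list(gene_ids, bc)
        genes_l[[mi]] <- methods::as(Matrix::Matrix(genes, sparse = TRUE),
                                     "CsparseMatrix")
        genes <- NULL
      }
      truth_l[[mi]] <- truth
    }

    tags <- do.call(cbind, tags_l)
    attr(tags, "families") <- list(row = paste0("R", 1:8), col = paste0("C", 1:12))
    out <- list(genes = if (include_genes) do.call(cbind, genes_l) else NULL,
                tags = tags,
                plate_maps = plate_maps,
                truth = do.call(rbind, truth_l),
                gene_truth = modules,
                mito_genes = mito_genes,
                config = config)
    class(out) <- "hashed_experiment"
    plex_log("synthdata", "generated %d cells over %d plate(s)",
             nrow(out$truth), config$n_models)
    out
  })
}

#' Random 4PL dose-response truths for a drug panel
#'
#' @param drugs Character vector of drug names.
#' @param concentrations The 5-point assay grid (used to centre EC50 draws).
#' @param seed RNG seed.
#' @return data.frame with columns drug, bottom, top, log10_ec50, hill.
#' @export
make_fourpl_truths <- function(drugs, concentrations = 10^seq(-1, 3), seed = 1) {
  with_seed(seed, {
    lx <- log10(range(concentrations))
    data.frame(drug = drugs,
               bottom = 0,
               top = stats::runif(length(drugs), 20, 95),
               log10_ec50 = stats::runif(length(drugs), lx[1] + 0.5, lx[2] - 0.5),
               hill = stats::runif(length(drugs), 0.7, 2),
               stringsAsFactors = FALSE)
  })
}

# 4PL in log10-concentration space; increasing in x for hill > 0.
fourpl_curve <- function(x, bottom, top, log10_ec50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10_ec50 - x)))
}

#' Generate a dose-response viability panel
#'
#' Five concentrations spanning a 10,000-fold (4 log10-unit) range per drug;
#' percent inhibition is the 4PL truth plus Gaussian noise, clipped to
#' `[-10, 110]`.
#'
#' @param fourpl_truths data.frame from [make_fourpl_truths()] (an optional
#'   `sample` column is carried through).
#' @param concentrations Increasing 5-point grid spanning exactly 4 log10
#'   units.
#' @param noise_sd Gaussian noise sd in percent-inhibition units.
#' @param seed RNG seed.
#' @return data.frame with columns sample, drug, concentration, response.
#' @export
generate_dose_response <- function(fourpl_truths, concentrations = 10^seq(-1, 3),
                                   noise_sd = 5, seed = 1) {
  if (is.unsorted(concentrations, strictly = TRUE))
    plex_stop("plex_config_error", "concentrations must be strictly increasing")
  if (length(concentrations) != 5 ||
      abs(log10(max(concentrations) / min(concentrations)) - 4) > 1e-8)
    plex_stop("plex_config_error",
              "need 5 concentrations spanning exactly a 10,000-fold range")
  if (is.null(fourpl_truths$sample)) fourpl_truths$sample <- "S1"
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(fourpl_truths)), function(i) {
      tr <- fourpl_truths[i, ]
      y <- fourpl_curve(log10(concentrations), tr$bottom, tr$top,
                        tr$log10_ec50, tr$hill)
      if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
      data.frame(sample = tr$sample, drug = tr$drug,
                 concentration = concentrations,
                 response = pmin(110, pmax(-10, y)), stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Generate a perturbation-signature corpus
#'
#' Emits a metadata table (experiment, MOA, tissue, timepoint) and, per
#' experiment, disjoint up and down gene sets of exactly `set_size` genes.
#' Planted genes are inserted into the up sets of experiments whose MOA is in
#' `planted_moas` with probability `planted_prob` (and never into down sets),
#' giving a known occurrence truth.
#'
#' @param n_experiments Number of experiments.
#' @param moas,tissues,timepoints Non-empty label pools sampled uniformly.
#' @param set_size Genes per up/down set.
#' @param gene_universe Symbols to draw from (default 3,000 synthetic ids).
#' @param planted_genes Genes planted into matching up sets.
#' @param planted_prob Per-experiment inclusion probability of each planted
#'   gene.
#' @param planted_moas MOAs whose experiments receive planted genes (default:
#'   all of `moas`).
#' @param seed RNG seed.
#' @return list(metadata, up, down); `up`/`down` are `gene_set_collection`s
#'   keyed by experiment id.
#' @export
generate_lincs_corpus <- function(n_experiments,
                                  moas = c("AKT inhibitor", "PI3K inhibitor"),
                                  tissues = c("ovary", "breast"),
                                  timepoints = c(24, 48, 72, 96, 120),
                                  set_size = 250,
                                  gene_universe = NULL,
                                  planted_genes = character(),
                                  planted_prob = 1,
                                  planted_moas = NULL,
                                  seed = 1) {
  if (!length(moas) || !length(tissues) || !length(timepoints))
    plex_stop("plex_config_error", "moas, tissues and timepoints must be non-empty")
  gene_universe <- toupper(gene_universe %||% sprintf("LG%05d", seq_len(3000)))
  gene_universe <- unique(c(gene_universe, toupper(planted_genes)))
  if (set_size * 2 > length(gene_universe))
    plex_stop("plex_config_error", "gene universe too small for disjoint up/down sets")
  planted_moas <- planted_moas %||% moas
  with_seed(seed, {
    ids <- sprintf("EXP%04d", seq_len(n_experiments))
    meta <- data.frame(experiment_id = ids,
                       moa = sample(moas, n_experiments, replace = TRUE),
                       tissue = sample(tissues, n_experiments, replace = TRUE),
                       timepoint = sample(timepoints, n_experiments, replace = TRUE),
                       stringsAsFactors = FALSE)
    up <- vector("list", n_experiments); down <- vector("list", n_experiments)
    pl <- toupper(planted_genes)
    for (i in seq_len(n_experiments)) {
      draw <- sample(setdiff(gene_universe, pl), 2 * set_size)
      u <- draw[seq_len(set_size)]; d <- draw[set_size + seq_len(set_size)]
      if (length(pl) && meta$moa[i] %in% planted_moas) {
        put <- pl[stats::runif(length(pl)) < planted_prob]
        if (length(put)) u[seq_along(put)] <- put
      }
      up[[i]] <- u; down[[i]] <- d
    }
    names(up) <- ids; names(down) <- ids
    list(metadata = meta,
         up = gene_set_collection(up),
         down = gene_set_collection(down))
  })
}
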