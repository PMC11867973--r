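# plexscreen

Analysis toolkit for **96-plex cell-hashing drug perturbation screens** read
out by single-cell RNA-Seq, as used for high-grade serous ovarian cancer
(HGSOC) cell lines and patient-derived cultures. Each well of a 96-well
plate is labelled with a unique pair of hashtag-oligo (HTO) antibody
conjugates — one of 8 row tags and one of 12 column tags, so 8 × 12 = 96
combinatorial addresses — then all wells are pooled into one scRNA-Seq run.
`plexscreen` takes it from there:

* **hashdemux** — dual-family HTO demultiplexing: centered log-ratio (CLR)
  transform per tag family, k-means background identification, per-tag
  negative binomial thresholds at the 0.99 quantile; cells that are singlets
  in *both* families map through the plate map to a well, drug, dose and
  mechanism of action (MOA).
* **cellqc** — UMI/mitochondrial QC (strict bounds 2,500–80,000 UMIs,
  per-model mito% maxima), log-normalization, SNN-graph Leiden clustering,
  one-vs-rest Wilcoxon markers with Bonferroni correction over all features.
* **pseudodge** — the screen's differential-expression engine: each
  (model, treatment) group is shuffled into subsamples of 10 cells (short
  remainders below 5 dropped, at least 2 subsets required — groups of ≤14
  cells are excluded), summed into pseudobulk, filtered at average
  log2 CPM < 1, TMM-normalized and tested per gene with a negative binomial
  quasi-likelihood F-test (BH-adjusted). DEG counting
  (|log2FC| > 0.5, FDR < 0.01, protein-coding), per-MOA gene unions
  (|log2FC| > 0.25) and capped, de-duplicated hypergeometric
  over-representation analysis sit on top.
* **sigscore** — marker-panel signature activity scores (top 50 up/down
  markers per cluster), 1,000-draw bootstrap significance, top-5%
  coefficient-of-variation selection.
* **drugresp** — 4PL dose-response fits over five concentrations spanning a
  10,000-fold range; drug sensitivity scores (DSS) as the normalized area
  above a 10% activity threshold,
  `DSS = 100 ∫ max(0, min(y,100) − t) dx / ((100 − t)(x_max − x_min))`;
  percentile cutoffs; exact two-sided Wilcoxon rank-sum comparison of group
  mean DSS (full enumeration up to n = 25, ties handled exactly).
* **lincscount** — perturbation-signature corpus filtering (MOA, tissue,
  timepoint) and per-gene up/down occurrence counting over top-250 gene
  sets, in waterfall order.
* **synthdata** — a fully labelled generator (NB gene counts with planted
  per-MOA log2FC modules, dual-HTO signal/background structure with
  doublets and negatives, mitochondrial content, 4PL truths, a
  perturbation corpus with planted genes) so every stage is testable
  without any sequencing data.

`plexio` supplies the on-disk formats: 10x-style MatrixMarket count
triplets, plate-map CSV (an example ships in
`inst/extdata/example_plate_map.csv`), GMT gene sets, annotation TSV.

## Worked example

One synthetic plate, demultiplexed and pushed through the pseudobulk DGE
and drug-sensitivity stages:

```r
library(plexscreen)

cfg <- sim_config(cells_per_well = 60, n_genes = 1000, module_size = 20, seed = 1)
ex  <- generate_hashed_experiment(cfg)
fam <- attr(ex$tags, "families")
row_call <- classify_family(ex$tags, fam$row, demux_config(seed = 1))
col_call <- classify_family(ex$tags, fam$col, demux_config(seed = 1))
dmx <- demultiplex(row_call, col_call, ex$plate_maps$JHOS2)
#> retained 4515 of 5374 cells (84.0%)

kept <- dmx$assignments[dmx$assignments$status == "retained", ]
qc   <- qc_filter(ex$genes[, kept$barcode], ex$mito_genes, qc_thresholds(), "JHOS2")
#> QC kept 4451 of 4515 cells

cells_of <- function(drug) intersect(kept$barcode[kept$drug == drug],
                                     colnames(qc$counts))
cfgp <- subsample_config(seed = 1)
st <- partition_group(cells_of("drug01"), cfgp, c("JHOS2", "drug01"))$subsets
sc <- partition_group(cells_of("DMSO"),  cfgp, c("JHOS2", "DMSO"))$subsets
names(st) <- paste0("trt", seq_along(st)); names(sc) <- paste0("ctl", seq_along(sc))
pb  <- cbind(aggregate_pseudobulk(qc$counts, sc), aggregate_pseudobulk(qc$counts, st))
grp <- factor(rep(c("control", "treatment"), c(length(sc), length(st))),
              levels = c("control", "treatment"))
dge <- nbql_test(filter_low_expression(pb), grp)
#> 29 subsets vs 10 subsets, 1000 genes tested, 20 at FDR<0.01
head(dge[order(dge$p), c("gene", "log2fc", "p", "fdr")], 5)
#>     gene    log2fc            p          fdr
#> 56 G0056  1.991842 3.487497e-64 3.487497e-61
#> 55 G0055  1.954696 7.698253e-59 3.849127e-56
#> 52 G0052  2.326039 7.183834e-49 2.394611e-46
#> 59 G0059  1.850322 2.728144e-48 6.820361e-46
#> 61 G0061 -2.156226 2.036342e-46 4.072684e-44
```

The 20 genes at FDR < 0.01 are precisely drug01's planted ±2 log2FC module;
the median estimate over the up-half is 1.97 against a truth of 2. Drug
sensitivity from a 5-drug dose-response panel:

```r
tr    <- make_fourpl_truths(sprintf("drug%02d", 1:5), seed = 1)
panel <- generate_dose_response(tr, noise_sd = 3, seed = 1)
m     <- dss_matrix(panel)
round(m[, 1], 1)
#> drug01 drug02 drug03 drug04 drug05
#>    6.3    5.2   18.1   33.6   20.5
dss_cutoff(m, 75)                 # screen-wide sensitivity cutoff
#> [1] 20.49
exact_wilcoxon(c(25, 28, 31), c(5, 8, 9, 11, 12))$p   # 3 vs 5, separated
#> [1] 0.03571429  (0.036 at three decimals)
```

A DSS above the recomputed 75th-percentile cutoff flags a drug as an active
hit for that sample; the exact rank-sum p-value is the statistic used to
compare mean DSS between marker-defined sample groups (e.g. CAV1-high vs
CAV1-low).

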