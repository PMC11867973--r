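# Readers/writers for the on-disk formats used throughout the pipeline:
# 10x-style MatrixMarket count triplets, plate-map CSVs, GMT gene-set files
# and gene annotation TSVs. All gene symbols are matched case-insensitively
# (upper-cased internally) because gene sets and annotations routinely come
# from mixed sources.

#' Read a 10x-style sparse count matrix
#'
#' Reads a MatrixMarket coordinate triplet file together with its companion
#' feature and barcode lists (the 10x triplet convention: `matrix.mtx`,
#' `features.tsv`, `barcodes.tsv`). Counts must be non-negative integers and
#' indices must lie within the header dimensions.
#'
#' @param matrix_path Path to the MatrixMarket `.mtx` file (1-based indices).
#' @param features_path Path to a one-column (or first-column-used) TSV of
#'   feature identifiers, one per matrix row.
#' @param barcodes_path Path to a TSV of cell barcodes, one per matrix column.
#' @return A [Matrix::dgCMatrix-class] with features as rows (named) and
#'   barcodes as columns (named).
#' @examples
#' d <- tempfile(); dir.create(d)
#' m <- Matrix::sparseMatrix(i = 1, j = 1, x = 7, dims = c(1, 1),
#'                           dimnames = list("G1", "CELL1"))
#' paths <- write_counts_mtx(m, d)
#' read_counts_mtx(paths$matrix, paths$features, paths$barcodes)
#' @export
read_counts_mtx <- function(matrix_path, features_path, barcodes_path) {
  for (p in c(matrix_path, features_path, barcodes_path)) {
    if (!file.exists(p)) plex_stop("plex_io_error", "file not found: %s", p)
  }
  m <- tryCatch(Matrix::readMM(matrix_path), error = function(e) {
    plex_stop("plex_format_error", "malformed MatrixMarket file '%s': %s",
              matrix_path, conditionMessage(e))
  })
  m <- methods::as(m, "CsparseMatrix")
  x <- m@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    plex_stop("plex_format_error",
              "count matrix '%s' has negative or non-integer entries", matrix_path)
  }
  features <- utils::read.delim(features_path, header = FALSE,
                                stringsAsFactors = FALSE)[, 1]
  barcodes <- utils::read.delim(barcodes_path, header = FALSE,
                                stringsAsFactors = FALSE)[, 1]
  if (length(features) != nrow(m) || length(barcodes) != ncol(m)) {
    plex_stop("plex_format_error",
              "dimension mismatch: matrix is %d x %d but %d features / %d barcodes given",
              nrow(m), ncol(m), length(features), length(barcodes))
  }
  if (anyDuplicated(features)) plex_stop("plex_format_error", "feature ids are not unique")
  if (anyDuplicated(barcodes)) plex_stop("plex_format_error", "barcode ids are not unique")
  dimnames(m) <- list(features, barcodes)
  validate_counts(m)
  plex_log("plexio", "read counts: %d features x %d cells, %d nonzeros",
           nrow(m), ncol(m), length(m@x))
  m
}

#' Write a sparse count matrix as MatrixMarket triplets
#'
#' Emits the 10x triplet convention (`matrix.mtx`, `features.tsv`,
#' `barcodes.tsv`) with an integer MatrixMarket header and 1-based indices,
#' so that [read_counts_mtx()] inverts it exactly.
#'
#' @param counts A sparse (or dense) matrix of non-negative integer counts
#'   with feature rownames and barcode colnames.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with elements `matrix`, `features`, `barcodes`
#'   holding the written paths.
#' @export
write_counts_mtx <- function(counts, out_dir) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  validate_counts(counts)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) plex_stop("plex_io_error", "cannot create '%s'", out_dir)
  }
  paths <- list(matrix = file.path(out_dir, "matrix.mtx"),
                features = file.path(out_dir, "features.tsv"),
                barcodes = file.path(out_dir, "barcodes.tsv"))
  tr <- Matrix::summary(counts)
  header <- c("%%MatrixMarket matrix coordinate integer general",
              sprintf("%d %d %d", nrow(counts), ncol(counts), nrow(tr)))
  body <- if (nrow(tr)) sprintf("%d %d %d", tr$i, tr$j, as.integer(tr$x)) else character()
  con <- tryCatch(file(paths$matrix, "w"), error = function(e)
    plex_stop("plex_io_error", "cannot write '%s'", paths$matrix))
  writeLines(c(header, body), con)
  close(con)
  writeLines(rownames(counts), paths$features)
  writeLines(colnames(counts), paths$barcodes)
  plex_log("plexio", "wrote counts: %d features x %d cells to %s",
           nrow(counts), ncol(counts), out_dir)
  invisible(paths)
}

# Shared invariants for count matrices (tags x cells or genes x cells).
validate_counts <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    plex_stop("plex_format_error", "count matrix must have feature and barcode names")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    plex_stop("plex_format_error", "feature/barcode ids must be unique")
  x <- if (methods::is(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(x) && (any(!is.finite(x)) || any(x < 0) || any(x != round(x))))
    plex_stop("plex_format_error", "counts must be finite non-negative integers")
  invisible(m)
}

#' Read a plate map CSV
#'
#' The plate map is the single source of the well-to-treatment mapping: one
#' row per well with its row-family and column-family hashtag, the model
#' (sample) plated in it, the drug, its mechanism-of-action (MOA) class,
#' concentration, replicate index and a control flag. Row tags are drawn from
#' a family of at most 8, column tags from a family of at most 12 (the 8 x 12
#' combinatorial layout of a 96-well plate), and every (row tag, column tag)
#' pair must be unique.
#'
#' @param csv_path Path to a CSV with header
#'   `well,row_tag,col_tag,model,drug,moa,concentration,unit,replicate,is_control`.
#' @return A `data.frame` of class `plate_map`.
#' @seealso [make_plate_map()] for generating the packaged example layout.
#' @export
read_plate_map <- function(csv_path) {
  if (!file.exists(csv_path)) plex_stop("plex_io_error", "file not found: %s", csv_path)
  pm <- tryCatch(utils::read.csv(csv_path, stringsAsFactors = FALSE),
                 error = function(e) plex_stop("plex_validation_error",
                                               "unreadable plate map: %s", conditionMessage(e)))
  validate_plate_map(pm)
}

#' Write a plate map CSV
#' @param plate_map A `plate_map` data.frame.
#' @param csv_path Output path.
#' @return Invisibly, `csv_path`.
#' @export
write_plate_map <- function(plate_map, csv_path) {
  utils::write.csv(as.data.frame(plate_map)[, plate_map_columns()],
                   csv_path, row.names = FALSE, quote = FALSE)
  invisible(csv_path)
}

plate_map_columns <- function() {
  c("well", "row_tag", "col_tag", "model", "drug", "moa",
    "concentration", "unit", "replicate", "is_control")
}

#' Validate a plate map
#' @param pm A data.frame with the plate-map columns.
#' @return The validated `plate_map`.
#' @export
validate_plate_map <- function(pm) {
  need <- plate_map_columns()
  if (nrow(pm) == 0) plex_stop("plex_validation_error", "plate map is empty")
  miss <- setdiff(need, names(pm))
  if (length(miss)) plex_stop("plex_validation_error",
                              "plate map missing columns: %s", paste(miss, collapse = ", "))
  pm$is_control <- as.logical(pm$is_control)
  if (anyNA(pm$is_control)) plex_stop("plex_validation_error", "is_control must be logical")
  pair <- paste(pm$row_tag, pm$col_tag, sep = "\r")
  if (anyDuplicated(pair))
    plex_stop("plex_validation_error", "duplicate (row_tag, col_tag) pair: %s",
              sub("\r", "/", pair[duplicated(pair)][1]))
  if (anyDuplicated(pm$well))
    plex_stop("plex_validation_error", "duplicate well id")
  if (length(unique(pm$row_tag)) > 8)
    plex_stop("plex_validation_error", "more than 8 distinct row tags")
  if (length(unique(pm$col_tag)) > 12)
    plex_stop("plex_validation_error", "more than 12 distinct column tags")
  ctrl <- tapply(pm$is_control, pm$model, any)
  if (!all(ctrl)) plex_stop("plex_validation_error",
                            "model without a control well: %s",
                            paste(names(ctrl)[!ctrl], collapse = ", "))
  class(pm) <- c("plate_map", "data.frame")
  pm
}

#' Read a GMT gene-set collection
#'
#' Tab-separated GMT: each line is `name<TAB>description<TAB>gene1<TAB>...`.
#' Genes are upper-cased and de-duplicated within a set; set names must be
#' unique.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors of class `gene_set_collection`,
#'   with a `description` attribute parallel to the sets.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) plex_stop("plex_io_error", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) plex_stop("plex_format_error",
                             "GMT line %d has fewer than 3 fields", bad[1])
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) plex_stop("plex_format_error",
                                   "duplicate gene-set name: %s", nm[duplicated(nm)][1])
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  if (any(vapply(sets, function(s) any(!nzchar(s)), TRUE)))
    plex_stop("plex_format_error", "empty gene symbol in GMT")
  names(sets) <- nm
  gene_set_collection(sets, vapply(fields, `[[`, "", 2L))
}

#' Construct a gene-set collection
#' @param sets Named list of character gene vectors.
#' @param description Optional character vector of per-set descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    plex_stop("plex_validation_error", "set names must be present and unique")
  sets <- lapply(sets, function(s) unique(toupper(as.character(s))))
  attr(sets, "description") <- description %||% rep("", length(sets))
  class(sets) <- "gene_set_collection"
  sets
}

#' Write a gene-set collection to GMT
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "description") %||% rep("", length(collection))
  desc[!nzchar(desc)] <- "na"
  writeLines(vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], desc[i], collection[[i]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Read a gene annotation TSV
#'
#' Two mandatory columns, `symbol` and `biotype` (e.g. `protein_coding`);
#' an optional `chromosome` column is carried through. Symbols are upper-cased
#' and must be unique after case-folding.
#'
#' @param path Path to the TSV (with header).
#' @return A `data.frame` with upper-cased unique `symbol`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) plex_stop("plex_io_error", "file not found: %s", path)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("symbol", "biotype") %in% names(ann)))
    plex_stop("plex_format_error", "annotation needs 'symbol' and 'biotype' columns")
  ann$symbol <- toupper(ann$symbol)
  if (anyDuplicated(ann$symbol))
    plex_stop("plex_format_error", "gene symbols not unique after upper-casing")
  ann
}
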