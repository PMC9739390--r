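#' Construct an ExpressionDataset
#'
#' Bundles a genes x samples matrix of log-scale expression (typically
#' log2(UPM + 1), UPM = UMI per million) with per-sample metadata describing
#' the differentiation design: cell line, replicate differentiation, and day.
#' Columns are reordered to the canonical (line, replicate, day) sort so that
#' downstream code can rely on a deterministic sample order.
#'
#' @param values numeric matrix, rows = gene symbols, columns = sample IDs.
#' @param samples data.frame with columns `sample_id`, `line_id`,
#'   `replicate_id`, `day` (integer; day -1 is a valid label).
#' @return An object of class `ExpressionDataset` with elements `values`
#'   (matrix, columns in canonical order) and `samples` (data.frame aligned
#'   to the columns).
#' @export
expression_dataset <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  required <- c("sample_id", "line_id", "replicate_id", "day")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  samples <- as.data.frame(samples)[, required]
  samples$sample_id <- as.character(samples$sample_id)
  samples$line_id <- as.character(samples$line_id)
  samples$replicate_id <- as.character(samples$replicate_id)
  samples$day <- as.integer(samples$day)

  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in metadata: ",
         samples$sample_id[duplicated(samples$sample_id)][1L])
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene symbols as rownames and sample IDs as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbol: ",
         rownames(values)[duplicated(rownames(values))][1L])
  unmatched <- setdiff(colnames(values), samples$sample_id)
  if (length(unmatched))
    stop("no metadata for sample column(s): ", paste(unmatched, collapse = ", "))
  unmatched <- setdiff(samples$sample_id, colnames(values))
  if (length(unmatched))
    stop("metadata row(s) without matrix column: ",
         paste(unmatched, collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must be finite; first offending gene: ",
         rownames(values)[which(!apply(is.finite(values), 1L, all))[1L]])

  ord <- order(samples$line_id, samples$replicate_id, samples$day)
  samples <- samples[ord, , drop = FALSE]
  rownames(samples) <- NULL
  values <- values[, samples$sample_id, drop = FALSE]

  .check_daily_grid(samples)

  structure(list(values = values, samples = samples),
            class = "ExpressionDataset")
}

## days must form a contiguous daily grid within every (line, replicate) series
.check_daily_grid <- function(samples) {
  key <- paste(samples$line_id, samples$replicate_id, sep = "/")
  for (k in unique(key)) {
    d <- sort(samples$day[key == k])
    if (anyDuplicated(d))
      stop("series ", k, " has duplicated day ", d[duplicated(d)][1L])
    if (length(d) > 1L && any(diff(d) != 1L)) {
      gap <- d[which(diff(d) != 1L)[1L]] + 1L
      stop("series ", k, " is missing day ", gap, " (days must be daily)")
    }
  }
  invisible(TRUE)
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", nrow(x$values), "genes x",
      ncol(x$values), "samples\n")
  cat("  lines:", paste(unique(x$samples$line_id), collapse = ", "), "\n")
  cat("  days:", min(x$samples$day), "..", max(x$samples$day), "\n")
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

#' Sorted day grid of a dataset
#' @param dataset an `ExpressionDataset`.
#' @return integer vector of unique days, ascending.
#' @export
day_grid <- function(dataset) sort(unique(dataset$samples$day))

#' Read an expression matrix and its sample metadata
#'
#' The matrix is a tab-delimited file whose header row holds sample IDs and
#' whose first column holds gene symbols; the metadata file is a TSV with
#' columns `sample_id`, `line_id`, `replicate_id`, `day`.
#'
#' @param matrix_path path to the tab-delimited genes x samples matrix.
#' @param metadata_path path to the sample metadata TSV.
#' @return An `ExpressionDataset`.
#' @export
read_expression <- function(matrix_path, metadata_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  genes <- as.character(tab[[1L]])
  vals <- tab[, -1L, drop = FALSE]
  not_num <- !vapply(vals, is.numeric, logical(1L))
  if (any(not_num)) {
    col <- names(vals)[not_num][1L]
    bad <- vals[[col]][is.na(suppressWarnings(as.numeric(vals[[col]])))][1L]
    stop("non-numeric expression value in column ", col, ": ", bad)
  }
  values <- as.matrix(vals)
  rownames(values) <- genes
  samples <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  expression_dataset(values, samples)
}

#' Write an expression dataset to matrix + metadata TSV files
#'
#' @param dataset an `ExpressionDataset`.
#' @param matrix_path,metadata_path output paths.
#' @return Invisibly, the dataset.
#' @export
write_expression <- function(dataset, matrix_path, metadata_path) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  tab <- data.frame(gene = rownames(dataset$values),
                    dataset$values, check.names = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$samples, metadata_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dataset)
}

#' Read a gene list (one symbol per line, `#` comments allowed)
#'
#' @param path file path.
#' @return character vector of gene symbols, duplicates removed, input
#'   order preserved.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}
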