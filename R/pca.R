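#' Principal-component summary of global transcriptomic progression
#'
#' PCA of the gene-wise mean-centered log-expression matrix over samples.
#' PC1 is sign-oriented so that its Spearman correlation with day is
#' non-negative, making progression fractions well-defined.
#'
#' @param dataset an `ExpressionDataset`.
#' @param n_components number of components to keep (default all).
#' @return Object of class `PcaSummary`: `coords` (samples x components
#'   score matrix), `explained` (variance fractions, non-increasing),
#'   `pc1_day_rho` (Spearman correlation of PC1 with day over all
#'   samples), `days` and `sample_ids`.
#' @export
pca_summary <- function(dataset, n_components = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  x <- dataset$values
  if (ncol(x) < 2L) stop("need at least 2 samples")
  centered <- x - rowMeans(x)
  if (all(abs(centered) < 1e-12))
    stop("constant expression matrix: principal components are undefined")
  ## prcomp over samples; gene-wise centering already done
  pc <- stats::prcomp(t(centered), center = FALSE, scale. = FALSE)
  k <- if (is.null(n_components)) ncol(pc$x) else min(n_components, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  days <- dataset$samples$day
  rho <- suppressWarnings(stats::cor(coords[, 1L], days, method = "spearman"))
  if (is.na(rho)) rho <- 0
  if (rho < 0) {
    coords[, 1L] <- -coords[, 1L]
    rho <- -rho
  }
  structure(list(coords = coords, explained = explained[seq_len(k)],
                 pc1_day_rho = rho, days = days,
                 sample_ids = dataset$samples$sample_id),
            class = "PcaSummary")
}

#' @export
print.PcaSummary <- function(x, ...) {
  cat("PcaSummary:", nrow(x$coords), "samples;",
      "PC1", sprintf("%.1f%%", 100 * x$explained[1L]), "variance;",
      "Spearman rho(PC1, day) =", sprintf("%.3f", x$pc1_day_rho), "\n")
  invisible(x)
}

#' Fraction of PC1 progression reached by a given day
#'
#' Computed from per-day medians of the PC1 score:
#' `(median PC1 at day - median at first day) /
#'  (median at last day - median at first day)`.
#'
#' @param summary a `PcaSummary`.
#' @param day a day on the grid.
#' @return numeric fraction (0 at the first day, 1 at the last).
#' @export
pc1_progress <- function(summary, day) {
  stopifnot(inherits(summary, "PcaSummary"))
  grid <- sort(unique(summary$days))
  if (!day %in% grid) stop("day ", day, " is not on the sampled grid")
  med <- function(d) stats::median(summary$coords[summary$days == d, 1L])
  m0 <- med(grid[1L]); m1 <- med(grid[length(grid)])
  if (abs(m1 - m0) < 1e-12)
    stop("PC1 medians at the endpoints coincide; progression undefined")
  (med(day) - m0) / (m1 - m0)
}
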