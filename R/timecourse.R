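#' Arrange a dataset as a gene x timepoint x replicate-series tensor
#'
#' Each (line, replicate) pair is one replicate series; every series must
#' cover the same daily grid.  In the reference study design 3 lines x 3
#' replicate differentiations give 9 series of 32 days.
#'
#' @param dataset an `ExpressionDataset`.
#' @return 3-d array `[gene, timepoint, series]` with dimnames; the series
#'   axis is named `line/replicate`.
#' @export
build_replicate_tensor <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  s <- dataset$samples
  days <- day_grid(dataset)
  key <- paste(s$line_id, s$replicate_id, sep = "/")
  series <- unique(key)
  for (k in series) {
    have <- s$day[key == k]
    miss <- setdiff(days, have)
    if (length(miss))
      stop("series ", k, " is missing day ", miss[1L])
  }
  tens <- array(NA_real_,
                dim = c(nrow(dataset$values), length(days), length(series)),
                dimnames = list(rownames(dataset$values),
                                as.character(days), series))
  for (si in seq_along(series)) {
    sel <- key == series[si]
    sub <- s[sel, , drop = FALSE]
    cols <- sub$sample_id[order(sub$day)]
    tens[, , si] <- dataset$values[, cols]
  }
  tens
}

## Moore-Penrose pseudo-inverse of a symmetric PSD matrix via eigen
.sym_pinv <- function(m, tol = 1e-10) {
  e <- eigen(m, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values), 1e-300)
  if (!any(pos)) return(matrix(0, nrow(m), ncol(m)))
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

#' Moderated multivariate Hotelling time-course statistic
#'
#' Ranks genes by evidence of temporal change across replicate series.
#' Each series profile is transformed by a contrast — consecutive
#' differences by default, so a constant profile maps exactly to the null
#' vector — giving per-series vectors \eqn{Y_r}.  With \eqn{\bar y} the
#' mean over the \eqn{n} series and \eqn{S} their sample covariance, the
#' per-gene covariance is shrunk toward the gene-ensemble average
#' \eqn{\hat\Lambda = \mathrm{mean}_g S_g}:
#' \deqn{\tilde S = ((n-1) S + \nu \hat\Lambda) / (n - 1 + \nu),\qquad
#'       \tilde T^2 = n\, \bar y^\top \tilde S^{-} \bar y,}
#' using a pseudo-inverse when \eqn{\tilde S} is rank-deficient (with the
#' study design the contrast dimension 31 exceeds n - 1 = 8, so shrinkage
#' plus pseudo-inverse is the normal path).  At \eqn{\nu = 0} on a
#' full-rank problem this is the classical one-sample Hotelling T².
#'
#' @param tensor array `[gene, timepoint, series]` from
#'   [build_replicate_tensor()].
#' @param nu prior degrees of freedom for the shrinkage (default `T - 1`,
#'   the contrast dimension).
#' @param contrast `"diff"` (consecutive differences, default) or
#'   `"center"` (mean-centered profile).
#' @return data.frame with columns `gene`, `t2_tilde`, `rank`, ordered by
#'   rank (ties in the statistic broken lexicographically by symbol).
#' @export
mb_statistic <- function(tensor, nu = NULL, contrast = c("diff", "center")) {
  contrast <- match.arg(contrast)
  stopifnot(length(dim(tensor)) == 3L)
  n_genes <- dim(tensor)[1L]
  tT <- dim(tensor)[2L]
  n <- dim(tensor)[3L]
  if (n < 2L) stop("need at least 2 replicate series")
  p <- if (contrast == "diff") tT - 1L else tT
  if (is.null(nu)) nu <- p
  stopifnot(nu >= 0)
  if (nu == 0 && (n - 1L) < p)
    warning("nu = 0 with n - 1 < contrast dimension: S is rank-deficient, ",
            "pseudo-inverse used")

  ## contrast-transformed data, per gene: p x n matrices
  ybar <- matrix(NA_real_, n_genes, p)
  Ss <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    prof <- matrix(tensor[g, , ], tT, n)
    Y <- if (contrast == "diff") diff(prof) else
      sweep(prof, 2L, colMeans(prof))
    yb <- rowMeans(Y)
    ybar[g, ] <- yb
    D <- Y - yb
    Ss[[g]] <- tcrossprod(D) / (n - 1L)
  }
  Lambda <- Reduce(`+`, Ss) / n_genes

  t2 <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    St <- ((n - 1L) * Ss[[g]] + nu * Lambda) / (n - 1L + nu)
    yb <- ybar[g, ]
    ## fast path: solve; fall back to pseudo-inverse if singular
    q <- tryCatch(solve(St, yb), error = function(e) NULL)
    if (is.null(q) || !all(is.finite(q))) q <- .sym_pinv(St) %*% yb
    t2[g] <- n * sum(yb * q)
  }
  genes <- dimnames(tensor)[[1L]]
  if (is.null(genes)) genes <- as.character(seq_len(n_genes))
  ord <- order(-t2, genes)
  out <- data.frame(gene = genes[ord], t2_tilde = t2[ord],
                    rank = seq_len(n_genes), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select the top-N time-varying genes
#'
#' @param stats data.frame from [mb_statistic()].
#' @param n number of genes to keep (default 3000).
#' @return character vector of gene symbols, best rank first.
#' @export
select_top_deg <- function(stats, n = 3000) {
  stopifnot(n >= 1, all(c("gene", "rank") %in% names(stats)))
  stats <- stats[order(stats$rank), , drop = FALSE]
  utils::head(stats$gene, n)
}
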