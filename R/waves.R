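## chronological letters: A..Z then AA, AB, ...
.chrono_letters <- function(k) {
  if (k <= 26L) return(LETTERS[seq_len(k)])
  c(LETTERS, as.vector(t(outer(LETTERS, LETTERS, paste0))))[seq_len(k)]
}

## k-means++ seeding (Arthur & Vassilvitskii); rows of x are points
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1L], ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1L) + 1L) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i] <- sample.int(n, 1L, prob = prob)
    nd <- rowSums((x - matrix(x[centers[i], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

#' Day at which a time profile changes the most
#'
#' Returns the later day of the consecutive pair (t-1, t) maximizing the
#' absolute difference |m(t) - m(t-1)|; ties go to the earliest such day,
#' so a constant profile returns the first day after the grid start.
#'
#' @param profile numeric time series.
#' @param days day labels (same length); default 0-based positions.
#' @return the day of maximal change.
#' @export
change_time <- function(profile, days = seq_along(profile) - 1L) {
  stopifnot(length(profile) >= 2L, length(days) == length(profile))
  d <- abs(diff(profile))
  days[which.max(d) + 1L]
}

## first day at which a profile reaches half of its total range
.half_range_time <- function(profile, days) {
  rng <- range(profile)
  if (diff(rng) < 1e-12) return(days[1L])
  days[which(profile >= rng[1L] + diff(rng) / 2)[1L]]
}

#' Assign chronological letters to clusters
#'
#' Clusters are sorted ascending by change-time of their mean profile;
#' ties are broken by the earlier time at which the mean profile first
#' reaches half of its total range, remaining ties by smaller raw cluster
#' id.  Letters A, B, C, ... are assigned in that order.
#'
#' @param change_times named numeric vector, cluster id -> change day.
#' @param half_range_times named numeric vector, same ids -> half-range
#'   crossing day (used only for ties; may be omitted).
#' @return named character vector, cluster id -> chronological letter.
#' @export
order_chronologically <- function(change_times, half_range_times = NULL) {
  ids <- names(change_times)
  if (is.null(ids)) ids <- as.character(seq_along(change_times))
  if (is.null(half_range_times))
    half_range_times <- stats::setNames(rep(0, length(ids)), ids)
  ord <- order(change_times, half_range_times[ids], as.integer(ids))
  stats::setNames(.chrono_letters(length(ids))[order(ord)], ids)[ids]
}

#' Cluster genes into chronologically ordered temporal expression waves
#'
#' Genes are z-scored per gene — so shape rather than amplitude drives the
#' grouping — and partitioned by k-means with k-means++ initialization, at
#' most `iterations` Lloyd iterations per restart, keeping the best of
#' `restarts` restarts by total within-cluster sum of squares.  By default
#' the features are the replicate-averaged per-day profiles (the quantity
#' the wave heatmap displays), which suppresses replicate noise and
#' line/batch offsets; clustering on all individual samples is available
#' via `features = "samples"`.  Raw clusters are then labelled A, B, ...
#' in ascending order of the day their replicate-averaged mean profile
#' changes the most.
#'
#' @param dataset an `ExpressionDataset`.
#' @param genes genes to cluster (subset of the dataset's genes).
#' @param k number of waves (default 12).
#' @param iterations Lloyd iteration cap per restart (default 2000).
#' @param restarts number of k-means++ restarts (default 10).
#' @param seed RNG seed.
#' @param features `"average"` (cluster on replicate-averaged day
#'   profiles, default) or `"samples"` (all individual samples).
#' @return Object of class `WaveClustering`: `k`, `assignment` (named
#'   integer, gene -> raw cluster), `mean_profile` (cluster x day matrix of
#'   replicate-averaged means), `change_time` (named, per raw cluster),
#'   `chrono_label` (named, cluster -> letter), `label_of_gene` (named
#'   character, gene -> letter), `days`.
#' @export
cluster_waves <- function(dataset, genes, k = 12, iterations = 2000,
                          restarts = 10, seed = 1,
                          features = c("average", "samples")) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  features <- match.arg(features)
  missing_genes <- setdiff(genes, rownames(dataset$values))
  if (length(missing_genes))
    stop("genes absent from dataset: ", paste(missing_genes, collapse = ", "))
  if (k > length(genes)) stop("k exceeds the number of genes")
  days <- day_grid(dataset)

  ## replicate-averaged per-day profiles (used for mean_profile/change_time,
  ## and as the clustering features when features = "average")
  avg <- vapply(days, function(d) {
    rowMeans(dataset$values[genes, dataset$samples$day == d, drop = FALSE])
  }, numeric(length(genes)))
  dimnames(avg) <- list(genes, as.character(days))

  feat <- if (features == "samples") dataset$values[genes, , drop = FALSE]
          else avg
  sds <- apply(feat, 1L, stats::sd)
  sds[sds < 1e-12] <- 1
  z <- (feat - rowMeans(feat)) / sds

  set.seed(seed)
  best <- NULL
  attempt <- 0L
  while (is.null(best) && attempt < 5L) {
    attempt <- attempt + 1L
    for (r in seq_len(restarts)) {
      ## "did not converge" warnings at the iteration cap are acceptable;
      ## empty-cluster errors make this restart invalid
      fit <- tryCatch({
        centers <- .kmeanspp_centers(z, k)
        suppressWarnings(stats::kmeans(z, centers = centers,
                                       iter.max = iterations,
                                       algorithm = "Lloyd"))
      }, error = function(e) NULL)
      if (!is.null(fit) && length(unique(fit$cluster)) == k &&
          (is.null(best) || fit$tot.withinss < best$tot.withinss))
        best <- fit
    }
  }
  if (is.null(best))
    stop("k-means failed to produce ", k, " non-empty clusters after ",
         attempt, " rounds of ", restarts, " restarts")

  assignment <- stats::setNames(best$cluster, genes)
  mean_profile <- t(vapply(seq_len(k), function(cl) {
    colMeans(avg[assignment == cl, , drop = FALSE])
  }, numeric(length(days))))
  dimnames(mean_profile) <- list(as.character(seq_len(k)),
                                 as.character(days))
  ct <- apply(mean_profile, 1L, change_time, days = days)
  hr <- apply(mean_profile, 1L, .half_range_time, days = days)
  chrono <- order_chronologically(ct, hr)

  structure(list(k = k, assignment = assignment,
                 mean_profile = mean_profile, change_time = ct,
                 chrono_label = chrono,
                 label_of_gene = stats::setNames(chrono[as.character(assignment)],
                                                 genes),
                 days = days),
            class = "WaveClustering")
}

#' @export
print.WaveClustering <- function(x, ...) {
  cat("WaveClustering:", length(x$assignment), "genes in", x$k,
      "waves (", paste(x$chrono_label[order(x$chrono_label)], collapse = " "),
      ")\n")
  invisible(x)
}

#' Gene-to-chronological-label map
#'
#' Accepts a `WaveClustering` or a named character vector (gene -> label)
#' and returns the latter form; used by network-comparison operations.
#'
#' @param x a `WaveClustering` or named character vector.
#' @return named character vector, gene -> chronological letter.
#' @export
gene_labels <- function(x) {
  if (inherits(x, "WaveClustering")) return(x$label_of_gene)
  if (is.character(x) && !is.null(names(x))) return(x)
  stop("expected a WaveClustering or a named character vector of labels")
}
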