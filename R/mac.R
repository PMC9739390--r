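#' MAC configuration
#'
#' Parameters of the lagged-correlation network inference.  The default
#' `max_lag_prop = 1/10` means that on a 32-day course at most
#' `floor(32/10) = 3` day windows are used to compute the maximum absolute
#' correlation.
#'
#' @param max_lag_prop fraction of the series length allowed as maximum
#'   lag (default 1/10).
#' @param alpha retention significance level for the permutation p-value
#'   (default 0.05; raw, no multiplicity correction by default).
#' @param n_permutations permutations for the null (default 200).
#' @param seed RNG seed.
#' @param combine_mode how per-line networks are merged: `"union"`,
#'   `"intersection"` or `"consensus_k"`.
#' @param consensus_k minimum number of lines for `"consensus_k"`.
#' @param null_mode `"pooled"` (null |MAC| values pooled across all pairs
#'   and permutations, default) or `"per_pair"`.
#' @param fdr apply Benjamini-Hochberg adjustment before thresholding
#'   (default FALSE, matching a raw p < alpha retention rule).
#' @return A list of class `MacConfig`.
#' @export
mac_config <- function(max_lag_prop = 0.1, alpha = 0.05,
                       n_permutations = 200, seed = 1,
                       combine_mode = c("union", "intersection", "consensus_k"),
                       consensus_k = 2, null_mode = c("pooled", "per_pair"),
                       fdr = FALSE) {
  stopifnot(max_lag_prop > 0, max_lag_prop <= 1, alpha > 0, alpha < 1,
            n_permutations >= 20)
  structure(list(max_lag_prop = max_lag_prop, alpha = alpha,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 combine_mode = match.arg(combine_mode),
                 consensus_k = as.integer(consensus_k),
                 null_mode = match.arg(null_mode), fdr = fdr),
            class = "MacConfig")
}

#' Replicate-averaged per-line day profiles
#'
#' @param dataset an `ExpressionDataset`.
#' @param line_id a line identifier present in the metadata.
#' @return genes x timepoints matrix of per-day means over that line's
#'   replicates, days ascending.
#' @export
average_line_profiles <- function(dataset, line_id) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (!line_id %in% dataset$samples$line_id)
    stop("unknown line id: ", line_id)
  sel <- dataset$samples$line_id == line_id
  days <- sort(unique(dataset$samples$day[sel]))
  out <- vapply(days, function(d) {
    rowMeans(dataset$values[, sel & dataset$samples$day == d, drop = FALSE])
  }, numeric(nrow(dataset$values)))
  dimnames(out) <- list(rownames(dataset$values), as.character(days))
  out
}

#' Maximum absolute correlation between two profiles over bounded lags
#'
#' For each lag `l` in `0..max_lag` the Pearson correlation between
#' `x[1..T-l]` (source window) and `y[(1+l)..T]` (target window) is
#' computed — the source leads, realizing a source-to-target time delay.
#' The returned lag maximizes |r| (exact ties to the smallest lag) and
#' `mac` is the signed correlation there.  Zero-variance windows yield a
#' correlation of 0.
#'
#' @param x,y numeric profiles of equal length T (T >= max_lag + 3).
#' @param max_lag maximum lag in grid steps (>= 0).
#' @return list with `lag_star` and `mac`.
#' @export
mac_score <- function(x, y, max_lag) {
  if (length(x) != length(y)) stop("profile length mismatch")
  tT <- length(x)
  stopifnot(max_lag >= 0, tT >= max_lag + 3)
  best_lag <- 0L
  best_r <- 0
  for (l in 0:max_lag) {
    xs <- x[seq_len(tT - l)]
    ys <- y[seq_len(tT - l) + l]
    r <- if (stats::sd(xs) < 1e-12 || stats::sd(ys) < 1e-12) 0 else
      stats::cor(xs, ys)
    if (abs(r) > abs(best_r)) {
      best_r <- r
      best_lag <- l
    }
  }
  list(lag_star = best_lag, mac = best_r)
}

## All-pairs lagged correlations for a genes x timepoints profile matrix.
## Returns list(mac = G x G signed matrix, lag = G x G integer matrix);
## entry [i, j] scores source i -> target j.  Ties in |r| across lags go
## to the smallest lag (strict > comparison).
mac_all_pairs <- function(profiles, max_lag) {
  tT <- ncol(profiles)
  g <- nrow(profiles)
  stopifnot(max_lag >= 0, tT >= max_lag + 3)
  best_r <- matrix(0, g, g)
  best_l <- matrix(0L, g, g)
  for (l in 0:max_lag) {
    xs <- t(profiles[, seq_len(tT - l), drop = FALSE])
    ys <- t(profiles[, seq_len(tT - l) + l, drop = FALSE])
    r <- suppressWarnings(stats::cor(xs, ys))
    r[!is.finite(r)] <- 0
    upd <- abs(r) > abs(best_r)
    best_r[upd] <- r[upd]
    best_l[upd] <- l
  }
  dimnames(best_r) <- dimnames(best_l) <-
    list(rownames(profiles), rownames(profiles))
  list(mac = best_r, lag = best_l)
}

#' Permutation p-values for observed |MAC| scores
#'
#' The null distribution is built by permuting the timepoint order
#' independently per gene and recomputing |MAC| over all lags for every
#' ordered pair in each permutation.  Under the default pooled scheme the
#' null values are pooled across pairs and permutations and
#' `p = (1 + #\{null |MAC| >= observed\}) / (1 + #null)` (the add-one
#' estimator, so p is never 0).  Under `per_pair` each pair is compared
#' against its own permutation values only.
#'
#' @param profiles genes x timepoints matrix.
#' @param pairs two-column character matrix/data.frame of ordered
#'   (source, target) pairs; default all ordered pairs of distinct genes.
#' @param max_lag maximum lag in grid steps.
#' @param n_permutations number of permutations.
#' @param seed RNG seed.
#' @param null_mode `"pooled"` or `"per_pair"`.
#' @return data.frame with columns `source`, `target`, `lag_star`, `mac`,
#'   `p_value`.
#' @export
permutation_pvalues <- function(profiles, pairs = NULL, max_lag,
                                n_permutations = 200, seed = 1,
                                null_mode = c("pooled", "per_pair")) {
  null_mode <- match.arg(null_mode)
  stopifnot(n_permutations >= 20)
  g <- nrow(profiles)
  genes <- rownames(profiles)
  if (is.null(genes)) stop("profiles must have gene rownames")
  if (is.null(pairs)) {
    pairs <- cbind(rep(genes, each = g), rep(genes, times = g))
    pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  } else {
    pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  }
  obs <- mac_all_pairs(profiles, max_lag)
  si <- match(pairs[, 1L], genes)
  ti <- match(pairs[, 2L], genes)
  if (anyNA(si) || anyNA(ti))
    stop("pair gene absent from profiles: ",
         c(pairs[, 1L][is.na(si)], pairs[, 2L][is.na(ti)])[1L])
  idx <- cbind(si, ti)
  obs_mac <- obs$mac[idx]
  obs_lag <- obs$lag[idx]

  tT <- ncol(profiles)
  off_diag <- row(obs$mac) != col(obs$mac)
  set.seed(seed)
  if (null_mode == "pooled") {
    null_pool <- numeric(0)
    acc <- vector("list", n_permutations)
    for (b in seq_len(n_permutations)) {
      perm <- profiles
      for (i in seq_len(g)) perm[i, ] <- profiles[i, sample.int(tT)]
      nb <- mac_all_pairs(perm, max_lag)
      acc[[b]] <- abs(nb$mac[off_diag])
    }
    null_pool <- sort(unlist(acc))
    n_null <- length(null_pool)
    ## #{null >= obs} = n_null - #{null < obs}
    n_lt <- findInterval(abs(obs_mac), null_pool, left.open = TRUE)
    p <- (1 + (n_null - n_lt)) / (1 + n_null)
  } else {
    exceed <- integer(nrow(pairs))
    for (b in seq_len(n_permutations)) {
      perm <- profiles
      for (i in seq_len(g)) perm[i, ] <- profiles[i, sample.int(tT)]
      nb <- mac_all_pairs(perm, max_lag)
      exceed <- exceed + (abs(nb$mac[idx]) >= abs(obs_mac))
    }
    p <- (1 + exceed) / (1 + n_permutations)
  }
  data.frame(source = pairs[, 1L], target = pairs[, 2L],
             lag_star = obs_lag, mac = obs_mac, p_value = p,
             stringsAsFactors = FALSE)
}
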