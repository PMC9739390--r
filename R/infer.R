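#' Infer the directed lagged TF network for one line
#'
#' All ordered pairs of distinct TFs are scored by maximum absolute
#' lagged correlation with `max_lag = floor(max_lag_prop * T)`.  An edge
#' is retained when its permutation p-value is below `alpha` and its best
#' lag is non-null (`lag_star >= 1`); positive MAC gives an activation
#' edge, negative a repression edge.  Self-loops are never considered.
#'
#' @param profiles genes x timepoints matrix (e.g. from
#'   [average_line_profiles()]).
#' @param tf_list TF symbols to score (subset of the profile genes).
#' @param config a `MacConfig`.
#' @return A `DirectedNetwork` whose node set is `tf_list`.
#' @export
infer_line_network <- function(profiles, tf_list, config = mac_config()) {
  stopifnot(inherits(config, "MacConfig"))
  missing_tf <- setdiff(tf_list, rownames(profiles))
  if (length(missing_tf))
    stop("TF absent from profiles: ", paste(missing_tf, collapse = ", "))
  if (!length(tf_list)) return(directed_network(NULL, nodes = character()))
  tT <- ncol(profiles)
  max_lag <- floor(config$max_lag_prop * tT)
  if (max_lag < 1)
    stop("T * max_lag_prop < 1: no non-null lag is possible")
  sub <- profiles[tf_list, , drop = FALSE]
  scored <- permutation_pvalues(sub, pairs = NULL, max_lag = max_lag,
                                n_permutations = config$n_permutations,
                                seed = config$seed,
                                null_mode = config$null_mode)
  p <- if (isTRUE(config$fdr)) stats::p.adjust(scored$p_value, "BH") else
    scored$p_value
  keep <- p < config$alpha & scored$lag_star >= 1L
  edges <- scored[keep, , drop = FALSE]
  if (nrow(edges)) {
    edges <- data.frame(source = edges$source, target = edges$target,
                        lag_days = edges$lag_star, mac = edges$mac,
                        p_value = edges$p_value,
                        edge_type = ifelse(edges$mac > 0, "activation",
                                           "repression"),
                        stringsAsFactors = FALSE)
  } else edges <- NULL
  directed_network(edges, nodes = tf_list)
}

#' Merge per-line directed networks into one consensus network
#'
#' `union` keeps an edge present in any line, `intersection` only edges
#' present in every line, `consensus_k` edges present in at least `k`
#' lines.  Edges whose sign disagrees across lines are dropped under
#' intersection/consensus; under union the majority sign wins and the
#' edge is flagged (`sign_conflict`).  The merged lag is the median of
#' the member lags, the merged MAC the mean over the members of the
#' retained sign, and the merged p-value the smallest member p-value.
#'
#' @param networks list of `DirectedNetwork` (one per line).
#' @param combine_mode `"union"`, `"intersection"` or `"consensus_k"`.
#' @param k minimum line count for `"consensus_k"`.
#' @return A `DirectedNetwork` over the union of the input node sets,
#'   with extra edge columns `n_lines` and `sign_conflict`.
#' @export
combine_line_networks <- function(networks,
                                  combine_mode = c("union", "intersection",
                                                   "consensus_k"),
                                  k = 2) {
  combine_mode <- match.arg(combine_mode)
  stopifnot(length(networks) >= 1,
            all(vapply(networks, inherits, logical(1L), "DirectedNetwork")))
  n_lines <- length(networks)
  if (combine_mode == "consensus_k" && k > n_lines)
    stop("consensus k exceeds the number of networks")
  need <- switch(combine_mode, union = 1L, intersection = n_lines,
                 consensus_k = as.integer(k))

  all_edges <- do.call(rbind, lapply(seq_along(networks), function(i) {
    e <- networks[[i]]$edges
    if (!nrow(e)) return(NULL)
    e$line <- i
    e[, c("source", "target", "lag_days", "mac", "p_value", "line")]
  }))
  nodes <- sort(unique(unlist(lapply(networks, `[[`, "nodes"))))
  if (is.null(all_edges) || !nrow(all_edges))
    return(directed_network(NULL, nodes = nodes))

  key <- paste(all_edges$source, all_edges$target, sep = "\r")
  merged <- lapply(split(all_edges, key), function(e) {
    pos <- sum(e$mac > 0)
    neg <- sum(e$mac < 0)
    conflict <- pos > 0 && neg > 0
    sgn <- if (pos > neg) 1 else if (neg > pos) -1 else sign(sum(e$mac))
    if (sgn == 0) return(NULL)  # exact tie in count and magnitude
    ## the majority sign must be supported by >= `need` lines; under
    ## intersection a conflicted edge therefore always drops
    if (max(pos, neg) < need) return(NULL)
    members <- e[sign(e$mac) == sgn, , drop = FALSE]
    data.frame(source = e$source[1L], target = e$target[1L],
               lag_days = stats::median(e$lag_days),
               mac = mean(members$mac), p_value = min(e$p_value),
               edge_type = if (sgn > 0) "activation" else "repression",
               n_lines = nrow(e), sign_conflict = conflict,
               stringsAsFactors = FALSE)
  })
  merged <- do.call(rbind, merged)
  directed_network(merged, nodes = nodes)
}
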