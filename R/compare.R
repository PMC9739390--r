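## undirected neighbor sets: unique unordered pairs from an edge table
.undirected_pairs <- function(a, b) {
  unique(paste(pmin(a, b), pmax(a, b), sep = "\r"))
}

#' Graph statistics of a network
#'
#' Neighbors are counted in the undirected sense (i and j are neighbors if
#' an edge exists in either direction); `density` is the average number of
#' distinct neighbors divided by (n_nodes - 1), i.e. the normalized
#' averaged number of neighbors.  Declared isolated nodes count in
#' `n_nodes` and pull the density down.
#'
#' @param network a `DirectedNetwork` or `ReferenceNetwork`.
#' @return list of class `NetworkStats`: `n_nodes`, `n_edges`,
#'   `n_activating`, `n_inhibitory` (both NA for an undirected reference),
#'   `avg_neighbors`, `density`.
#' @export
network_stats <- function(network) {
  if (inherits(network, "DirectedNetwork")) {
    nodes <- network$nodes
    a <- network$edges$source
    b <- network$edges$target
    n_act <- sum(network$edges$edge_type == "activation")
    n_inh <- sum(network$edges$edge_type == "repression")
    n_edges <- nrow(network$edges)
  } else if (inherits(network, "ReferenceNetwork")) {
    nodes <- reference_nodes(network)
    a <- network$edges$protein1
    b <- network$edges$protein2
    n_act <- NA_integer_
    n_inh <- NA_integer_
    n_edges <- nrow(network$edges)
  } else stop("expected a DirectedNetwork or ReferenceNetwork")
  if (length(nodes) < 2L)
    stop("density is undefined for a network with fewer than 2 nodes")
  pairs <- .undirected_pairs(a, b)
  ends <- unlist(strsplit(pairs, "\r", fixed = TRUE))
  deg <- table(factor(ends, levels = nodes))
  avg_neighbors <- mean(deg)
  structure(list(n_nodes = length(nodes), n_edges = n_edges,
                 n_activating = n_act, n_inhibitory = n_inh,
                 avg_neighbors = avg_neighbors,
                 density = avg_neighbors / (length(nodes) - 1L)),
            class = "NetworkStats")
}

#' @export
print.NetworkStats <- function(x, ...) {
  cat("NetworkStats:", x$n_nodes, "nodes,", x$n_edges, "edges; density",
      sprintf("%.4f", x$density), "\n")
  invisible(x)
}

#' Overlap of a reference undirected network with a directed network
#'
#' Fractions of reference features recovered by the expression-based
#' directed network.  A reference pair \{a, b\} counts as recovered when an
#' edge a->b or b->a exists, regardless of sign or lag (the reference
#' carries neither).  The node fraction counts reference nodes that are
#' non-isolated in the directed network.
#'
#' @param directed a `DirectedNetwork`.
#' @param reference a `ReferenceNetwork` (already score-filtered and
#'   restricted to the query gene list).
#' @return list of class `OverlapReport`: `node_overlap_fraction`,
#'   `link_overlap_fraction`, `n_reference_nodes`, `n_reference_links`.
#' @export
overlap <- function(directed, reference) {
  stopifnot(inherits(directed, "DirectedNetwork"),
            inherits(reference, "ReferenceNetwork"))
  if (!nrow(reference$edges)) stop("empty reference network")
  ref_nodes <- reference_nodes(reference)
  non_isolated <- unique(c(directed$edges$source, directed$edges$target))
  node_frac <- length(intersect(ref_nodes, non_isolated)) / length(ref_nodes)
  ref_pairs <- .undirected_pairs(reference$edges$protein1,
                                 reference$edges$protein2)
  dir_pairs <- .undirected_pairs(directed$edges$source,
                                 directed$edges$target)
  link_frac <- mean(ref_pairs %in% dir_pairs)
  structure(list(node_overlap_fraction = node_frac,
                 link_overlap_fraction = link_frac,
                 n_reference_nodes = length(ref_nodes),
                 n_reference_links = length(ref_pairs)),
            class = "OverlapReport")
}

#' @export
print.OverlapReport <- function(x, ...) {
  cat(sprintf("OverlapReport: %.1f%% of %d reference nodes, %.1f%% of %d reference links recovered\n",
              100 * x$node_overlap_fraction, x$n_reference_nodes,
              100 * x$link_overlap_fraction, x$n_reference_links))
  invisible(x)
}

#' Recovered fraction of reference links between successive waves
#'
#' Restricts the reference pairs to those whose endpoints lie in
#' chronologically adjacent waves (letters c and c+1) and returns the
#' fraction recovered by the directed network, as in [overlap()].  When no
#' reference pair joins adjacent waves the fraction is undefined and
#' `NA` is returned (never 0).
#'
#' @param directed a `DirectedNetwork`.
#' @param reference a `ReferenceNetwork`.
#' @param clustering a `WaveClustering` or named gene -> letter vector.
#' @return fraction in [0, 1], or `NA_real_` when undefined.
#' @export
successive_cluster_links <- function(directed, reference, clustering) {
  stopifnot(inherits(directed, "DirectedNetwork"),
            inherits(reference, "ReferenceNetwork"))
  labels <- gene_labels(clustering)
  ref_genes <- reference_nodes(reference)
  unlabelled <- setdiff(ref_genes, names(labels))
  if (length(unlabelled))
    stop("gene without cluster label: ", unlabelled[1L])
  letters_seen <- sort(unique(labels))
  rank_of <- stats::setNames(seq_along(letters_seen), letters_seen)
  r1 <- rank_of[labels[reference$edges$protein1]]
  r2 <- rank_of[labels[reference$edges$protein2]]
  adjacent <- abs(r1 - r2) == 1L
  if (!any(adjacent)) return(NA_real_)
  ref_pairs <- .undirected_pairs(reference$edges$protein1[adjacent],
                                 reference$edges$protein2[adjacent])
  dir_pairs <- .undirected_pairs(directed$edges$source,
                                 directed$edges$target)
  mean(ref_pairs %in% dir_pairs)
}

#' Extract the downstream sub-network of seed TFs
#'
#' Keeps edges from any seed to any TF whose chronological label is in
#' `target_labels` and whose edge type passes the filter (activation by
#' default), then induces the subgraph on the seeds plus the selected
#' targets, retaining all edges of the allowed type among them (including
#' target-to-target edges).
#'
#' @param directed a `DirectedNetwork`.
#' @param seeds seed TF symbols (must be network nodes).
#' @param clustering a `WaveClustering` or named gene -> letter vector.
#' @param target_labels chronological letters that qualify a target.
#' @param edge_type_filter edge types to keep (default `"activation"`).
#' @return A `DirectedNetwork` over seeds plus selected targets.
#' @export
extract_subnetwork <- function(directed, seeds, clustering, target_labels,
                               edge_type_filter = "activation") {
  stopifnot(inherits(directed, "DirectedNetwork"))
  unknown <- setdiff(seeds, directed$nodes)
  if (length(unknown))
    stop("unknown seed: ", paste(unknown, collapse = ", "))
  labels <- gene_labels(clustering)
  e <- directed$edges
  pass_type <- e$edge_type %in% edge_type_filter
  tgt_label <- labels[e$target]
  pick <- pass_type & e$source %in% seeds &
    !is.na(tgt_label) & tgt_label %in% target_labels
  targets <- unique(e$target[pick])
  keep_nodes <- union(seeds, targets)
  among <- pass_type & e$source %in% keep_nodes & e$target %in% keep_nodes
  edges <- e[among, , drop = FALSE]
  directed_network(if (nrow(edges)) edges else NULL, nodes = keep_nodes)
}
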