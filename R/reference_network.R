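#' Construct a ReferenceNetwork
#'
#' An undirected weighted edge list in the STRING style: unordered gene
#' pairs with a combined interaction score in [0, 1].  Pairs are stored once
#' with endpoints in lexicographic order; self-pairs are dropped and
#' duplicate pairs collapsed keeping the maximum score.
#'
#' @param edges data.frame with columns `protein1`, `protein2`,
#'   `combined_score`.
#' @return Object of class `ReferenceNetwork` with a normalized `edges`
#'   data.frame.
#' @export
reference_network <- function(edges) {
  stopifnot(all(c("protein1", "protein2", "combined_score") %in% names(edges)))
  a <- as.character(edges$protein1)
  b <- as.character(edges$protein2)
  s <- as.numeric(edges$combined_score)
  keep <- a != b
  a <- a[keep]; b <- b[keep]; s <- s[keep]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (length(key)) {
    s <- vapply(split(s, key), max, numeric(1L))
    pairs <- do.call(rbind, strsplit(names(s), "\r", fixed = TRUE))
    edges <- data.frame(protein1 = pairs[, 1L], protein2 = pairs[, 2L],
                        combined_score = unname(s),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$protein1, edges$protein2), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(protein1 = character(), protein2 = character(),
                        combined_score = numeric())
  }
  structure(list(edges = edges), class = "ReferenceNetwork")
}

#' Read a STRING-dialect interaction file and filter by combined score
#'
#' Accepts both export dialects: scores on the 0-1 or the 0-1000 scale
#' (auto-detected from the maximum value; scores are divided by 1000 when
#' any exceeds 1).  Edges below `min_score` are removed; the threshold is
#' inclusive, matching the usual reading of a "minimum required interaction
#' score".
#'
#' @param path TSV (or whitespace-delimited) file with columns `protein1`,
#'   `protein2`, `combined_score`.
#' @param min_score minimum combined score on the 0-1 scale (default 0.4).
#' @return A `ReferenceNetwork`.
#' @export
read_reference_network <- function(path, min_score = 0.4) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty reference network file: ", path)
  parts <- strsplit(lines, "[\t ]+")
  n_fields <- lengths(parts)
  header <- parts[[1L]]
  idx <- match(c("protein1", "protein2", "combined_score"), header)
  if (anyNA(idx))
    stop("line 1: header must name protein1, protein2, combined_score")
  bad <- which(n_fields[-1L] < max(idx)) + 1L
  if (length(bad))
    stop("line ", bad[1L], ": expected at least ", max(idx), " fields")
  body <- parts[-1L]
  p1 <- vapply(body, `[`, character(1L), idx[1L])
  p2 <- vapply(body, `[`, character(1L), idx[2L])
  sc <- suppressWarnings(as.numeric(vapply(body, `[`, character(1L), idx[3L])))
  if (anyNA(sc))
    stop("line ", which(is.na(sc))[1L] + 1L, ": non-numeric combined_score")
  if (length(sc) && max(sc) > 1) sc <- sc / 1000
  keep <- sc >= min_score
  reference_network(data.frame(protein1 = p1[keep], protein2 = p2[keep],
                               combined_score = sc[keep],
                               stringsAsFactors = FALSE))
}

#' Nodes of a reference network (endpoints of its retained edges)
#' @param reference a `ReferenceNetwork`.
#' @return character vector of gene symbols.
#' @export
reference_nodes <- function(reference) {
  stopifnot(inherits(reference, "ReferenceNetwork"))
  sort(unique(c(reference$edges$protein1, reference$edges$protein2)))
}

#' @export
print.ReferenceNetwork <- function(x, ...) {
  cat("ReferenceNetwork:", nrow(x$edges), "undirected edges over",
      length(reference_nodes(x)), "nodes\n")
  invisible(x)
}
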