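#' Partition samples into k cross-validation folds
#'
#' Seeded shuffle followed by contiguous chunking; fold sizes differ by at
#' most one (the first `n %% k` folds take the extra sample). Every sample
#' appears in exactly one fold.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param k number of folds (>= 2, <= number of samples).
#' @param seed integer RNG seed.
#' @return List of k character vectors (the test folds).
#' @export
kfold_split <- function(sample_ids, k = 5, seed = 1) {
  n <- length(sample_ids)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("more folds than samples")
  set.seed(seed)
  shuffled <- sample(sample_ids)
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  split(shuffled, rep(seq_len(k), times = sizes))
}

#' Top-K precision, recall and F1 of a ranked gene list
#'
#' @param ranking ordered character vector of gene identifiers (best first).
#' @param truth nonempty character vector of reference driver genes.
#' @param K list prefix length; if it exceeds the ranking length the full
#'   list is evaluated with a warning.
#' @return List with `K`, `precision`, `recall`, `f1` (F1 is 0 when
#'   precision + recall is 0).
#' @export
topk_metrics <- function(ranking, truth, K) {
  stopifnot(K >= 1, length(truth) > 0)
  if (K > length(ranking)) {
    warning("K exceeds ranking length; evaluating the full list")
    K <- length(ranking)
  }
  hits <- length(intersect(ranking[seq_len(K)], truth))
  precision <- hits / K
  recall <- hits / length(unique(truth))
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(K = K, precision = precision, recall = recall, f1 = f1)
}

.ppi_igraph <- function(ppi) {
  igraph::graph_from_data_frame(ppi$edges[, c("from", "to")], directed = FALSE,
                                vertices = ppi$nodes)
}

#' Degree-preserving edge rewiring (negative control)
#'
#' Randomly rewires the network by double-edge swaps that preserve every
#' node's degree exactly; swaps that would create self-loops or duplicate
#' edges are rejected. Confidence scores are reassigned to the rewired edges
#' (the confidence multiset is preserved, the pairing with specific edges is
#' not meaningful after rewiring).
#'
#' @param ppi a [ppi_network()] with at least 2 edges.
#' @param n_swaps number of attempted swaps (default 10 per edge).
#' @param seed integer RNG seed.
#' @return A rewired `ppi_network` with identical degree multiset.
#' @export
edge_shuffle <- function(ppi, n_swaps = 10 * n_edges(ppi), seed = 1) {
  if (n_edges(ppi) < 2) stop("too few edges to swap")
  set.seed(seed)
  g <- igraph::rewire(.ppi_igraph(ppi),
                      igraph::keeping_degseq(loops = FALSE, niter = n_swaps))
  el <- igraph::as_edgelist(g)
  ppi_network(data.frame(from = el[, 1], to = el[, 2],
                         confidence = sort(ppi$edges$confidence),
                         stringsAsFactors = FALSE))
}

#' Random gene-label permutation (negative control)
#'
#' Keeps the network topology intact but permutes the gene labels over the
#' nodes, destroying the correspondence between a gene's features and its
#' network position. The drawn permutation is redrawn if it is the identity.
#'
#' @param ppi a [ppi_network()].
#' @param seed integer RNG seed.
#' @return A relabeled `ppi_network`, isomorphic to the input.
#' @export
node_shuffle <- function(ppi, seed = 1) {
  set.seed(seed)
  nodes <- ppi$nodes
  if (length(nodes) < 2) return(ppi)
  repeat {
    perm <- stats::setNames(sample(nodes), nodes)
    if (any(perm != nodes)) break
  }
  ppi_network(data.frame(from = unname(perm[ppi$edges$from]),
                         to = unname(perm[ppi$edges$to]),
                         confidence = ppi$edges$confidence,
                         stringsAsFactors = FALSE))
}

#' Degree multiset of a PPI network
#' @param ppi a [ppi_network()].
#' @return Sorted integer vector of node degrees.
#' @export
degree_multiset <- function(ppi) {
  sort(as.integer(table(factor(c(ppi$edges$from, ppi$edges$to),
                               levels = ppi$nodes))))
}

#' Overlap of top-K genes across rankings
#'
#' Computes the common intersection of the top K genes of each ranking plus
#' the size of every intersection region (all non-empty combinations of the
#' rankings, exclusive counts as in a Venn diagram).
#'
#' @param rankings named list (>= 2) of ordered gene identifier vectors.
#' @param K prefix length; rankings shorter than K are used in full with a
#'   warning.
#' @return List with `intersection` (character vector common to all top-K
#'   lists) and `counts` (named integer vector of exclusive Venn region
#'   sizes, names like `"netA&netB"`).
#' @export
topk_overlap <- function(rankings, K = 100) {
  stopifnot(length(rankings) >= 2)
  if (is.null(names(rankings))) names(rankings) <- paste0("list", seq_along(rankings))
  tops <- lapply(rankings, function(r) {
    if (length(r) < K) {
      warning("ranking shorter than K; using the full list")
      r
    } else r[seq_len(K)]
  })
  genes <- unique(unlist(tops))
  member <- vapply(tops, function(t) genes %in% t, logical(length(genes)))
  if (length(genes) == 1) member <- matrix(member, nrow = 1,
                                           dimnames = list(NULL, names(tops)))
  region <- apply(member, 1, function(m) paste(names(tops)[m], collapse = "&"))
  counts <- table(region)
  list(intersection = sort(genes[rowSums(member) == length(tops)]),
       counts = stats::setNames(as.integer(counts), names(counts)))
}
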