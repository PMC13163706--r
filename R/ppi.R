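#' Protein-protein interaction network
#'
#' A `ppi_network` is an undirected, confidence-weighted gene-gene graph held
#' as an edge table. Edges are stored with `from < to` lexicographically, no
#' self-loops and no duplicate pairs; duplicates are collapsed keeping the
#' maximum confidence.
#'
#' @param edges data frame with columns `from`, `to` (character gene symbols)
#'   and optionally `confidence` (numeric in \[0, 1\]; missing column means 1).
#' @return An object of class `ppi_network`: a list with `edges` (data frame
#'   `from`, `to`, `confidence`) and `nodes` (sorted character vector).
#' @export
ppi_network <- function(edges) {
  stopifnot(is.data.frame(edges))
  if (!all(c("from", "to") %in% names(edges))) {
    stop("edges must have columns 'from' and 'to'")
  }
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  conf <- if ("confidence" %in% names(edges)) as.numeric(edges$confidence) else rep(1, length(from))
  if (anyNA(conf)) stop("non-numeric confidence value")
  keep <- from != to
  from <- from[keep]; to <- to[keep]; conf <- conf[keep]
  a <- pmin(from, to)
  b <- pmax(from, to)
  if (length(a)) {
    key <- paste(a, b, sep = "\r")
    conf <- vapply(split(conf, key), max, numeric(1))
    pairs <- do.call(rbind, strsplit(names(conf), "\r", fixed = TRUE))
    ord <- order(pairs[, 1], pairs[, 2])
    out <- data.frame(from = pairs[ord, 1], to = pairs[ord, 2],
                      confidence = unname(conf[ord]), stringsAsFactors = FALSE)
  } else {
    out <- data.frame(from = character(), to = character(), confidence = numeric(),
                      stringsAsFactors = FALSE)
  }
  structure(list(edges = out, nodes = sort(unique(c(out$from, out$to)))),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network: %d genes, %d interactions\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of edges of a PPI network
#' @param ppi a [ppi_network()].
#' @return Integer edge count.
#' @export
n_edges <- function(ppi) nrow(ppi$edges)

#' Read a PPI edge list, applying a confidence filter
#'
#' Reads a 2- or 3-column tab-delimited edge list (gene, gene, confidence).
#' A missing confidence column is treated as confidence 1 for every edge.
#' Interactions below the confidence threshold are dropped (e.g. the CPDB
#' convention keeps scores >= 0.5; the STRING convention keeps scores
#' strictly > 0.85, obtained with `strict_greater = TRUE`). Self-loops are
#' removed and duplicate unordered pairs collapsed to their maximum
#' confidence.
#'
#' @param path path to the tab-delimited edge list (no header).
#' @param min_confidence numeric threshold in \[0, 1\].
#' @param strict_greater if `TRUE` keep edges with confidence strictly greater
#'   than the threshold; otherwise greater-or-equal.
#' @return A [ppi_network()].
#' @export
read_ppi <- function(path, min_confidence = 0.5, strict_greater = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2)) stop("PPI edge row with fewer than two fields")
  from <- vapply(parts, `[[`, character(1), 1)
  to <- vapply(parts, `[[`, character(1), 2)
  conf <- rep(1, length(parts))
  has3 <- nf >= 3
  if (any(has3)) {
    raw <- vapply(parts[has3], `[[`, character(1), 3)
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) stop("non-numeric confidence value in PPI file")
    conf[has3] <- val
  }
  keep <- if (strict_greater) conf > min_confidence else conf >= min_confidence
  ppi_network(data.frame(from = from[keep], to = to[keep],
                         confidence = conf[keep], stringsAsFactors = FALSE))
}

#' Sparse gene-gene adjacency of a PPI network
#'
#' @param ppi a [ppi_network()].
#' @param genes character vector defining row/column order; edges touching
#'   genes outside this set are dropped.
#' @return A symmetric sparse 0/1 `Matrix::sparseMatrix` (genes x genes).
#' @export
ppi_adjacency <- function(ppi, genes) {
  i <- match(ppi$edges$from, genes)
  j <- match(ppi$edges$to, genes)
  keep <- !is.na(i) & !is.na(j)
  i <- i[keep]; j <- j[keep]
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                       dims = c(length(genes), length(genes)),
                       dimnames = list(genes, genes), use.last.ij = TRUE)
}
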