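#' Read a genes-x-samples numeric matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' symbols (the dialect written by [write_cohort()]).
#'
#' @param path path to the tab-delimited file.
#' @return Numeric matrix, rownames = genes, colnames = samples.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (!all(is.finite(m))) stop("non-finite values in matrix ", path)
  m
}

#' Read a binary genes-x-samples mutation matrix from TSV
#'
#' @inheritParams read_expression
#' @return Binary 0/1 matrix, rownames = genes, colnames = samples.
#' @export
read_mutation <- function(path) {
  m <- read_expression(path)
  if (!all(m %in% c(0, 1))) stop("mutation matrix must be binary 0/1")
  m
}

#' Read a driver gene list
#'
#' One gene symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path path to the plain-text list.
#' @return Character vector of unique gene symbols.
#' @export
read_driver_list <- function(path) {
  lines <- trimws(readLines(path))
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Per-gene expression z-scores across samples
#'
#' Standardizes each gene row across samples: z = (x - mu) / sigma. Rows with
#' zero spread return all zeros (such genes can never be flagged aberrant).
#'
#' @param expr numeric genes-x-samples matrix with at least 2 columns.
#' @param sd_type `"population"` (divide by n) or `"sample"` (divide by n-1).
#' @return Matrix of z-scores, same dimnames as `expr`.
#' @export
compute_zscores <- function(expr, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!is.matrix(expr) || ncol(expr) < 2) stop("need a matrix with >= 2 samples")
  if (!all(is.finite(expr))) stop("non-finite expression values")
  mu <- rowMeans(expr)
  cent <- expr - mu
  denom <- if (sd_type == "population") ncol(expr) else ncol(expr) - 1L
  sdv <- sqrt(rowSums(cent^2) / denom)
  z <- cent / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z
}

#' Flag aberrantly expressed gene-sample entries
#'
#' An entry is aberrant when its z-score meets the threshold (default z >= 2).
#' With `two_sided = TRUE` the magnitude is compared instead (|z| >= threshold).
#'
#' @param z z-score matrix from [compute_zscores()].
#' @param threshold aberrance cutoff in z-units.
#' @param two_sided flag both tails instead of the upper tail only.
#' @return Binary 0/1 matrix of the same shape.
#' @export
flag_aberrant <- function(z, threshold = 2, two_sided = FALSE) {
  if (!all(is.finite(z))) stop("non-finite z-scores")
  v <- if (two_sided) abs(z) else z
  (v >= threshold) + 0
}

#' Filter mutated genes by downstream expression impact
#'
#' A mutated gene is retained only if its mutation plausibly perturbs
#' downstream expression: under the default same-sample coupling, gene g is
#' kept iff there is a sample j with `mut[g, j] == 1` and some PPI neighbor h
#' of g aberrant in that same sample j. Cohort-level coupling (`"cohort"`)
#' relaxes this to a neighbor aberrant in any sample. Genes never mutated are
#' always excluded.
#'
#' @param mut binary genes-x-samples mutation matrix.
#' @param aberrant binary genes-x-samples matrix from [flag_aberrant()], with
#'   the same dimnames as `mut`.
#' @param ppi a [ppi_network()].
#' @param coupling `"sample"` (default) or `"cohort"`.
#' @return Character vector of retained gene symbols (sorted).
#' @export
filter_mutated_genes <- function(mut, aberrant, ppi,
                                 coupling = c("sample", "cohort")) {
  coupling <- match.arg(coupling)
  stopifnot(identical(dim(mut), dim(aberrant)))
  if (nrow(mut) == 0 || sum(mut) == 0) stop("empty mutation matrix")
  if (n_edges(ppi) == 0) stop("empty PPI network")
  genes <- rownames(mut)
  adj <- ppi_adjacency(ppi, genes)
  # nbr_ab[g, j] > 0 iff some PPI neighbor of g is aberrant in sample j
  nbr_ab <- as.matrix(adj %*% aberrant) > 0
  hit <- if (coupling == "sample") {
    rowSums(mut * nbr_ab) > 0
  } else {
    rowSums(mut) > 0 & rowSums(nbr_ab) > 0
  }
  sort(genes[hit])
}

#' Assemble a cohort dataset from harmonized matrices
#'
#' Restricts the mutation and expression matrices to the retained genes and
#' builds the three model inputs: the gene feature matrix `Xg` (binary
#' mutations, genes x samples), the sample feature matrix `Xs` (expression,
#' samples x genes), and the driver gene-sample association matrix `A` with
#' `A[i, j] = 1` iff gene i is mutated in sample j and is a known driver.
#' Gene order is lexicographic; sample order follows the input columns.
#'
#' @param expr numeric genes-x-samples expression matrix.
#' @param mut binary genes-x-samples mutation matrix (same dimnames).
#' @param retained character vector of genes to keep (subset of rownames).
#' @param known_drivers character vector of known driver gene symbols.
#' @return An object of class `cohort_dataset`: list with `Xg`, `Xs`, `A`,
#'   `genes`, `samples`, `known_drivers`.
#' @export
build_dataset <- function(expr, mut, retained, known_drivers) {
  stopifnot(identical(rownames(expr), rownames(mut)),
            identical(colnames(expr), colnames(mut)))
  retained <- sort(unique(retained))
  if (length(retained) == 0) stop("empty retained gene set")
  if (!all(retained %in% rownames(mut))) stop("retained genes missing from matrices")
  known_drivers <- unique(as.character(known_drivers))
  if (!any(known_drivers %in% retained)) {
    message("note: no known driver among the retained genes")
  }
  Xg <- mut[retained, , drop = FALSE]
  Xs <- t(expr[retained, , drop = FALSE])
  A <- Xg * (retained %in% known_drivers)
  structure(list(Xg = Xg, Xs = Xs, A = A, genes = retained,
                 samples = colnames(mut), known_drivers = known_drivers),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf(paste0("Cohort dataset: %d genes x %d samples\n",
                     "  known drivers among retained genes: %d\n",
                     "  positive gene-sample associations:  %d\n"),
              length(x$genes), length(x$samples),
              sum(x$genes %in% x$known_drivers), sum(x$A)))
  invisible(x)
}

#' Build a cohort dataset from raw inputs
#'
#' End-to-end preprocessing: harmonizes the gene universes of the expression
#' matrix, mutation matrix and PPI network (intersection; dropped symbols are
#' reported), harmonizes samples (columns present in both matrices, in
#' expression column order), computes expression z-scores, flags aberrant
#' entries, filters mutated genes by the PPI/aberrance coupling, and
#' assembles the [build_dataset()] matrices.
#'
#' @param expr numeric genes-x-samples expression matrix.
#' @param mut binary genes-x-samples mutation matrix.
#' @param ppi a [ppi_network()].
#' @param known_drivers character vector of driver gene symbols.
#' @param z_threshold aberrance cutoff (z-units).
#' @param two_sided flag both expression tails.
#' @param sd_type standard deviation convention, see [compute_zscores()].
#' @param coupling mutation-aberration coupling, see [filter_mutated_genes()].
#' @param quiet suppress harmonization messages.
#' @return A `cohort_dataset`.
#' @export
build_cohort <- function(expr, mut, ppi, known_drivers, z_threshold = 2,
                         two_sided = FALSE, sd_type = "population",
                         coupling = "sample", quiet = FALSE) {
  genes <- sort(intersect(intersect(rownames(expr), rownames(mut)), ppi$nodes))
  if (length(genes) == 0) stop("no genes shared by expression, mutation and PPI inputs")
  dropped <- length(union(rownames(expr), rownames(mut))) - length(genes)
  samples <- intersect(colnames(expr), colnames(mut))
  if (length(samples) < 2) stop("need at least 2 shared samples")
  if (!quiet && dropped > 0) {
    message(sprintf("harmonization dropped %d gene symbol(s); %d genes, %d samples retained",
                    dropped, length(genes), length(samples)))
  }
  expr <- expr[genes, samples, drop = FALSE]
  mut <- mut[genes, samples, drop = FALSE]
  z <- compute_zscores(expr, sd_type = sd_type)
  ab <- flag_aberrant(z, threshold = z_threshold, two_sided = two_sided)
  retained <- filter_mutated_genes(mut, ab, ppi, coupling = coupling)
  if (!quiet) {
    message(sprintf("expression-impact filter retained %d of %d mutated genes",
                    length(retained), sum(rowSums(mut) > 0)))
  }
  build_dataset(expr, mut, retained, known_drivers)
}
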