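#' Simulate a planted-driver tumor cohort
#'
#' Generates a random gene-gene interaction network, a binary somatic mutation
#' matrix, and an expression matrix in which mutated planted drivers shift the
#' expression of their network neighbors in the same sample. This emulates the
#' premise that driver mutations perturb downstream expression through the
#' interaction network: when a planted driver is mutated in a sample, each of
#' its neighbors has its expression in that sample shifted by
#' `neighbor_shift * noise_sd` (additively per mutated driver neighbor) on top
#' of per-gene Gaussian noise. The baseline expression is zero-mean Gaussian
#' with standard deviation `noise_sd`, so `neighbor_shift` is interpretable in
#' z-units against the usual aberrance threshold of 2.
#'
#' The defaults define a cohort with strong, recoverable signal: 200 genes,
#' 50 samples, 20 planted drivers mutated in 30% of samples versus a 5%
#' passenger rate, and a +3 z-unit neighbor shift.
#'
#' @param n_genes,n_samples,n_drivers cohort dimensions; `n_drivers < n_genes`.
#' @param driver_mut_rate,passenger_mut_rate per-gene per-sample mutation
#'   probabilities in \[0, 1\].
#' @param neighbor_shift expression shift (in units of `noise_sd`) applied to
#'   neighbors of a mutated driver in that sample.
#' @param edge_prob Erdős–Rényi edge probability of the random network.
#' @param noise_sd per-gene expression noise standard deviation.
#' @param network_model `"erdos_renyi"` or `"barabasi_albert"` (preferential
#'   attachment, degree-heterogeneous; uses `edge_prob` to set the mean degree).
#' @param seed integer RNG seed; the cohort is fully reproducible from it.
#' @return An object of class `synthetic_cohort`: list with `expr`, `mut`
#'   (genes x samples matrices), `ppi` (a [ppi_network()]), `drivers`
#'   (character vector of planted drivers) and `spec` (the parameters used).
#' @export
simulate_cohort <- function(n_genes = 200, n_samples = 50, n_drivers = 20,
                            driver_mut_rate = 0.3, passenger_mut_rate = 0.05,
                            neighbor_shift = 3, edge_prob = 0.04,
                            noise_sd = 1,
                            network_model = c("erdos_renyi", "barabasi_albert"),
                            seed = 1) {
  network_model <- match.arg(network_model)
  stopifnot(n_drivers < n_genes, n_samples >= 2,
            driver_mut_rate >= 0 && driver_mut_rate <= 1,
            passenger_mut_rate >= 0 && passenger_mut_rate <= 1,
            edge_prob > 0 && edge_prob <= 1, noise_sd > 0)
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  samples <- sprintf("S%03d", seq_len(n_samples))

  g <- if (network_model == "erdos_renyi") {
    igraph::sample_gnp(n_genes, edge_prob)
  } else {
    igraph::sample_pa(n_genes, m = max(1L, round(edge_prob * (n_genes - 1) / 2)),
                      directed = FALSE)
  }
  el <- igraph::as_edgelist(g)
  ppi <- ppi_network(data.frame(
    from = genes[el[, 1]], to = genes[el[, 2]],
    confidence = round(stats::runif(nrow(el), 0.5, 1), 4),
    stringsAsFactors = FALSE))

  drivers <- sort(sample(genes, n_drivers))
  rate <- ifelse(genes %in% drivers, driver_mut_rate, passenger_mut_rate)
  mut <- matrix(as.double(stats::rbinom(n_genes * n_samples, 1, rep(rate, n_samples))),
                nrow = n_genes, dimnames = list(genes, samples))

  expr <- matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                 nrow = n_genes, dimnames = list(genes, samples))
  adj <- ppi_adjacency(ppi, genes)
  # shift[h, j] = number of mutated driver neighbors of h in sample j
  drv_mut <- mut * (genes %in% drivers)
  shift <- as.matrix(adj %*% drv_mut)
  expr <- expr + neighbor_shift * noise_sd * shift
  expr <- round(expr, 6)

  structure(list(expr = expr, mut = mut, ppi = ppi, drivers = drivers,
                 spec = list(n_genes = n_genes, n_samples = n_samples,
                             n_drivers = n_drivers,
                             driver_mut_rate = driver_mut_rate,
                             passenger_mut_rate = passenger_mut_rate,
                             neighbor_shift = neighbor_shift,
                             edge_prob = edge_prob, noise_sd = noise_sd,
                             network_model = network_model, seed = seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort: %d genes x %d samples, ",
                     "%d planted drivers, %d PPI edges (seed %d)\n"),
              nrow(x$mut), ncol(x$mut), length(x$drivers),
              n_edges(x$ppi), x$spec$seed))
  invisible(x)
}

.write_matrix_tsv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
}

#' Write a cohort fixture to disk
#'
#' Emits `expression.tsv`, `mutation.tsv`, `ppi.tsv` and `drivers.txt` in
#' exactly the dialects the readers consume; the round trip through
#' [read_expression()], [read_mutation()], [read_ppi()] and
#' [read_driver_list()] is lossless.
#'
#' @param cohort a `synthetic_cohort` (or any list with `expr`, `mut`, `ppi`,
#'   `drivers`).
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             mutation = file.path(dir, "mutation.tsv"),
             ppi = file.path(dir, "ppi.tsv"),
             drivers = file.path(dir, "drivers.txt"))
  .write_matrix_tsv(cohort$expr, paths[["expression"]])
  .write_matrix_tsv(cohort$mut, paths[["mutation"]])
  e <- cohort$ppi$edges
  writeLines(paste(e$from, e$to,
                   format(e$confidence, digits = 17, trim = TRUE,
                          scientific = FALSE), sep = "\t"),
             paths[["ppi"]])
  writeLines(cohort$drivers, paths[["drivers"]])
  invisible(paths)
}
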