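#' Row-normalize a nonnegative matrix
#'
#' Divides each row by its sum (the degree-normalization D^-1 A used for the
#' bipartite aggregation matrices). Rows summing to zero are left at zero, so
#' isolated nodes simply propagate no neighbor information.
#'
#' @param A nonnegative numeric matrix.
#' @return Matrix whose nonzero rows sum to 1.
#' @export
row_normalize <- function(A) {
  if (any(A < 0)) stop("negative entries in adjacency")
  rs <- rowSums(A)
  A / ifelse(rs > 0, rs, 1)
}

#' Subsample neighbors to a fixed fan-out
#'
#' For each row of a binary adjacency matrix, keeps at most `size` of its
#' nonzero entries, chosen uniformly without replacement under the given seed.
#' Rows with `size` or fewer neighbors are unchanged. The result is meant to
#' be row-normalized afterwards.
#'
#' @param A binary 0/1 matrix.
#' @param size maximum neighbors kept per row (>= 1).
#' @param seed integer RNG seed; same seed and input give identical output.
#' @return Binary matrix with row sums capped at `size`.
#' @export
sample_neighbors <- function(A, size, seed = 1) {
  if (!all(A %in% c(0, 1))) stop("adjacency must be binary for neighbor sampling")
  stopifnot(size >= 1)
  set.seed(seed)
  out <- A
  for (i in seq_len(nrow(A))) {
    nz <- which(A[i, ] > 0)
    if (length(nz) > size) {
      drop <- sample(nz, length(nz) - size)
      out[i, drop] <- 0
    }
  }
  out
}

#' One GraphSAGE layer on one side of the bipartite graph
#'
#' Computes `ReLU(H_self %*% W_self + A_norm %*% H_other %*% W_neigh)`:
#' the node's own features and the degree-normalized mean of its neighbors'
#' features (nodes of the other type), each linearly transformed, summed and
#' passed through ReLU.
#'
#' @param H_self features of the updated node type (n x d_in).
#' @param H_other features of the other node type (m x d_other).
#' @param A_norm row-normalized n x m aggregation matrix.
#' @param W_self,W_neigh weight matrices (d_in x d_out, d_other x d_out).
#' @return The updated n x d_out feature matrix (entrywise >= 0).
#' @export
sage_layer <- function(H_self, H_other, A_norm, W_self, W_neigh) {
  pmax(H_self %*% W_self + A_norm %*% (H_other %*% W_neigh), 0)
}

#' Glorot-uniform weight matrix
#' @param nr,nc dimensions.
#' @return nr x nc matrix drawn from U(-l, l), l = sqrt(6 / (nr + nc)).
#' @keywords internal
glorot <- function(nr, nc) {
  l <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -l, l), nr, nc)
}

#' Initialize all learnable parameters
#'
#' @param G,N numbers of genes and samples (layer-1 input widths).
#' @param hidden_dim embedding width d of the SAGE layers and the
#'   cross-attention outputs.
#' @param attention_dim inner width dk of the Q/K/V projections.
#' @param proj_dim width k of the final linear projections fed to the cosine
#'   decoder.
#' @param n_layers 1 or 2 SAGE layers.
#' @param use_bwfa include the bidirectional cross-attention parameters.
#' @param share_qkv share one Q/K/V projection set across the two attention
#'   directions instead of direction-specific sets.
#' @param seed integer RNG seed.
#' @return A named list of parameter matrices (class `driver_params`).
#' @export
init_params <- function(G, N, hidden_dim = 64, attention_dim = 64,
                        proj_dim = 64, n_layers = 2, use_bwfa = TRUE,
                        share_qkv = FALSE, seed = 1) {
  stopifnot(n_layers %in% c(1, 2))
  set.seed(seed)
  d <- hidden_dim; dk <- attention_dim; k <- proj_dim
  p <- list()
  # layer 1: gene nodes see N-dim own features and G-dim neighbor features
  p$sage <- list(list(Wg_self = glorot(N, d), Wg_neigh = glorot(G, d),
                      Ws_self = glorot(G, d), Ws_neigh = glorot(N, d)))
  if (n_layers == 2) {
    p$sage[[2]] <- list(Wg_self = glorot(d, d), Wg_neigh = glorot(d, d),
                        Ws_self = glorot(d, d), Ws_neigh = glorot(d, d))
  }
  if (use_bwfa) {
    p$bwfa <- list(
      g = list(Wq = glorot(d, dk), Wk = glorot(d, dk), Wv = glorot(d, dk),
               Wp = glorot(dk, d), b = rep(0, d)),
      s = list(Wq = glorot(d, dk), Wk = glorot(d, dk), Wv = glorot(d, dk),
               Wp = glorot(dk, d), b = rep(0, d)))
    if (share_qkv) {
      p$bwfa$s$Wq <- p$bwfa$g$Wq
      p$bwfa$s$Wk <- p$bwfa$g$Wk
      p$bwfa$s$Wv <- p$bwfa$g$Wv
    }
  }
  p$W0 <- glorot(d, k)
  p$W1 <- glorot(d, k)
  p$config <- list(hidden_dim = d, attention_dim = dk, proj_dim = k,
                   n_layers = n_layers, use_bwfa = use_bwfa,
                   share_qkv = share_qkv, seed = seed)
  class(p) <- "driver_params"
  p
}

#' Aggregation matrices for the bipartite graph
#'
#' Builds the row-normalized gene-to-sample and sample-to-gene aggregation
#' matrices from the dataset, optionally after zeroing held-out sample
#' columns (so held-out samples contribute no label information) and after
#' fixed-fan-out neighbor sampling.
#'
#' @param dataset a `cohort_dataset`.
#' @param adjacency_source `"association"` uses the driver-restricted
#'   association matrix A; `"mutation"` uses the full mutation matrix Xg.
#' @param mask_samples sample identifiers whose adjacency columns are zeroed.
#' @param sampling_size optional fan-out cap per node (`NULL` = dense).
#' @param seed seed for neighbor sampling.
#' @return List with `An_g` (G x N) and `An_s` (N x G), nonzero rows sum to 1.
#' @export
aggregation_matrices <- function(dataset, adjacency_source = c("association", "mutation"),
                                 mask_samples = NULL, sampling_size = NULL,
                                 seed = 1) {
  adjacency_source <- match.arg(adjacency_source)
  A <- if (adjacency_source == "association") dataset$A else dataset$Xg
  if (!is.null(mask_samples)) {
    A[, dataset$samples %in% mask_samples] <- 0
  }
  Ag <- A
  As <- t(A)
  if (!is.null(sampling_size)) {
    Ag <- sample_neighbors(Ag, sampling_size, seed = seed)
    As <- sample_neighbors(As, sampling_size, seed = seed + 1L)
  }
  list(An_g = row_normalize(Ag), An_s = row_normalize(As))
}

#' Encode gene and sample nodes with the two-layer bipartite GraphSAGE
#'
#' Applies [sage_layer()] to both node types per layer: genes aggregate from
#' sample nodes, samples aggregate from gene nodes, both sides updated from
#' the previous layer's representations.
#'
#' @param dataset a `cohort_dataset` providing the initial features
#'   (`Xg` for genes, `Xs` for samples).
#' @param params a `driver_params` from [init_params()].
#' @param agg aggregation matrices from [aggregation_matrices()].
#' @return List with `Hg` (G x d) and `Hs` (N x d) final embeddings.
#' @export
encode <- function(dataset, params, agg) {
  Hg <- dataset$Xg
  Hs <- dataset$Xs
  for (layer in params$sage) {
    Hg_new <- sage_layer(Hg, Hs, agg$An_g, layer$Wg_self, layer$Wg_neigh)
    Hs_new <- sage_layer(Hs, Hg, agg$An_s, layer$Ws_self, layer$Ws_neigh)
    Hg <- Hg_new
    Hs <- Hs_new
  }
  list(Hg = Hg, Hs = Hs)
}
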