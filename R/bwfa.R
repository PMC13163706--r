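#' Scaled dot-product attention weights
#'
#' Softmax over each row of `Q %*% t(K) / sqrt(dk)`. Computed with the usual
#' per-row max subtraction for numerical stability; every row of the result
#' sums to 1.
#'
#' @param Q query matrix (n x dk).
#' @param K key matrix (m x dk).
#' @param dk positive scaling dimension (normally `ncol(Q)`).
#' @return Row-stochastic n x m attention matrix.
#' @export
attention_scores <- function(Q, K, dk = ncol(Q)) {
  stopifnot(dk > 0, ncol(Q) == ncol(K))
  logits <- tcrossprod(Q, K) / sqrt(dk)
  softmax_rows(logits)
}

#' Row-wise softmax
#' @param logits numeric matrix.
#' @return Matrix of the same shape with rows summing to 1.
#' @keywords internal
softmax_rows <- function(logits) {
  shifted <- exp(logits - apply(logits, 1, max))
  shifted / rowSums(shifted)
}

#' Bidirectional weighted feature aggregation (cross-attention)
#'
#' Re-aggregates the encoder embeddings with a single-head scaled dot-product
#' cross-attention in both directions: gene representations query the sample
#' representations (genes re-weight samples by learned relevance) and vice
#' versa. Each direction projects queries/keys/values linearly (no bias),
#' takes the attention-weighted sum of values, and applies an output
#' projection with bias followed by ReLU.
#'
#' @param G gene embeddings (G x d), normally the encoder output `Hg`.
#' @param S sample embeddings (N x d), normally the encoder output `Hs`.
#' @param bwfa the `bwfa` component of a `driver_params`: per-direction lists
#'   `g` and `s` holding `Wq`, `Wk`, `Wv` (d x dk), `Wp` (dk x d), `b` (d).
#' @return List with `Ghat` (G x d), `Shat` (N x d), and the attention
#'   matrices `E_gs` (G x N) and `E_sg` (N x G).
#' @export
bwfa_forward <- function(G, S, bwfa) {
  dk <- ncol(bwfa$g$Wq)
  Qg <- G %*% bwfa$g$Wq
  Ks <- S %*% bwfa$g$Wk
  Vs <- S %*% bwfa$g$Wv
  E_gs <- attention_scores(Qg, Ks, dk)
  Gp <- E_gs %*% Vs
  Ghat <- pmax(sweep(Gp %*% bwfa$g$Wp, 2, bwfa$g$b, `+`), 0)

  Qs <- S %*% bwfa$s$Wq
  Kg <- G %*% bwfa$s$Wk
  Vg <- G %*% bwfa$s$Wv
  E_sg <- attention_scores(Qs, Kg, dk)
  Sp <- E_sg %*% Vg
  Shat <- pmax(sweep(Sp %*% bwfa$s$Wp, 2, bwfa$s$b, `+`), 0)

  list(Ghat = Ghat, Shat = Shat, E_gs = E_gs, E_sg = E_sg)
}
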