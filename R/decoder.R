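#' Final linear projections before the decoder
#'
#' Plain linear maps (no activation) taking the aggregated gene and sample
#' representations to the common decoding space.
#'
#' @param Ghat,Shat aggregated gene (G x d) and sample (N x d) matrices.
#' @param W0,W1 projection weights (d x k).
#' @return List with `Hg` (G x k) and `Hs` (N x k).
#' @export
project_embeddings <- function(Ghat, Shat, W0, W1) {
  list(Hg = Ghat %*% W0, Hs = Shat %*% W1)
}

#' Decode gene-sample driver probabilities by cosine similarity
#'
#' `P[i, j] = (cos(hg_i, hs_j) + 1) / 2`, mapping cosine similarity in
#' \[-1, 1\] onto a probability in \[0, 1\]. A zero-norm embedding row has
#' cosine defined as 0, giving probability 0.5.
#'
#' @param Hg gene embeddings (G x k).
#' @param Hs sample embeddings (N x k).
#' @return G x N matrix of probabilities in \[0, 1\].
#' @export
cosine_probability <- function(Hg, Hs) {
  if (!all(is.finite(Hg)) || !all(is.finite(Hs))) stop("non-finite embeddings")
  ng <- sqrt(rowSums(Hg^2))
  ns <- sqrt(rowSums(Hs^2))
  Gn <- Hg / ifelse(ng > 0, ng, 1)
  Sn <- Hs / ifelse(ns > 0, ns, 1)
  C <- tcrossprod(Gn, Sn)
  C <- pmin(pmax(C, -1), 1)
  (C + 1) / 2
}

#' Weighted binary cross-entropy over a training mask
#'
#' `L = -(1/|M|) * sum_{(i,j) in M} [ beta * A * log(P) + (1-A) * log(1-P) ]`
#' where M is the set of masked-in gene-sample pairs and `beta` up-weights the
#' scarce positive class. Probabilities are clipped into
#' `[eps, 1 - eps]` (eps = 1e-7) to keep the logs finite.
#'
#' @param P predicted probability matrix in \[0, 1\].
#' @param A binary ground-truth matrix of the same shape.
#' @param mask logical/0-1 matrix selecting the training pairs; must select at
#'   least one entry.
#' @param beta positive weight on the positive-class term (`beta = 1` recovers
#'   plain BCE).
#' @param eps clipping constant.
#' @return Scalar loss.
#' @export
weighted_bce <- function(P, A, mask, beta = 1, eps = 1e-7) {
  mask <- mask != 0
  if (!any(mask)) stop("empty training mask")
  if (beta <= 0) stop("beta must be positive")
  p <- pmin(pmax(P[mask], eps), 1 - eps)
  a <- A[mask]
  -mean(beta * a * log(p) + (1 - a) * log(1 - p))
}

#' Gradient of the weighted BCE with respect to the probabilities
#'
#' Returns dL/dP entrywise (zero outside the mask and where the clip is
#' active), matching [weighted_bce()].
#'
#' @inheritParams weighted_bce
#' @return Matrix of the same shape as `P`.
#' @export
weighted_bce_grad <- function(P, A, mask, beta = 1, eps = 1e-7) {
  mask <- mask != 0
  if (!any(mask)) stop("empty training mask")
  G <- array(0, dim = dim(P))
  inside <- mask & P > eps & P < 1 - eps
  G[inside] <- -(beta * A[inside] / P[inside] -
                   (1 - A[inside]) / (1 - P[inside])) / sum(mask)
  G
}

#' Default positive-class weight for a masked dataset
#'
#' The ratio of negative to positive entries inside the training mask — the
#' standard imbalance heuristic. Falls back to 1 (with a warning) when the
#' mask contains no positives.
#'
#' @param A binary label matrix.
#' @param mask logical/0-1 mask.
#' @return Positive scalar.
#' @export
default_beta <- function(A, mask) {
  mask <- mask != 0
  pos <- sum(A[mask] == 1)
  neg <- sum(A[mask] == 0)
  if (pos == 0) {
    warning("no positive labels inside the training mask; beta set to 1")
    return(1)
  }
  max(1, neg / pos)
}
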