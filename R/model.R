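# Full model: bipartite GraphSAGE encoder -> bidirectional cross-attention ->
# linear projections -> cosine decoder. Forward keeps every intermediate so
# the analytic reverse pass (verified against finite differences in the test
# suite) can run without recomputation.

model_forward <- function(dataset, params, agg, cache = FALSE) {
  cc <- params$config
  Hg <- dataset$Xg
  Hs <- dataset$Xs
  layers <- list()
  for (layer in params$sage) {
    Zg <- Hg %*% layer$Wg_self + agg$An_g %*% (Hs %*% layer$Wg_neigh)
    Zs <- Hs %*% layer$Ws_self + agg$An_s %*% (Hg %*% layer$Ws_neigh)
    layers[[length(layers) + 1L]] <- list(Hg_in = Hg, Hs_in = Hs, Zg = Zg, Zs = Zs)
    Hg <- pmax(Zg, 0)
    Hs <- pmax(Zs, 0)
  }
  if (cc$use_bwfa) {
    bw <- bwfa_forward_cache(Hg, Hs, params$bwfa)
    Ghat <- bw$Ghat
    Shat <- bw$Shat
  } else {
    bw <- NULL
    Ghat <- Hg
    Shat <- Hs
  }
  Pg <- Ghat %*% params$W0
  Ps <- Shat %*% params$W1
  ng <- sqrt(rowSums(Pg^2))
  ns <- sqrt(rowSums(Ps^2))
  Gn <- Pg / ifelse(ng > 0, ng, 1)
  Sn <- Ps / ifelse(ns > 0, ns, 1)
  C <- pmin(pmax(tcrossprod(Gn, Sn), -1), 1)
  P <- (C + 1) / 2
  dimnames(P) <- list(dataset$genes, dataset$samples)
  if (!cache) return(P)
  list(P = P, C = C, Gn = Gn, Sn = Sn, ng = ng, ns = ns, Pg = Pg, Ps = Ps,
       Ghat = Ghat, Shat = Shat, Hg = Hg, Hs = Hs, bw = bw, layers = layers)
}

# bwfa_forward plus the intermediates needed by the reverse pass
bwfa_forward_cache <- function(G, S, bwfa) {
  dk <- ncol(bwfa$g$Wq)
  Qg <- G %*% bwfa$g$Wq; Ks <- S %*% bwfa$g$Wk; Vs <- S %*% bwfa$g$Wv
  E_gs <- softmax_rows(tcrossprod(Qg, Ks) / sqrt(dk))
  Gp <- E_gs %*% Vs
  Zg <- sweep(Gp %*% bwfa$g$Wp, 2, bwfa$g$b, `+`)
  Qs <- S %*% bwfa$s$Wq; Kg <- G %*% bwfa$s$Wk; Vg <- G %*% bwfa$s$Wv
  E_sg <- softmax_rows(tcrossprod(Qs, Kg) / sqrt(dk))
  Sp <- E_sg %*% Vg
  Zs <- sweep(Sp %*% bwfa$s$Wp, 2, bwfa$s$b, `+`)
  list(Ghat = pmax(Zg, 0), Shat = pmax(Zs, 0), dk = dk,
       Qg = Qg, Ks = Ks, Vs = Vs, E_gs = E_gs, Gp = Gp, Zg = Zg,
       Qs = Qs, Kg = Kg, Vg = Vg, E_sg = E_sg, Sp = Sp, Zs = Zs)
}

softmax_backward <- function(E, dE) E * (dE - rowSums(dE * E))

model_backward <- function(dataset, params, agg, fw, dP) {
  cc <- params$config
  g <- list()
  dC <- dP / 2
  # cosine: y = x/|x|; dx = (dy - y * (y . dy)) / |x|, zero-norm rows get 0
  dGn <- dC %*% fw$Sn
  dSn <- crossprod(dC, fw$Gn)
  dPg <- (dGn - fw$Gn * rowSums(dGn * fw$Gn)) / ifelse(fw$ng > 0, fw$ng, 1)
  dPs <- (dSn - fw$Sn * rowSums(dSn * fw$Sn)) / ifelse(fw$ns > 0, fw$ns, 1)
  dPg[fw$ng == 0, ] <- 0
  dPs[fw$ns == 0, ] <- 0
  g$W0 <- crossprod(fw$Ghat, dPg)
  g$W1 <- crossprod(fw$Shat, dPs)
  dGhat <- tcrossprod(dPg, params$W0)
  dShat <- tcrossprod(dPs, params$W1)

  if (cc$use_bwfa) {
    bw <- fw$bw
    s <- sqrt(bw$dk)
    dG <- matrix(0, nrow(fw$Hg), ncol(fw$Hg))
    dS <- matrix(0, nrow(fw$Hs), ncol(fw$Hs))
    # gene direction
    dZg <- dGhat * (bw$Zg > 0)
    gb_g <- list(b = colSums(dZg), Wp = crossprod(bw$Gp, dZg))
    dGp <- tcrossprod(dZg, params$bwfa$g$Wp)
    dE <- tcrossprod(dGp, bw$Vs)
    dVs <- crossprod(bw$E_gs, dGp)
    dL <- softmax_backward(bw$E_gs, dE)
    dQg <- dL %*% bw$Ks / s
    dKs <- crossprod(dL, bw$Qg) / s
    gb_g$Wq <- crossprod(fw$Hg, dQg)
    gb_g$Wk <- crossprod(fw$Hs, dKs)
    gb_g$Wv <- crossprod(fw$Hs, dVs)
    dG <- dG + tcrossprod(dQg, params$bwfa$g$Wq)
    dS <- dS + tcrossprod(dKs, params$bwfa$g$Wk) + tcrossprod(dVs, params$bwfa$g$Wv)
    # sample direction
    dZs <- dShat * (bw$Zs > 0)
    gb_s <- list(b = colSums(dZs), Wp = crossprod(bw$Sp, dZs))
    dSp <- tcrossprod(dZs, params$bwfa$s$Wp)
    dE <- tcrossprod(dSp, bw$Vg)
    dVg <- crossprod(bw$E_sg, dSp)
    dL <- softmax_backward(bw$E_sg, dE)
    dQs <- dL %*% bw$Kg / s
    dKg <- crossprod(dL, bw$Qs) / s
    gb_s$Wq <- crossprod(fw$Hs, dQs)
    gb_s$Wk <- crossprod(fw$Hg, dKg)
    gb_s$Wv <- crossprod(fw$Hg, dVg)
    dS <- dS + tcrossprod(dQs, params$bwfa$s$Wq)
    dG <- dG + tcrossprod(dKg, params$bwfa$s$Wk) + tcrossprod(dVg, params$bwfa$s$Wv)
    if (cc$share_qkv) {
      gb_g$Wq <- gb_g$Wq + gb_s$Wq
      gb_g$Wk <- gb_g$Wk + gb_s$Wk
      gb_g$Wv <- gb_g$Wv + gb_s$Wv
      gb_s$Wq <- gb_g$Wq; gb_s$Wk <- gb_g$Wk; gb_s$Wv <- gb_g$Wv
    }
    g$bwfa <- list(g = gb_g, s = gb_s)
    dHg <- dG
    dHs <- dS
  } else {
    dHg <- dGhat
    dHs <- dShat
  }

  g$sage <- vector("list", length(params$sage))
  for (l in rev(seq_along(params$sage))) {
    layer <- params$sage[[l]]
    cachel <- fw$layers[[l]]
    dZg <- dHg * (cachel$Zg > 0)
    dZs <- dHs * (cachel$Zs > 0)
    Tg <- crossprod(agg$An_g, dZg)   # N x d
    Ts <- crossprod(agg$An_s, dZs)   # G x d
    g$sage[[l]] <- list(
      Wg_self = crossprod(cachel$Hg_in, dZg),
      Wg_neigh = crossprod(cachel$Hs_in, Tg),
      Ws_self = crossprod(cachel$Hs_in, dZs),
      Ws_neigh = crossprod(cachel$Hg_in, Ts))
    if (l > 1) {
      dHg <- tcrossprod(dZg, layer$Wg_self) + tcrossprod(Ts, layer$Ws_neigh)
      dHs <- tcrossprod(dZs, layer$Ws_self) + tcrossprod(Tg, layer$Wg_neigh)
    }
  }
  g
}

# recursive Adam over the nested parameter/gradient lists
adam_init <- function(p) rapply(p, function(x) x * 0, how = "replace")

adam_step <- function(p, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  walk(p, g, m, v)
}

#' Fit the driver gene-sample model to a cohort
#'
#' Trains the full model end-to-end on the bipartite gene-sample graph:
#' a GraphSAGE encoder (1 or 2 layers), optionally the bidirectional
#' cross-attention aggregator, linear projections, and a cosine-similarity
#' decoder, optimized with Adam against the weighted binary cross-entropy on
#' the training-sample columns of the driver association matrix. Held-out
#' sample columns are zeroed in the aggregation adjacency during both training
#' and inference, so no label information from held-out samples is used, yet
#' the returned score matrix covers every sample.
#'
#' @param dataset a `cohort_dataset` from [build_cohort()]/[build_dataset()].
#' @param train_samples sample identifiers forming the training fold
#'   (default: all samples).
#' @param hidden_dim embedding width d of the encoder and aggregator.
#' @param attention_dim Q/K/V inner width dk.
#' @param proj_dim decoder projection width k.
#' @param n_layers number of GraphSAGE layers (1 or 2).
#' @param use_bwfa enable the bidirectional cross-attention aggregator; when
#'   off, encoder embeddings feed the projections directly.
#' @param share_qkv tie the Q/K/V projections across the two attention
#'   directions.
#' @param adjacency_source `"association"` (driver-restricted matrix A, the
#'   reference wiring) or `"mutation"` (full mutation matrix).
#' @param sampling_size optional fixed neighbor fan-out (e.g. one of
#'   5, 10, 15, 20, 25, 30); resampled every epoch; `NULL` uses the dense
#'   normalized adjacency.
#' @param beta positive-class weight of the loss; `NULL` uses the
#'   negatives-to-positives ratio inside the training mask ([default_beta()]).
#' @param epochs,learning_rate Adam schedule.
#' @param seed integer seed governing initialization and neighbor sampling;
#'   runs are deterministic given the seed.
#' @param verbose print the loss every 50 epochs.
#' @return An object of class `driver_fit` with components `params`
#'   (trained weights), `scores` (G x N probability matrix over all samples),
#'   `loss` (per-epoch trajectory), `beta`, `train_samples`, `genes`,
#'   `samples`, `known_drivers`, and `config`.
#' @seealso [predict.driver_fit()], [sample_rankings()], [driver_pipeline()]
#' @export
driver_fit <- function(dataset, train_samples = NULL, hidden_dim = 64,
                       attention_dim = 64, proj_dim = 64, n_layers = 2,
                       use_bwfa = TRUE, share_qkv = FALSE,
                       adjacency_source = "association", sampling_size = NULL,
                       beta = NULL, epochs = 200, learning_rate = 1e-3,
                       seed = 1, verbose = FALSE) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (is.null(train_samples)) train_samples <- dataset$samples
  if (!all(train_samples %in% dataset$samples)) stop("unknown training sample id")
  G <- length(dataset$genes)
  N <- length(dataset$samples)
  mask <- matrix(FALSE, G, N, dimnames = list(dataset$genes, dataset$samples))
  mask[, dataset$samples %in% train_samples] <- TRUE
  if (is.null(beta)) beta <- default_beta(dataset$A, mask)
  held_out <- setdiff(dataset$samples, train_samples)

  params <- init_params(G, N, hidden_dim = hidden_dim,
                        attention_dim = attention_dim, proj_dim = proj_dim,
                        n_layers = n_layers, use_bwfa = use_bwfa,
                        share_qkv = share_qkv, seed = seed)
  trainable <- params[intersect(c("sage", "bwfa", "W0", "W1"), names(params))]
  m <- adam_init(trainable)
  v <- adam_init(trainable)

  dense_agg <- aggregation_matrices(dataset, adjacency_source,
                                    mask_samples = held_out)
  loss_hist <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    agg <- if (is.null(sampling_size)) dense_agg else
      aggregation_matrices(dataset, adjacency_source, mask_samples = held_out,
                           sampling_size = sampling_size,
                           seed = (seed + 2L * epoch) %% .Machine$integer.max)
    fw <- model_forward(dataset, params, agg, cache = TRUE)
    loss <- weighted_bce(fw$P, dataset$A, mask, beta = beta)
    if (!is.finite(loss)) {
      stop(sprintf("training diverged at epoch %d (non-finite loss)", epoch))
    }
    loss_hist[epoch] <- loss
    dP <- weighted_bce_grad(fw$P, dataset$A, mask, beta = beta)
    grads <- model_backward(dataset, params, agg, fw, dP)
    upd <- adam_step(trainable, grads[names(trainable)], m, v,
                     lr = learning_rate, t = epoch)
    trainable <- upd$p; m <- upd$m; v <- upd$v
    params[names(trainable)] <- trainable
    if (verbose && (epoch %% 50 == 0 || epoch == 1)) {
      message(sprintf("epoch %4d  loss %.5f", epoch, loss))
    }
  }
  scores <- model_forward(dataset, params, dense_agg)
  structure(list(params = params, scores = scores, loss = loss_hist,
                 beta = beta, train_samples = train_samples,
                 genes = dataset$genes, samples = dataset$samples,
                 known_drivers = dataset$known_drivers, A = dataset$A,
                 mask = mask,
                 config = c(params$config,
                            list(adjacency_source = adjacency_source,
                                 sampling_size = sampling_size,
                                 epochs = epochs,
                                 learning_rate = learning_rate))),
            class = "driver_fit")
}

#' @export
print.driver_fit <- function(x, ...) {
  cat(sprintf(paste0("Bipartite gene-sample driver model\n",
                     "  %d genes x %d samples (%d training samples)\n",
                     "  layers: %d, cross-attention: %s, beta: %.2f\n",
                     "  loss: %.5f -> %.5f over %d epochs\n"),
              length(x$genes), length(x$samples), length(x$train_samples),
              x$config$n_layers, ifelse(x$config$use_bwfa, "on", "off"),
              x$beta, x$loss[1], x$loss[length(x$loss)], length(x$loss)))
  invisible(x)
}

#' @export
summary.driver_fit <- function(object, ...) {
  pos <- object$A == 1 & object$mask
  neg <- object$A == 0 & object$mask
  out <- list(
    n_genes = length(object$genes), n_samples = length(object$samples),
    n_train = length(object$train_samples), beta = object$beta,
    loss_initial = object$loss[1], loss_final = object$loss[length(object$loss)],
    mean_score_positive = mean(object$scores[pos]),
    mean_score_negative = mean(object$scores[neg]),
    config = object$config)
  class(out) <- "summary.driver_fit"
  out
}

#' @export
print.summary.driver_fit <- function(x, ...) {
  cat(sprintf(paste0("driver_fit summary\n",
                     "  %d genes x %d samples (%d training)\n",
                     "  beta = %.2f; loss %.5f -> %.5f\n",
                     "  mean score on positive training pairs: %.4f\n",
                     "  mean score on negative training pairs: %.4f\n"),
              x$n_genes, x$n_samples, x$n_train, x$beta,
              x$loss_initial, x$loss_final,
              x$mean_score_positive, x$mean_score_negative))
  invisible(x)
}

#' @export
coef.driver_fit <- function(object, ...) object$params

#' Predict driver probabilities
#'
#' Returns the gene-sample driver probability matrix. With a new
#' `cohort_dataset` of identical dimensions and gene/sample layout the trained
#' weights are applied to it; otherwise the fitted scores are returned.
#'
#' @param object a `driver_fit`.
#' @param dataset optional `cohort_dataset` to score.
#' @param ... unused.
#' @return G x N matrix of probabilities in \[0, 1\].
#' @export
predict.driver_fit <- function(object, dataset = NULL, ...) {
  if (is.null(dataset)) return(object$scores)
  stopifnot(inherits(dataset, "cohort_dataset"),
            length(dataset$genes) == length(object$genes),
            length(dataset$samples) == length(object$samples))
  agg <- aggregation_matrices(dataset, object$config$adjacency_source,
                              mask_samples = setdiff(object$samples,
                                                     object$train_samples))
  model_forward(dataset, object$params, agg)
}

#' @export
fitted.driver_fit <- function(object, ...) object$scores

#' @export
residuals.driver_fit <- function(object, ...) object$A - object$scores

#' @export
plot.driver_fit <- function(x, ...) {
  graphics::plot(seq_along(x$loss), x$loss, type = "l", xlab = "epoch",
                 ylab = "weighted BCE", main = "training loss", ...)
  invisible(x)
}
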