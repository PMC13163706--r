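test_that("full-model analytic gradients match finite differences", {
  ds <- small_dataset(seed = 3)
  G <- length(ds$genes); N <- length(ds$samples)
  p <- init_params(G, N, hidden_dim = 5, attention_dim = 4, proj_dim = 3,
                   seed = 7)
  agg <- aggregation_matrices(ds)
  mask <- matrix(TRUE, G, N)
  beta <- 2.5
  fw <- model_forward(ds, p, agg, cache = TRUE)
  dP <- weighted_bce_grad(fw$P, ds$A, mask, beta = beta)
  gr <- model_backward(ds, p, agg, fw, dP)

  lossfun <- function(pp) {
    weighted_bce(model_forward(ds, pp, agg), ds$A, mask, beta = beta)
  }
  check_block <- function(get, set, gmat, n = 4) {
    set.seed(101)
    for (idx in sample(length(gmat), n)) {
      eps <- 1e-6
      fd <- (lossfun(set(p, idx, eps)) - lossfun(set(p, idx, -eps))) / (2 * eps)
      expect_equal(gmat[idx], fd, tolerance = 1e-4)
    }
  }
  check_block(NULL, function(p, i, e) { p$W0[i] <- p$W0[i] + e; p }, gr$W0)
  check_block(NULL, function(p, i, e) { p$W1[i] <- p$W1[i] + e; p }, gr$W1)
  check_block(NULL, function(p, i, e) { p$bwfa$g$Wq[i] <- p$bwfa$g$Wq[i] + e; p },
              gr$bwfa$g$Wq)
  check_block(NULL, function(p, i, e) { p$bwfa$s$Wv[i] <- p$bwfa$s$Wv[i] + e; p },
              gr$bwfa$s$Wv)
  check_block(NULL, function(p, i, e) { p$bwfa$g$b[i] <- p$bwfa$g$b[i] + e; p },
              gr$bwfa$g$b, n = 2)
  check_block(NULL, function(p, i, e) {
    p$sage[[1]]$Wg_neigh[i] <- p$sage[[1]]$Wg_neigh[i] + e; p
  }, gr$sage[[1]]$Wg_neigh)
  check_block(NULL, function(p, i, e) {
    p$sage[[2]]$Ws_self[i] <- p$sage[[2]]$Ws_self[i] + e; p
  }, gr$sage[[2]]$Ws_self)
})

test_that("training reduces the loss, is seed-deterministic, and scores stay in [0,1]", {
  ds <- small_dataset(seed = 3)
  fit <- driver_fit(ds, hidden_dim = 12, attention_dim = 12, proj_dim = 8,
                    epochs = 60, seed = 5)
  expect_lt(fit$loss[length(fit$loss)], fit$loss[1])
  expect_true(all(fit$scores >= 0 & fit$scores <= 1))
  fit2 <- driver_fit(ds, hidden_dim = 12, attention_dim = 12, proj_dim = 8,
                     epochs = 60, seed = 5)
  expect_identical(fit$loss, fit2$loss)
  expect_identical(fit$scores, fit2$scores)

  # the S3 surface
  expect_output(print(fit), "Bipartite gene-sample driver model")
  s <- summary(fit)
  expect_gt(s$mean_score_positive, s$mean_score_negative)
  expect_type(coef(fit), "list")
  expect_identical(predict(fit), fit$scores)
  expect_identical(fitted(fit), fit$scores)
  expect_equal(dim(residuals(fit)), dim(fit$scores))
})

test_that("large positive-class weight pushes positive training scores toward 1", {
  ds <- small_dataset(seed = 12)
  lo <- driver_fit(ds, hidden_dim = 8, attention_dim = 8, proj_dim = 6,
                   epochs = 120, beta = 1, seed = 2)
  hi <- driver_fit(ds, hidden_dim = 8, attention_dim = 8, proj_dim = 6,
                   epochs = 120, beta = 200, seed = 2)
  pos <- ds$A == 1
  expect_gt(mean(hi$scores[pos]), mean(lo$scores[pos]))
  expect_gt(mean(hi$scores[pos]), 0.9)
})

test_that("held-out samples receive no label information but are still scored", {
  ds <- small_dataset(seed = 3)
  test <- ds$samples[1:3]
  train <- setdiff(ds$samples, test)
  fit <- driver_fit(ds, train_samples = train, hidden_dim = 8,
                    attention_dim = 8, proj_dim = 6, epochs = 40, seed = 1)
  expect_false(any(is.na(fit$scores[, test])))
  # zeroing the held-out columns of A entirely must not change anything:
  ds2 <- ds
  ds2$A[, ds$samples %in% test] <- 0
  fit2 <- driver_fit(ds2, train_samples = train, hidden_dim = 8,
                     attention_dim = 8, proj_dim = 6, epochs = 40, seed = 1)
  expect_identical(fit$scores, fit2$scores)
  expect_error(driver_fit(ds, train_samples = "nope"), "unknown")
})

test_that("single-layer and attention-free configurations train", {
  ds <- small_dataset(seed = 3)
  f1 <- driver_fit(ds, n_layers = 1, use_bwfa = FALSE, hidden_dim = 8,
                   attention_dim = 8, proj_dim = 6, epochs = 40, seed = 4)
  expect_lt(f1$loss[40], f1$loss[1])
  expect_null(f1$params$bwfa)
  expect_length(f1$params$sage, 1)
  f2 <- driver_fit(ds, share_qkv = TRUE, hidden_dim = 8, attention_dim = 8,
                   proj_dim = 6, epochs = 40, seed = 4)
  expect_identical(f2$params$bwfa$g$Wq, f2$params$bwfa$s$Wq)
  expect_lt(f2$loss[40], f2$loss[1])
})

test_that("per-epoch neighbor sampling trains deterministically", {
  ds <- small_dataset(seed = 3)
  a <- driver_fit(ds, sampling_size = 5, hidden_dim = 8, attention_dim = 8,
                  proj_dim = 6, epochs = 30, seed = 11)
  b <- driver_fit(ds, sampling_size = 5, hidden_dim = 8, attention_dim = 8,
                  proj_dim = 6, epochs = 30, seed = 11)
  expect_identical(a$loss, b$loss)
  expect_lt(a$loss[30], a$loss[1])
})
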