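test_that("per-sample candidate lists keep the ceiling of half the mutated genes", {
  genes <- sprintf("g%d", 1:6)
  samples <- c("s1", "s2", "s3")
  mut <- cbind(s1 = c(1, 1, 1, 1, 0, 0),
               s2 = c(1, 1, 1, 1, 1, 0),
               s3 = c(0, 0, 0, 0, 0, 0))
  rownames(mut) <- genes
  set.seed(8)
  scores <- matrix(runif(18), 6, 3, dimnames = list(genes, samples))
  rk <- sample_rankings(scores, mut)
  expect_equal(nrow(rk$s1), 2)  # 4 mutated -> 2 kept
  expect_equal(nrow(rk$s2), 3)  # 5 mutated -> ceiling(2.5) = 3
  expect_equal(nrow(rk$s3), 0)  # no mutations -> empty ranking
  # kept genes are the top-scoring mutated ones, in descending order
  expect_true(all(diff(rk$s2$score) <= 0))
  expect_true(all(rk$s1$gene %in% genes[mut[, "s1"] == 1]))

  # equal scores break ties by gene symbol
  scores2 <- scores; scores2[, "s1"] <- 0.5
  rk2 <- sample_rankings(scores2, mut)
  expect_equal(rk2$s1$gene, c("g1", "g2"))
})

test_that("rank weights follow the exponential decay law", {
  expect_equal(rank_weight(1, 0.7), 1)
  expect_equal(rank_weight(5, 0), 1)  # alpha 0 is unweighted voting
  expect_equal(rank_weight(2, 0.5), exp(-0.5))
  expect_equal(rank_weight(1:4, 1), exp(-(0:3)))
  expect_error(rank_weight(0, 1), "ranks start at 1")
})

test_that("EPV reproduces the hand-derived single-sample instance", {
  rk <- list(s1 = data.frame(gene = c("g1", "g2"), score = c(0.9, 0.4)))
  res <- epv_scores(rk, alpha = 0.5, universe = c("g1", "g2", "g3"))
  expect_equal(res$gene, c("g1", "g2", "g3"))
  expect_equal(res$score[1], 1)
  expect_equal(res$score[2], exp(-0.5) / (1 + exp(-0.5)), tolerance = 1e-12)
  expect_equal(res$score[2], 0.3775, tolerance = 1e-3)
  expect_equal(res$score[3], 0)
})

test_that("EPV matches the brute-force pairwise oracle on random instances", {
  set.seed(20)
  for (rep in 1:60) {
    G <- sample(2:20, 1)
    N <- sample(1:10, 1)
    alpha <- runif(1)
    rks <- random_rankings(G, N, seed = 1000 + rep)
    if (all(vapply(rks, nrow, integer(1)) == 0)) next
    universe <- sprintf("g%02d", seq_len(G))
    got <- epv_scores(rks, alpha = alpha, universe = universe)
    want <- epv_oracle(rks, alpha, universe)
    got <- got[order(got$gene), ]
    expect_equal(got$win, want$win, tolerance = 1e-12)
    expect_equal(got$loss, want$loss, tolerance = 1e-12)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("EPV bookkeeping invariants hold", {
  rks <- random_rankings(12, 6, seed = 77)
  res <- epv_scores(rks, alpha = 0.3, universe = sprintf("g%02d", 1:12))
  # every vote cast is someone's loss
  expect_equal(sum(res$win), sum(res$loss), tolerance = 1e-10)
  expect_true(all(res$score >= 0 & res$score <= 1))
  # a gene absent from every list never wins
  listed <- unique(unlist(lapply(rks, `[[`, "gene")))
  absent <- setdiff(res$gene, listed)
  expect_true(all(res$win[res$gene %in% absent] == 0))
  expect_true(all(res$score[res$gene %in% absent] == 0))

  # duplicating every sample doubles win/loss but leaves scores unchanged
  doubled <- epv_scores(c(rks, rks), alpha = 0.3,
                        universe = sprintf("g%02d", 1:12))
  expect_equal(doubled$win, 2 * res$win, tolerance = 1e-10)
  expect_equal(doubled$loss, 2 * res$loss, tolerance = 1e-10)
  expect_equal(doubled$gene, res$gene)
  expect_equal(doubled$score, res$score, tolerance = 1e-10)

  # a gene ranked first everywhere and present everywhere scores 1
  rks1 <- lapply(rks, function(r) {
    rbind(data.frame(gene = "g99", score = 2), r[r$gene != "g99", ])
  })
  top <- epv_scores(rks1, alpha = 0.3, universe = c(sprintf("g%02d", 1:12), "g99"))
  expect_equal(top$score[top$gene == "g99"], 1)
})

test_that("improving a gene's rank in one sample never lowers its EPV score", {
  set.seed(55)
  for (rep in 1:20) {
    rks <- random_rankings(10, 4, seed = 500 + rep)
    sizes <- vapply(rks, nrow, integer(1))
    cand <- which(sizes >= 2)
    if (length(cand) == 0) next
    s <- cand[1]
    g <- rks[[s]]$gene[2]
    alpha <- runif(1)
    universe <- sprintf("g%02d", 1:10)
    before <- epv_scores(rks, alpha = alpha, universe = universe)
    rks[[s]] <- rks[[s]][c(2, 1, seq_len(sizes[s])[-(1:2)]), ]
    after <- epv_scores(rks, alpha = alpha, universe = universe)
    expect_gte(after$score[after$gene == g], before$score[before$gene == g])
  }
})

test_that("Condorcet baseline agrees with unit-strength EPV ordering", {
  # one voter: the ranking is reproduced verbatim
  one <- list(s1 = data.frame(gene = c("a", "b", "c"), score = 3:1))
  expect_equal(condorcet_rank(one, universe = c("a", "b", "c"))$gene,
               c("a", "b", "c"))
  set.seed(42)
  for (rep in 1:40) {
    rks <- random_rankings(sample(3:12, 1), sample(2:6, 1), seed = 3000 + rep)
    if (all(vapply(rks, nrow, integer(1)) == 0)) next
    cond <- condorcet_rank(rks)
    epv0 <- epv_scores(rks, alpha = 0)
    expect_equal(cond$gene, epv0$gene)
    expect_equal(cond$win, epv0$win, tolerance = 1e-10)
    expect_equal(cond$score, epv0$score, tolerance = 1e-10)
  }
})

test_that("cyclic preferences resolve deterministically", {
  cyc <- list(
    s1 = data.frame(gene = c("a", "b", "c"), score = 3:1),
    s2 = data.frame(gene = c("b", "c", "a"), score = 3:1),
    s3 = data.frame(gene = c("c", "a", "b"), score = 3:1))
  r1 <- condorcet_rank(cyc)
  r2 <- condorcet_rank(cyc)
  expect_identical(r1, r2)
  # symmetric cycle: all tied, broken by gene symbol
  expect_equal(r1$gene, c("a", "b", "c"))
})

test_that("cancer-tag defaults for the decay rate", {
  expect_equal(default_alpha(), 0.5)
  expect_equal(default_alpha("BRCA"), 0.9)
  expect_equal(default_alpha("luad"), 0.3)
  expect_equal(default_alpha("prad"), 0.6)
  expect_equal(default_alpha("coad"), 0.5)
})
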