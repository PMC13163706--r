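test_that("PPI reader applies threshold, drops self-loops, dedups by max confidence", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t0.4", "A\tC\t0.5", "B\tC\t0.9",
               "TP53\tTP53\t0.99", "D\tE\t0.6", "E\tD\t0.8"), f)
  net <- read_ppi(f, min_confidence = 0.5)
  expect_equal(n_edges(net), 3)
  expect_false(any(net$edges$from == net$edges$to))
  de <- net$edges[net$edges$from == "D", ]
  expect_equal(de$confidence, 0.8)

  # strict threshold drops the boundary edge
  strict <- read_ppi(f, min_confidence = 0.5, strict_greater = TRUE)
  expect_equal(n_edges(strict), 2)

  # missing confidence column means confidence 1
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tC"), f2)
  expect_equal(read_ppi(f2, min_confidence = 0.9)$edges$confidence, c(1, 1))

  # malformed rows error
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t0.7", "loner"), f3)
  expect_error(read_ppi(f3), "fewer than two")
  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("A\tB\thigh", f4)
  expect_error(read_ppi(f4), "non-numeric")
})

test_that("edge count is monotone non-increasing in the confidence threshold", {
  f <- withr::local_tempfile(fileext = ".tsv")
  set.seed(7)
  writeLines(sprintf("N%02d\tN%02d\t%.3f", 1:30, 31:60, runif(30)), f)
  counts <- vapply(seq(0, 1, by = 0.1),
                   function(th) n_edges(read_ppi(f, min_confidence = th)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("z-scores match hand evaluation and handle constant rows", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  z <- compute_zscores(m)
  expect_equal(z["a", ], c(s1 = -1.2247, s2 = 0, s3 = 1.2247), tolerance = 1e-4)
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  # sample-sd convention shrinks |z|
  zs <- compute_zscores(m, sd_type = "sample")
  expect_equal(unname(zs["a", 1]), -1, tolerance = 1e-12)
  expect_error(compute_zscores(m[, 1, drop = FALSE]), ">= 2 samples")
  m[1, 1] <- NA
  expect_error(compute_zscores(m), "non-finite")
})

test_that("aberrance flag respects the >= 2 boundary and the two-sided switch", {
  z <- matrix(c(2, 1.999, -3, 0), 1, 4)
  expect_equal(as.numeric(flag_aberrant(z)), c(1, 0, 0, 0))
  expect_equal(as.numeric(flag_aberrant(z, two_sided = TRUE)), c(1, 0, 1, 0))
})

test_that("aberrance flags are invariant under per-gene affine rescaling", {
  set.seed(11)
  expr <- matrix(rnorm(20 * 8), 20, 8,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:8)))
  flags <- flag_aberrant(compute_zscores(expr))
  a <- runif(20, 0.5, 4)
  b <- rnorm(20, sd = 10)
  rescaled <- expr * a + b
  expect_equal(flag_aberrant(compute_zscores(rescaled)), flags)
})

test_that("mutated-gene filter enforces same-sample coupling", {
  genes <- c("g1", "g2", "g3")
  mut <- matrix(c(1, 0, 0, 0, 0, 0), 3, 2, dimnames = list(genes, c("s1", "s2")))
  ab <- matrix(0, 3, 2, dimnames = dimnames(mut))
  net <- ppi_network(data.frame(from = "g1", to = "g2"))

  ab["g2", "s1"] <- 1  # neighbor aberrant in the mutated sample
  expect_equal(filter_mutated_genes(mut, ab, net), "g1")

  ab["g2", ] <- c(0, 1)  # neighbor aberrant only in the other sample
  expect_equal(filter_mutated_genes(mut, ab, net), character())
  # ... but cohort-level coupling accepts it
  expect_equal(filter_mutated_genes(mut, ab, net, coupling = "cohort"), "g1")

  # an unmutated gene is never retained even with aberrant neighbors
  ab["g1", ] <- 1
  expect_false("g2" %in% filter_mutated_genes(mut, ab, net))
})

test_that("adding PPI edges never removes a retained gene", {
  set.seed(23)
  for (rep in 1:5) {
    co <- small_cohort(seed = rep)
    z <- compute_zscores(co$expr)
    ab <- flag_aberrant(z)
    base <- filter_mutated_genes(co$mut, ab, co$ppi)
    extra <- co$ppi$edges
    nodes <- rownames(co$mut)
    new_edges <- data.frame(from = sample(nodes, 15), to = sample(nodes, 15))
    bigger <- ppi_network(rbind(extra[, 1:2], new_edges))
    expect_true(all(base %in% filter_mutated_genes(co$mut, ab, bigger)))
  }
})

test_that("dataset assembly splits labels correctly and A <= Xg holds", {
  ds <- toy_dataset()
  # g1 is a known driver: its mutations become positive associations
  expect_equal(unname(ds$A["g1", ]), unname(ds$Xg["g1", ]))
  # g2 mutated but not a driver
  expect_equal(unname(ds$A["g2", ]), c(0, 0))
  expect_equal(unname(ds$Xg["g2", c("s1", "s2")]), c(1, 1))
  # Xs is the transposed expression
  expect_equal(ds$Xs["s2", "g3"], -2)
  expect_true(all(ds$A <= ds$Xg))
  expect_error(build_dataset(matrix(0, 2, 2), matrix(0, 2, 2),
                             character(), "g1"))
})

test_that("A <= Xg on random cohorts after full preprocessing", {
  for (s in 1:3) {
    ds <- small_dataset(seed = s + 10)
    expect_true(all(ds$A <= ds$Xg))
    expect_equal(rownames(ds$Xg), sort(rownames(ds$Xg)))
  }
})
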