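# Small in-code fixtures shared across test files.

# A dense small synthetic cohort whose preprocessing retains a usable gene set.
small_cohort <- function(seed = 3) {
  simulate_cohort(n_genes = 40, n_samples = 12, n_drivers = 6,
                  edge_prob = 0.2, seed = seed)
}

small_dataset <- function(seed = 3) {
  co <- small_cohort(seed)
  build_cohort(co$expr, co$mut, co$ppi, co$drivers, quiet = TRUE)
}

# A tiny hand-made dataset with fixed values (3 genes x 2 samples).
toy_dataset <- function() {
  genes <- c("g1", "g2", "g3")
  samples <- c("s1", "s2")
  mut <- matrix(c(1, 1, 0, 0, 1, 1), 3, 2, dimnames = list(genes, samples))
  expr <- matrix(c(0.5, -1, 2, 1.5, 0, -2), 3, 2, dimnames = list(genes, samples))
  build_dataset(expr, mut, retained = genes, known_drivers = c("g1"))
}

# Random per-sample rankings over a gene universe, for voting tests.
random_rankings <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  out <- lapply(seq_len(n_samples), function(s) {
    m <- sample(0:n_genes, 1)
    picked <- if (m > 0) sample(genes, m) else character()
    data.frame(gene = picked, score = sort(stats::runif(m), decreasing = TRUE),
               stringsAsFactors = FALSE)
  })
  names(out) <- sprintf("s%02d", seq_len(n_samples))
  out
}

# Brute-force EPV oracle: materializes every ordered pair x sample.
epv_oracle <- function(rankings, alpha, universe) {
  universe <- sort(unique(universe))
  U <- length(universe)
  win <- stats::setNames(numeric(U), universe)
  loss <- stats::setNames(numeric(U), universe)
  for (rk in rankings) {
    pos <- match(universe, rk$gene)
    for (i in seq_len(U)) for (j in seq_len(U)) {
      if (i == j || is.na(pos[i])) next
      if (is.na(pos[j]) || pos[i] < pos[j]) {
        w <- exp(-alpha * (pos[i] - 1))
        win[i] <- win[i] + w
        loss[j] <- loss[j] + w
      }
    }
  }
  tot <- win + loss
  data.frame(gene = universe, win = unname(win), loss = unname(loss),
             score = unname(ifelse(tot > 0, win / tot, 0)),
             stringsAsFactors = FALSE)
}
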