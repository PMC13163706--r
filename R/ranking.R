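#' Per-sample candidate driver rankings
#'
#' For each sample, restricts to the genes mutated in that sample, orders them
#' by predicted score descending (ties broken by gene symbol ascending), and
#' keeps the top `ceiling(keep_fraction * m)` of the m mutated genes as the
#' sample-specific candidate driver subset. Samples with no mutated gene get
#' an empty ranking.
#'
#' @param scores G x N gene-sample probability matrix with dimnames.
#' @param mut binary G x N mutation matrix sharing the same dimnames.
#' @param keep_fraction fraction of each sample's mutated genes kept.
#' @return Named list (one element per sample) of data frames with columns
#'   `gene` and `score`, ordered rank 1 first.
#' @export
sample_rankings <- function(scores, mut, keep_fraction = 0.5) {
  stopifnot(identical(dim(scores), dim(mut)),
            identical(rownames(scores), rownames(mut)),
            keep_fraction > 0, keep_fraction <= 1)
  out <- lapply(colnames(scores), function(s) {
    g <- rownames(mut)[mut[, s] == 1]
    if (length(g) == 0) {
      return(data.frame(gene = character(), score = numeric(),
                        stringsAsFactors = FALSE))
    }
    sc <- scores[g, s]
    ord <- order(-sc, g)
    keep <- seq_len(ceiling(keep_fraction * length(g)))
    data.frame(gene = g[ord][keep], score = unname(sc[ord][keep]),
               stringsAsFactors = FALSE)
  })
  names(out) <- colnames(scores)
  out
}

#' Exponential rank weight
#'
#' The voting strength of a gene at rank r (rank 1 = best):
#' `exp(-alpha * (r - 1))`. `alpha = 0` gives unweighted (unit-strength)
#' voting; larger `alpha` concentrates influence on the top of each list.
#'
#' @param r rank position(s), >= 1.
#' @param alpha nonnegative exponential decay rate.
#' @return Weight(s) in (0, 1\].
#' @export
rank_weight <- function(r, alpha) {
  if (any(r < 1)) stop("ranks start at 1")
  exp(-alpha * (r - 1))
}

#' Exponential Pairwise Voting over per-sample rankings
#'
#' Every ordered gene pair (gi, gj) is compared within every sample: gi beats
#' gj in a sample when gi appears in that sample's candidate list and either
#' outranks gj or gj is absent, contributing gi's rank weight
#' [rank_weight()] as voting strength. A gene's win strength sums the
#' strengths of its victories across all samples and opponents; its loss
#' strength sums the strengths of the victories against it. The final score is
#' `P = win / (win + loss)` (0 when the gene was never compared), and genes
#' are ranked by P descending, ties by win descending then symbol ascending.
#'
#' @param rankings list of per-sample rankings from [sample_rankings()].
#' @param alpha exponential decay rate of the rank weights.
#' @param universe gene identifiers eligible to vote/be voted on; default is
#'   every gene appearing in at least one candidate list. Supplying all
#'   retained genes instead enlarges the pool of absent opponents.
#' @return An object of class `epv_result`: data frame with columns `gene`,
#'   `win`, `loss`, `score`, ordered by the final ranking.
#' @export
epv_scores <- function(rankings, alpha = 0.5, universe = NULL) {
  lists <- rankings[vapply(rankings, nrow, integer(1)) > 0]
  if (length(lists) == 0) stop("no non-empty sample rankings")
  if (is.null(universe)) {
    universe <- unique(unlist(lapply(lists, `[[`, "gene")))
  }
  universe <- sort(unique(as.character(universe)))
  U <- length(universe)
  win <- stats::setNames(numeric(U), universe)
  loss <- stats::setNames(numeric(U), universe)
  for (rk in lists) {
    genes <- rk$gene
    r <- seq_along(genes)
    w <- rank_weight(r, alpha)
    # gi at rank r beats the (|list| - r) genes below it plus the
    # (U - |list|) universe genes absent from the list
    win[genes] <- win[genes] + w * (U - r)
    # a listed gene loses to every gene ranked above it
    loss[genes] <- loss[genes] + cumsum(c(0, w[-length(w)]))
    # an absent gene loses to every listed gene
    absent <- setdiff(universe, genes)
    loss[absent] <- loss[absent] + sum(w)
  }
  tot <- win + loss
  score <- ifelse(tot > 0, win / tot, 0)
  ord <- order(-score, -win, universe)
  structure(data.frame(gene = universe[ord], win = unname(win[ord]),
                       loss = unname(loss[ord]), score = unname(score[ord]),
                       stringsAsFactors = FALSE),
            class = c("epv_result", "data.frame"))
}

#' @export
print.epv_result <- function(x, n = 10, ...) {
  cat(sprintf("EPV ranking over %d genes (top %d shown)\n",
              nrow(x), min(n, nrow(x))))
  print.data.frame(utils::head(x, n), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Condorcet (Copeland) rank aggregation baseline
#'
#' Pairwise majority voting with unit vote strength: in each sample, a listed
#' gene scores one win against every gene it outranks and every absent gene.
#' Genes are ranked by their Copeland-style win proportion
#' `win / (win + loss)`. This is the unweighted ablation baseline for
#' [epv_scores()] and is implemented independently of it (explicit pairwise
#' tallies).
#'
#' @inheritParams epv_scores
#' @return Data frame with columns `gene`, `win`, `loss`, `score`, ordered by
#'   the final ranking (ties: win descending, then symbol).
#' @export
condorcet_rank <- function(rankings, universe = NULL) {
  lists <- rankings[vapply(rankings, nrow, integer(1)) > 0]
  if (length(lists) == 0) stop("no non-empty sample rankings")
  if (is.null(universe)) {
    universe <- unique(unlist(lapply(lists, `[[`, "gene")))
  }
  universe <- sort(unique(as.character(universe)))
  U <- length(universe)
  wins <- matrix(0, U, U, dimnames = list(universe, universe))
  for (rk in lists) {
    pos <- match(universe, rk$gene)  # NA when absent
    for (i in seq_len(U)) {
      if (is.na(pos[i])) next
      beats <- is.na(pos) | pos[i] < pos
      beats[i] <- FALSE
      wins[i, beats] <- wins[i, beats] + 1
    }
  }
  win <- rowSums(wins)
  loss <- colSums(wins)
  tot <- win + loss
  score <- ifelse(tot > 0, win / tot, 0)
  ord <- order(-score, -win, universe)
  data.frame(gene = universe[ord], win = unname(win[ord]),
             loss = unname(loss[ord]), score = unname(score[ord]),
             stringsAsFactors = FALSE)
}

#' Cancer-specific default decay rate
#'
#' Returns the tuned exponential decay rate for a known cohort tag
#' (`"brca"` 0.9, `"luad"` 0.3, `"prad"` 0.6) and 0.5 otherwise.
#'
#' @param dataset_tag optional cohort tag, case-insensitive.
#' @return Numeric alpha.
#' @export
default_alpha <- function(dataset_tag = NULL) {
  if (is.null(dataset_tag)) return(0.5)
  switch(tolower(dataset_tag), brca = 0.9, luad = 0.3, prad = 0.6, 0.5)
}
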