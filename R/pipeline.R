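#' End-to-end cross-validated driver prioritization
#'
#' Runs the full procedure on a preprocessed cohort: k-fold sample split; per
#' fold, the model is trained on the training samples ([driver_fit()]) and
#' scores the held-out samples; each sample's candidate list is built from the
#' fold in which it was held out (so no ranking uses in-fold label
#' information); Exponential Pairwise Voting aggregates all out-of-fold lists
#' into the final cohort ranking. When reference drivers are known, per-fold
#' EPV rankings over each fold's test samples are also scored with top-K
#' precision/recall/F1 and averaged across folds.
#'
#' @param dataset a `cohort_dataset`.
#' @param k_folds number of cross-validation folds.
#' @param alpha EPV decay rate (see [default_alpha()]).
#' @param keep_fraction per-sample candidate fraction ([sample_rankings()]).
#' @param K_grid vector of K values for the per-fold top-K metrics.
#' @param ranking_method `"epv"` or `"condorcet"` for the final aggregation.
#' @param truth reference driver genes for evaluation (default: the dataset's
#'   known drivers).
#' @param seed integer seed driving the fold split and every model fit.
#' @param out_dir optional directory; when given, the ranking, per-sample
#'   candidate lists, metrics and a run manifest are written as TSV/JSON.
#' @param verbose print per-fold progress.
#' @param ... further arguments passed to [driver_fit()] (e.g. `epochs`,
#'   `hidden_dim`, `n_layers`, `use_bwfa`, `sampling_size`).
#' @return An object of class `driver_pipeline`: list with `ranking` (the
#'   final aggregated data frame), `rankings_per_sample`, `scores`
#'   (out-of-fold score matrix), `folds`, `metrics` (per fold x K data frame
#'   or NULL), `mean_metrics`, and `config`.
#' @export
driver_pipeline <- function(dataset, k_folds = 5, alpha = 0.5,
                            keep_fraction = 0.5, K_grid = c(10, 20, 50, 100),
                            ranking_method = c("epv", "condorcet"),
                            truth = NULL, seed = 1, out_dir = NULL,
                            verbose = FALSE, ...) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  ranking_method <- match.arg(ranking_method)
  if (is.null(truth)) truth <- intersect(dataset$known_drivers, dataset$genes)
  folds <- kfold_split(dataset$samples, k = k_folds, seed = seed)

  oof_scores <- matrix(NA_real_, length(dataset$genes), length(dataset$samples),
                       dimnames = list(dataset$genes, dataset$samples))
  per_sample <- vector("list", length(dataset$samples))
  names(per_sample) <- dataset$samples
  metrics <- NULL

  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(dataset$samples, test)
    if (verbose) message(sprintf("fold %d/%d: %d train / %d test samples",
                                 f, length(folds), length(train), length(test)))
    fit <- driver_fit(dataset, train_samples = train,
                      seed = (seed + 104729L * f) %% .Machine$integer.max, ...)
    sc <- fit$scores
    oof_scores[, test] <- sc[, test]
    fold_lists <- sample_rankings(sc[, test, drop = FALSE],
                                  dataset$Xg[, test, drop = FALSE],
                                  keep_fraction = keep_fraction)
    per_sample[test] <- fold_lists
    if (length(truth) > 0 &&
        any(vapply(fold_lists, nrow, integer(1)) > 0)) {
      fold_rank <- if (ranking_method == "epv") {
        epv_scores(fold_lists, alpha = alpha)
      } else {
        condorcet_rank(fold_lists)
      }
      mk <- lapply(K_grid, function(K) {
        m <- suppressWarnings(topk_metrics(fold_rank$gene, truth, K))
        data.frame(fold = f, K = K, precision = m$precision,
                   recall = m$recall, f1 = m$f1)
      })
      metrics <- rbind(metrics, do.call(rbind, mk))
    }
  }

  final <- if (ranking_method == "epv") {
    epv_scores(per_sample, alpha = alpha)
  } else {
    condorcet_rank(per_sample)
  }
  mean_metrics <- if (!is.null(metrics)) {
    agg <- stats::aggregate(metrics[c("precision", "recall", "f1")],
                            by = metrics["K"], FUN = mean)
    agg[order(agg$K), ]
  }
  res <- structure(list(ranking = final, rankings_per_sample = per_sample,
                        scores = oof_scores, folds = folds, metrics = metrics,
                        mean_metrics = mean_metrics, truth = truth,
                        config = list(k_folds = k_folds, alpha = alpha,
                                      keep_fraction = keep_fraction,
                                      K_grid = K_grid,
                                      ranking_method = ranking_method,
                                      seed = seed, fit_args = list(...))),
                   class = "driver_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' @export
print.driver_pipeline <- function(x, ...) {
  cat(sprintf(paste0("Cross-validated driver prioritization (%d folds, %s, ",
                     "alpha = %.2f)\n"),
              x$config$k_folds, x$config$ranking_method, x$config$alpha))
  cat("Top of the cohort ranking:\n")
  print.data.frame(utils::head(x$ranking, 10), row.names = FALSE, digits = 4)
  if (!is.null(x$mean_metrics)) {
    cat("Mean cross-validated top-K metrics:\n")
    print.data.frame(x$mean_metrics, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write pipeline outputs to a run directory
#'
#' Emits `ranking.tsv` (rank, gene, score, win, loss), `candidates.tsv`
#' (sample, rank, gene, score), `metrics.tsv` (fold, K, precision, recall,
#' f1) when available, and `manifest.json` capturing configuration, seed and
#' package version.
#'
#' @param result a `driver_pipeline`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_pipeline <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rk <- result$ranking
  utils::write.table(
    data.frame(rank = seq_len(nrow(rk)), gene = rk$gene, score = rk$score,
               win = rk$win, loss = rk$loss),
    file.path(dir, "ranking.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  cand <- do.call(rbind, lapply(names(result$rankings_per_sample), function(s) {
    df <- result$rankings_per_sample[[s]]
    if (nrow(df) == 0) return(NULL)
    data.frame(sample = s, rank = seq_len(nrow(df)), gene = df$gene,
               score = df$score)
  }))
  utils::write.table(cand, file.path(dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$metrics)) {
    utils::write.table(result$metrics, file.path(dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- c(result$config[setdiff(names(result$config), "fit_args")],
                result$config$fit_args,
                list(package_version = as.character(utils::packageVersion("driversage"))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Three-factor ablation over the model components
#'
#' Runs the pipeline under all 8 combinations of: encoder depth (1 vs 2
#' GraphSAGE layers), bidirectional cross-attention (on vs off), and rank
#' aggregation (EPV vs Condorcet), on one dataset, reporting the F1 of the
#' final cohort ranking at `K` against the reference drivers.
#'
#' @param dataset a `cohort_dataset`.
#' @param K ranking prefix at which F1 is evaluated.
#' @param alpha EPV decay rate.
#' @param seed integer seed (shared across configurations so they see the
#'   same folds).
#' @param verbose print each configuration as it runs.
#' @param ... further arguments passed to [driver_pipeline()] /
#'   [driver_fit()] (e.g. `epochs`, `k_folds`, `hidden_dim`).
#' @details The two ranking strategies are applied to the same fitted models
#'   (only the aggregation step differs), so the 8 configurations require 4
#'   cross-validated fits.
#' @return Data frame with 8 rows: `n_layers`, `bwfa`, `ranking`,
#'   `precision`, `recall`, `f1`.
#' @export
run_ablation <- function(dataset, K = 20, alpha = 0.5, seed = 1,
                         verbose = FALSE, ...) {
  fits <- expand.grid(n_layers = c(2, 1), bwfa = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(fits)), function(i) {
    cfg <- fits[i, ]
    if (verbose) {
      message(sprintf("ablation fit %d/4: layers=%d bwfa=%s",
                      i, cfg$n_layers, cfg$bwfa))
    }
    res <- driver_pipeline(dataset, ranking_method = "epv", alpha = alpha,
                           K_grid = K, seed = seed, n_layers = cfg$n_layers,
                           use_bwfa = cfg$bwfa, ...)
    cond <- condorcet_rank(res$rankings_per_sample)
    do.call(rbind, lapply(c("epv", "condorcet"), function(method) {
      rk <- if (method == "epv") res$ranking$gene else cond$gene
      m <- suppressWarnings(topk_metrics(rk, res$truth, K))
      data.frame(n_layers = cfg$n_layers, bwfa = cfg$bwfa, ranking = method,
                 precision = m$precision, recall = m$recall, f1 = m$f1)
    }))
  })
  do.call(rbind, out)
}
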