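#' Binary classification metrics for association prediction
#'
#' Computes the seven evaluation metrics from labels and scores: thresholded
#' accuracy, sensitivity (recall), specificity, precision, and Matthews
#' correlation coefficient, plus threshold-free AUROC and AUPR. AUROC is the
#' probability that a random positive outscores a random negative (ties
#' count one half, i.e. the rank/Mann-Whitney form); AUPR integrates the
#' precision-recall curve as a step function over distinct score thresholds.
#' Degenerate MCC denominators (a zero row or column of the confusion
#' matrix) yield 0 by convention; precision with no positive predictions is
#' reported as 0.
#'
#' @param labels Binary vector (0/1); both classes must be present.
#' @param scores Numeric scores, same length.
#' @param threshold Scores strictly above `threshold` predict class 1
#'   (default 0.5).
#' @return A one-row tibble with columns `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `mcc`, `auroc`, `aupr`.
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) abort("Length mismatch between labels and scores.")
  if (!all(labels %in% c(0L, 1L))) abort("Labels must be 0/1.")
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) abort("Both classes are required to compute AUROC/AUPR.")

  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)

  mcc_den <- sqrt(as.double(tp + fp)) * sqrt(as.double(tp + fn)) *
    sqrt(as.double(tn + fp)) * sqrt(as.double(tn + fn))
  mcc <- if (mcc_den == 0) 0 else (as.double(tp) * tn - as.double(fp) * fn) / mcc_den

  tibble::tibble(
    accuracy = (tp + tn) / length(labels),
    sensitivity = tp / np,
    specificity = tn / nn,
    precision = if (tp + fp == 0L) 0 else tp / (tp + fp),
    mcc = mcc,
    auroc = auroc_rank(labels, scores),
    aupr = aupr_step(labels, scores)
  )
}

# Mann-Whitney form: ties contribute 1/2
auroc_rank <- function(labels, scores) {
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

# step integration of the precision-recall curve over distinct thresholds
aupr_step <- function(labels, scores) {
  np <- sum(labels == 1L)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  keep <- c(sc[-length(sc)] != sc[-1L], TRUE)  # last index of each tie group
  tp <- cumsum(lab)[keep]
  n_pred <- seq_along(lab)[keep]
  recall <- tp / np
  precision <- tp / n_pred
  sum(diff(c(0, recall)) * precision)
}

#' Repeated stratified cross-validation of the association pipeline
#'
#' Splits the known associations into `folds` disjoint parts (per repeat),
#' and for every fold rebuilds the whole pipeline from the training
#' positives only: similarity networks, integrated similarities,
#' auto-encoder features, the CDHN, and both embeddings. A balanced
#' training set (training positives plus an equal uniform sample of unknown
#' cells) trains the classifier, which is then scored on the held-out
#' positives plus an equally sized held-out negative sample. Held-out pairs
#' never influence any training-fold artifact.
#'
#' @param assoc An `association_matrix`.
#' @param ontology A `disease_ontology` covering (at least some of) the
#'   diseases.
#' @param config A [cda_config()].
#' @param folds Number of folds (default 5).
#' @param repeats Number of repetitions with reshuffled folds (default 10).
#' @param scheme Embedding scheme: `"both"` (fused), `"local_only"`, or
#'   `"global_only"`.
#' @param classifier Classifier kind (see [train_classifier()]).
#' @param seed Master seed; drives fold assignment, negative sampling, and
#'   every embedding stage.
#' @param keep_artifacts Keep each fold's similarity/embedding artifacts in
#'   the result (memory-hungry; used for leakage auditing).
#' @return A `cda_cv` object; see [tidy.cda_cv()], [glance.cda_cv()],
#'   [autoplot.cda_cv()].
#' @export
cross_validate <- function(assoc, ontology, config = cda_config(), folds = 5,
                           repeats = 10, scheme = c("both", "local_only", "global_only"),
                           classifier = "et", seed = 1, keep_artifacts = FALSE) {
  scheme <- match.arg(scheme)
  cda_cv_engine(assoc, ontology, config, folds, repeats, schemes = scheme,
                classifier = classifier, seed = seed, keep_artifacts = keep_artifacts)
}

#' Ablation over the local / global embedding schemes
#'
#' Runs the cross-validation three times over the embedding schemes --
#' local-only (GCN), global-only (walk embedding), and both (fused) -- with
#' identical fold partitions, negative samples, and per-fold embeddings, so
#' scheme comparisons are paired.
#'
#' @inheritParams cross_validate
#' @return A `cda_cv` object whose rows span the three schemes.
#' @export
run_ablation <- function(assoc, ontology, config = cda_config(), folds = 5,
                         repeats = 10, classifier = "et", seed = 1) {
  cda_cv_engine(assoc, ontology, config, folds, repeats,
                schemes = c("local_only", "global_only", "both"),
                classifier = classifier, seed = seed)
}

cda_cv_engine <- function(assoc, ontology, config, folds, repeats, schemes,
                          classifier, seed, keep_artifacts = FALSE) {
  stopifnot(inherits(assoc, "association_matrix"))
  folds <- check_scalar_int(folds, "folds", 2L)
  repeats <- check_scalar_int(repeats, "repeats")
  pos <- which(assoc$values == 1, arr.ind = TRUE)
  dimnames(pos) <- list(NULL, c("circ_index", "disease_index"))
  if (nrow(pos) < folds) abort("Fewer positives than folds.")

  metric_rows <- list()
  pred_rows <- list()
  artifacts <- list()
  fold_assignments <- vector("list", repeats)
  for (rep_i in seq_len(repeats)) {
    assign_f <- with_local_seed(derive_seed(seed, paste0("folds-", rep_i)), {
      sample(rep_len(seq_len(folds), nrow(pos)))
    })
    fold_assignments[[rep_i]] <- assign_f
    for (f in seq_len(folds)) {
      test_pos <- pos[assign_f == f, , drop = FALSE]
      train_pos <- pos[assign_f != f, , drop = FALSE]
      a_train <- assoc$values
      a_train[test_pos] <- 0
      assoc_train <- new_association_matrix(a_train, assoc$circ_ids, assoc$disease_ids)

      test_neg <- sample_negatives(assoc, seed = derive_seed(seed, sprintf("testneg-%d-%d", rep_i, f)),
                                   n = nrow(test_pos))
      train_neg <- sample_negatives(assoc_train,
                                    seed = derive_seed(seed, sprintf("trainneg-%d-%d", rep_i, f)),
                                    exclude = rbind(test_pos, test_neg),
                                    n = ceiling(config$neg_ratio * nrow(train_pos)))

      emb <- build_embedding(assoc_train, ontology, config,
                             seed = derive_seed(seed, sprintf("emb-%d-%d", rep_i, f)))
      if (keep_artifacts) {
        artifacts[[sprintf("r%d_f%d", rep_i, f)]] <- emb
      }

      train_pairs <- rbind(train_pos, train_neg)
      train_labels <- rep(c(1L, 0L), c(nrow(train_pos), nrow(train_neg)))
      test_pairs <- rbind(test_pos, test_neg)
      test_labels <- rep(c(1L, 0L), c(nrow(test_pos), nrow(test_neg)))

      for (sch in schemes) {
        h_use <- switch(sch, local_only = emb$Hl, global_only = emb$Hg, both = emb$H)
        ftr <- make_pair_features(h_use, train_pairs, emb$n_circ, mode = config$pair_mode)
        fte <- make_pair_features(h_use, test_pairs, emb$n_circ, mode = config$pair_mode)
        model <- train_classifier(ftr, train_labels, kind = classifier,
                                  seed = derive_seed(seed, sprintf("clf-%d-%d", rep_i, f)),
                                  num_trees = config$num_trees)
        scores <- score_pairs(model, fte)
        ms <- compute_metrics(test_labels, scores, threshold = config$threshold)
        metric_rows[[length(metric_rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(scheme = sch, repeat_id = rep_i, fold = f), ms
        )
        pred_rows[[length(pred_rows) + 1L]] <- tibble::tibble(
          scheme = sch, repeat_id = rep_i, fold = f,
          label = test_labels, score = scores
        )
      }
    }
  }

  structure(
    list(
      metrics = dplyr::bind_rows(metric_rows),
      predictions = dplyr::bind_rows(pred_rows),
      schemes = schemes, folds = folds, repeats = repeats,
      classifier = classifier, seed = seed, config = config,
      positives = pos, fold_assignments = fold_assignments,
      artifacts = if (keep_artifacts) artifacts else NULL
    ),
    class = "cda_cv"
  )
}

#' @export
print.cda_cv <- function(x, ...) {
  cat(sprintf("<cda_cv> %d-fold x %d repeat(s), classifier '%s'\n",
              x$folds, x$repeats, x$classifier))
  print(glance(x))
  invisible(x)
}

#' Per-fold cross-validation metrics
#' @param x A `cda_cv` object.
#' @param ... Unused.
#' @return Tibble with one row per scheme x repeat x fold.
#' @export
tidy.cda_cv <- function(x, ...) x$metrics

#' Cross-validation summary (mean and standard deviation per metric)
#' @param x A `cda_cv` object.
#' @param ... Unused.
#' @return Tibble with one row per scheme and `<metric>_mean` / `<metric>_sd`
#'   columns, aggregated over all folds and repeats.
#' @export
glance.cda_cv <- function(x, ...) {
  metric_cols <- c("accuracy", "sensitivity", "specificity", "precision",
                   "mcc", "auroc", "aupr")
  x$metrics |>
    dplyr::group_by(.data$scheme) |>
    dplyr::summarise(
      n_folds = dplyr::n(),
      dplyr::across(dplyr::all_of(metric_cols),
                    list(mean = mean, sd = sd)),
      .groups = "drop"
    )
}

#' Plot cross-validation results
#'
#' `type = "roc"` and `type = "pr"` pool the held-out predictions per scheme
#' and draw the ROC / precision-recall curve; `type = "metrics"` shows
#' per-fold metric distributions as boxplots.
#'
#' @param object A `cda_cv` object.
#' @param type `"roc"`, `"pr"`, or `"metrics"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cda_cv <- function(object, type = c("roc", "pr", "metrics"), ...) {
  type <- match.arg(type)
  if (type == "metrics") {
    long <- tidyr::pivot_longer(object$metrics,
                                cols = c("accuracy", "sensitivity", "specificity",
                                         "precision", "mcc", "auroc", "aupr"),
                                names_to = "metric", values_to = "value")
    return(
      ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value,
                                         fill = .data$scheme)) +
        ggplot2::geom_boxplot(outlier.size = 0.6) +
        ggplot2::labs(x = NULL, y = "value", fill = "scheme") +
        ggplot2::theme_minimal()
    )
  }
  curves <- object$predictions |>
    dplyr::group_by(.data$scheme) |>
    dplyr::group_modify(function(d, key) {
      if (type == "roc") roc_points(d$label, d$score) else pr_points(d$label, d$score)
    }) |>
    dplyr::ungroup()
  if (type == "roc") {
    ggplot2::ggplot(curves, ggplot2::aes(x = .data$x, y = .data$y,
                                         colour = .data$scheme)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
      ggplot2::geom_line() +
      ggplot2::labs(x = "false positive rate", y = "true positive rate",
                    colour = "scheme") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(curves, ggplot2::aes(x = .data$x, y = .data$y,
                                         colour = .data$scheme)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "recall", y = "precision", colour = "scheme") +
      ggplot2::theme_minimal()
  }
}

roc_points <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  keep <- c(sc[-length(sc)] != sc[-1L], TRUE)
  tp <- cumsum(lab)[keep]; fp <- cumsum(1 - lab)[keep]
  tibble::tibble(x = c(0, fp / max(fp)), y = c(0, tp / max(tp)))
}

pr_points <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  keep <- c(sc[-length(sc)] != sc[-1L], TRUE)
  tp <- cumsum(lab)[keep]
  n_pred <- seq_along(lab)[keep]
  tibble::tibble(x = tp / sum(lab), y = tp / n_pred)
}

#' Render a cross-validation report table
#'
#' Formats per-fold and summary rows (4-decimal values) and optionally
#' writes them to a TSV file.
#'
#' @param cv A `cda_cv` object.
#' @param path Optional output TSV path.
#' @return Tibble of formatted rows, invisibly if `path` is given.
#' @export
report_cv <- function(cv, path = NULL) {
  stopifnot(inherits(cv, "cda_cv"))
  metric_cols <- c("accuracy", "sensitivity", "specificity", "precision",
                   "mcc", "auroc", "aupr")
  per_fold <- cv$metrics |>
    dplyr::mutate(row = sprintf("repeat %d fold %d", .data$repeat_id, .data$fold)) |>
    dplyr::select(dplyr::all_of(c("scheme", "row", metric_cols)))
  summary_rows <- cv$metrics |>
    dplyr::group_by(.data$scheme) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metric_cols),
                                   ~ sprintf("%.4f +/- %.4f", mean(.x), sd(.x))),
                     .groups = "drop") |>
    dplyr::mutate(row = "mean +/- sd", .after = "scheme")
  out <- dplyr::bind_rows(
    dplyr::mutate(per_fold, dplyr::across(dplyr::all_of(metric_cols),
                                          ~ sprintf("%.4f", .x))),
    summary_rows
  )
  if (!is.null(path)) {
    readr::write_tsv(out, path, progress = FALSE)
    return(invisible(out))
  }
  out
}
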