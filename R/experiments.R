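#' Assemble a labeled dataset from two feature tables
#'
#' Row-stacks a positive (class 1, label 1) and a negative (class 2,
#' label 0) feature table, after checking that both use the same encoding
#' scheme and carry identical feature columns in identical order.
#'
#' @param positives,negatives Feature tibbles from [kmer_frequencies()] or
#'   [encode_structure()] (an `id` column plus numeric feature columns).
#' @return A tibble with columns `id`, `label` (1/0) and the feature
#'   columns, carrying the common `scheme` attribute.
#' @export
build_dataset <- function(positives, negatives) {
  if (nrow(positives) == 0L || nrow(negatives) == 0L) {
    abort("Both classes must be non-empty; a one-class dataset is degenerate.")
  }
  sp <- attr(positives, "scheme")
  sn <- attr(negatives, "scheme")
  if (!is.null(sp) && !is.null(sn) && !identical(sp, sn)) {
    abort(sprintf("Scheme mismatch: positives are '%s', negatives are '%s'.", sp, sn))
  }
  fp <- setdiff(names(positives), "id")
  fn <- setdiff(names(negatives), "id")
  if (!identical(fp, fn)) {
    bad <- which(fp[seq_len(min(length(fp), length(fn)))] !=
                   fn[seq_len(min(length(fp), length(fn)))])
    div <- if (length(bad) > 0) fp[bad[1]] else
      c(setdiff(fp, fn), setdiff(fn, fp))[1]
    abort(sprintf("Feature name order differs between classes; first divergent feature: '%s'.", div))
  }
  out <- bind_rows(mutate(positives, label = 1L, .after = "id"),
                   mutate(negatives, label = 0L, .after = "id"))
  attr(out, "scheme") <- sp %||% sn
  inform(sprintf("Dataset: %d positives, %d negatives, %d features.",
                 nrow(positives), nrow(negatives), length(fp)))
  out
}

#' Run a cross-validated Random-Forest classification experiment
#'
#' Trains probability Random Forests (2000 trees by default) under seeded
#' stratified k-fold cross-validation. Per held-out fold it records ROC-AUC
#' and the threshold metrics accuracy, precision and recall, together with
#' the fold confusion matrix; pooled out-of-fold predictions provide the ROC
#' and precision-recall curves. Feature importances come from a final forest
#' fitted on all data, as normalized impurity (Gini) importance summing
#' to 1. Fully reproducible given `seed` (single-threaded forests).
#'
#' @param data A labeled dataset from [build_dataset()].
#' @param n_trees Number of trees per forest (default 2000).
#' @param cv_folds Number of stratified folds (default 5).
#' @param seed Integer seed controlling fold assignment and forests.
#' @param threshold Probability threshold for accuracy/precision/recall
#'   (default 0.5).
#' @param name Optional experiment name (for printing and summaries).
#' @return An object of class `sl_experiment`; see [tidy.sl_experiment()],
#'   [glance.sl_experiment()] and [autoplot.sl_experiment()].
#' @export
run_experiment <- function(data, n_trees = 2000L, cv_folds = 5L, seed = 1L,
                           threshold = 0.5, name = NULL) {
  feats <- setdiff(names(data), c("id", "label"))
  if (length(feats) == 0L) abort("`data` has no feature columns.")
  if (!all(data$label %in% c(0L, 1L))) abort("`label` must be 0/1.")
  counts <- table(factor(data$label, levels = c(0L, 1L)))
  if (min(counts) < 2L * cv_folds) {
    abort(sprintf(
      "Need >= 2 instances per class per fold (smallest class has %d for %d folds); add data or use fewer folds.",
      min(counts), cv_folds))
  }
  xmat <- as.matrix(data[, feats])
  y <- factor(ifelse(data$label == 1L, "pos", "neg"), levels = c("neg", "pos"))

  fold <- integer(nrow(data))
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
  })

  oof <- numeric(nrow(data))
  metrics <- purrr::map(seq_len(cv_folds), function(f) {
    test <- fold == f
    fit <- ranger::ranger(x = xmat[!test, , drop = FALSE], y = y[!test],
                          num.trees = n_trees, probability = TRUE,
                          seed = seed + f, num.threads = 1L)
    prob <- predict(fit, data = xmat[test, , drop = FALSE],
                    num.threads = 1L)$predictions[, "pos"]
    oof[test] <<- prob
    truth <- y[test]
    cm <- confusion_counts(truth == "pos", prob >= threshold)
    tibble(fold = f,
           auc = auc_score(truth == "pos", prob),
           accuracy = (cm$tp + cm$tn) / sum(unlist(cm)),
           precision = if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else NA_real_,
           recall = cm$tp / (cm$tp + cm$fn),
           tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
           n_test = length(truth))
  }) |> bind_rows()

  final <- ranger::ranger(x = xmat, y = y, num.trees = n_trees,
                          probability = TRUE, importance = "impurity",
                          seed = seed, num.threads = 1L)
  imp <- final$variable.importance
  if (sum(imp) > 0) imp <- imp / sum(imp)
  importances <- tibble(feature = names(imp), importance = unname(imp)) |>
    arrange(desc(.data$importance), .data$feature) |>
    mutate(rank = row_number())

  structure(list(
    name = name %||% "experiment",
    scheme = attr(data, "scheme"),
    spec = list(n_trees = as.integer(n_trees), cv_folds = as.integer(cv_folds),
                seed = as.integer(seed), threshold = threshold),
    class_counts = c(neg = unname(counts[1]), pos = unname(counts[2])),
    metrics = metrics,
    oof = tibble(id = data$id, label = data$label, fold = fold, prob = oof),
    roc_curve = roc_points(data$label == 1L, oof),
    pr_curve = pr_points(data$label == 1L, oof),
    importances = importances,
    top10 = head(importances$feature, 10L),
    model = structure(list(fit = final, features = feats,
                           scheme = attr(data, "scheme"),
                           threshold = threshold),
                      class = "sl_rf")),
    class = "sl_experiment")
}

confusion_counts <- function(truth, called) {
  list(tp = sum(truth & called), fp = sum(!truth & called),
       tn = sum(!truth & !called), fn = sum(truth & !called))
}

# ROC-AUC via pROC, with fixed direction so a random score gives ~0.5.
auc_score <- function(truth, score) {
  if (length(unique(truth)) < 2L) {
    abort("A fold ended up single-class; add data or use fewer folds.")
  }
  r <- pROC::roc(response = factor(ifelse(truth, "pos", "neg"),
                                   levels = c("neg", "pos")),
                 predictor = score, levels = c("neg", "pos"),
                 direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

roc_points <- function(truth, score) {
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]
  tibble(fpr = c(0, cumsum(!truth) / max(sum(!truth), 1L)),
         tpr = c(0, cumsum(truth) / max(sum(truth), 1L)))
}

pr_points <- function(truth, score) {
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]
  tp <- cumsum(truth)
  tibble(recall = tp / max(sum(truth), 1L),
         precision = tp / seq_along(truth))
}

#' @export
print.sl_experiment <- function(x, ...) {
  g <- generics::glance(x)
  cat(sprintf("<sl_experiment> '%s' (%s scheme)\n", x$name,
              x$scheme %||% "unknown"))
  cat(sprintf("  %d neg / %d pos, %d features, %d trees, %d-fold CV (seed %d)\n",
              x$class_counts["neg"], x$class_counts["pos"],
              length(x$model$features), x$spec$n_trees, x$spec$cv_folds,
              x$spec$seed))
  cat(sprintf("  AUC %.3f +/- %.3f | accuracy %.3f | precision %.3f | recall %.3f\n",
              g$auc_mean, g$auc_sd, g$accuracy_mean, g$precision_mean,
              g$recall_mean))
  cat("  top importances:", paste(head(x$top10, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy an `sl_experiment`
#'
#' @param x An [run_experiment()] result.
#' @param what One of `"metrics"` (per-fold metrics and confusion counts,
#'   the default), `"importance"` (ranked normalized importances),
#'   `"roc"` or `"pr"` (pooled out-of-fold curve points).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sl_experiment <- function(x, what = c("metrics", "importance", "roc", "pr"),
                               ...) {
  switch(match.arg(what),
         metrics = x$metrics,
         importance = x$importances,
         roc = x$roc_curve,
         pr = x$pr_curve)
}

#' Glance at an `sl_experiment`
#'
#' @param x An [run_experiment()] result.
#' @param ... Unused.
#' @return A one-row tibble with across-fold means and standard deviations
#'   of AUC, accuracy, precision and recall, plus experiment dimensions.
#' @export
glance.sl_experiment <- function(x, ...) {
  m <- x$metrics
  tibble(name = x$name, scheme = x$scheme %||% NA_character_,
         auc_mean = mean(m$auc), auc_sd = sd(m$auc),
         accuracy_mean = mean(m$accuracy), accuracy_sd = sd(m$accuracy),
         precision_mean = mean(m$precision, na.rm = TRUE),
         precision_sd = sd(m$precision, na.rm = TRUE),
         recall_mean = mean(m$recall), recall_sd = sd(m$recall),
         n = sum(x$class_counts), n_features = length(x$model$features),
         n_trees = x$spec$n_trees, cv_folds = x$spec$cv_folds,
         seed = x$spec$seed)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot ROC and precision-recall curves of an experiment
#'
#' @param object An [run_experiment()] result.
#' @param ... Unused.
#' @return A ggplot with ROC and PR panels (pooled out-of-fold predictions).
#' @export
autoplot.sl_experiment <- function(object, ...) {
  dat <- bind_rows(
    mutate(object$roc_curve, panel = "ROC", x = .data$fpr, y = .data$tpr),
    mutate(object$pr_curve, panel = "Precision-recall", x = .data$recall,
           y = .data$precision))
  guide <- tibble(panel = "ROC", x = c(0, 1), y = c(0, 1))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(linewidth = 0.7, colour = "#2c7fb8") +
    ggplot2::geom_line(data = guide, linetype = "dashed", colour = "grey60") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::coord_cartesian(ylim = c(0, 1), xlim = c(0, 1)) +
    ggplot2::labs(title = object$name, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Apply a trained model to a foreign set and report the recognition rate
#'
#' Scores a set of feature vectors with a trained forest and returns the
#' fraction recognized, i.e. assigned positive-class probability at or above
#' `threshold`. Used to ask how often a model trained on one element family
#' (e.g. retrotransposon 3'-end stem-loops) fires on another (e.g. processed
#' pseudogenes or mRNA 3' ends).
#'
#' @param object An `sl_experiment` or its `$model` (`sl_rf`).
#' @param features A feature tibble in the training scheme, with identical
#'   feature columns in identical order.
#' @param threshold Recognition threshold on the positive-class probability
#'   (default 0.5).
#' @return An object of class `sl_recognition`: a list with `fraction`, `n`,
#'   `n_recognized`, `threshold` and a `predictions` tibble (`id`, `prob`,
#'   `recognized`).
#' @export
cross_apply <- function(object, features, threshold = 0.5) {
  model <- if (inherits(object, "sl_experiment")) object$model else object
  if (!inherits(model, "sl_rf")) abort("`object` must be an sl_experiment or sl_rf model.")
  if (nrow(features) == 0L) abort("The foreign set is empty.")
  sf <- attr(features, "scheme")
  if (!is.null(sf) && !is.null(model$scheme) && !identical(sf, model$scheme)) {
    abort(sprintf("Scheme mismatch: model was trained on '%s', features are '%s'.",
                  model$scheme, sf))
  }
  fn <- setdiff(names(features), c("id", "label"))
  if (!identical(fn, model$features)) {
    abort("Foreign features do not match the training features (names/order).")
  }
  prob <- predict(model$fit, data = as.matrix(features[, fn]),
                  num.threads = 1L)$predictions[, "pos"]
  rec <- prob >= threshold
  structure(list(fraction = mean(rec), n = length(rec),
                 n_recognized = sum(rec), threshold = threshold,
                 predictions = tibble(id = features$id, prob = prob,
                                      recognized = rec)),
            class = "sl_recognition")
}

#' @export
print.sl_recognition <- function(x, ...) {
  cat(sprintf("<sl_recognition> %d/%d recognized (%.1f%%) at threshold %.2f\n",
              x$n_recognized, x$n, 100 * x$fraction, x$threshold))
  invisible(x)
}

#' Tally top-10 importances across structure-based experiments
#'
#' Splits every top-10 feature name of each experiment into its
#' `position:property` parts and tallies, across experiments, how often each
#' property and each position appears among the top 10. For loop and bulge
#' features the "property" part is the one-hot nucleotide (A/C/G/T).
#'
#' @param reports A list of `sl_experiment` objects (or a single one), all
#'   using the structure-based scheme.
#' @return An object of class `sl_importance_summary`: a list with
#'   `by_property` and `by_position` count tibbles (sorted descending) and
#'   `n_reports`.
#' @export
summarize_importances <- function(reports) {
  if (inherits(reports, "sl_experiment")) reports <- list(reports)
  ok <- vapply(reports, function(r) inherits(r, "sl_experiment"), logical(1))
  if (!all(ok)) abort("`reports` must be sl_experiment objects.")
  schemes <- vapply(reports, function(r) r$scheme %||% "unknown", character(1))
  if (!all(schemes == "structure_sl")) {
    abort("Importance tallies are defined for the structure-based scheme only.")
  }
  feats <- unlist(lapply(reports, function(r) r$top10))
  parts <- stringr::str_split_fixed(feats, stringr::fixed(":"), 2)
  if (any(parts[, 2] == "")) {
    abort(sprintf("Malformed feature name '%s' (expected position:property).",
                  feats[which(parts[, 2] == "")[1]]))
  }
  tally <- function(v, nm) {
    tb <- table(v)
    out <- tibble(key = names(tb), count = as.integer(tb))
    out <- arrange(out, desc(.data$count), .data$key)
    names(out)[1] <- nm
    out
  }
  structure(list(by_property = tally(parts[, 2], "property"),
                 by_position = tally(parts[, 1], "position"),
                 n_reports = length(reports)),
            class = "sl_importance_summary")
}

#' @export
print.sl_importance_summary <- function(x, ...) {
  cat(sprintf("<sl_importance_summary> over %d experiment(s)\n", x$n_reports))
  cat("  properties:",
      paste(sprintf("%s (%d)", head(x$by_property$property, 5),
                    head(x$by_property$count, 5)), collapse = ", "), "\n")
  cat("  positions: ",
      paste(sprintf("%s (%d)", head(x$by_position$position, 5),
                    head(x$by_position$count, 5)), collapse = ", "), "\n")
  invisible(x)
}

#' Plot importance tallies
#'
#' @param object An [summarize_importances()] result.
#' @param ... Unused.
#' @return A ggplot of property and position tallies.
#' @export
autoplot.sl_importance_summary <- function(object, ...) {
  dat <- bind_rows(
    mutate(object$by_property, panel = "Property", key = .data$property),
    mutate(object$by_position, panel = "Position", key = .data$position))
  dat <- mutate(dat, key = stats::reorder(.data$key, .data$count))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$count, y = .data$key)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "Appearances in top-10", y = NULL) +
    ggplot2::theme_minimal()
}
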