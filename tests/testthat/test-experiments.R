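test_that("dataset assembly enforces the feature contract", {
  withr::local_seed(1)
  pos <- random_features(5, tag = "p")
  neg <- random_features(5, tag = "n")
  d <- suppressMessages(build_dataset(pos, neg))
  expect_identical(nrow(d), 10L)
  expect_identical(sum(d$label), 5L)
  expect_identical(attr(d, "scheme"), "sequence_kmer")
  expect_error(suppressMessages(build_dataset(pos, neg[0, ])), "one-class")
  perm <- neg[, c("id", sample(setdiff(names(neg), "id")))]
  attr(perm, "scheme") <- "sequence_kmer"
  expect_error(suppressMessages(build_dataset(pos, perm)),
               "first divergent feature")
  other <- neg
  attr(other, "scheme") <- "structure_sl"
  expect_error(suppressMessages(build_dataset(pos, other)), "Scheme mismatch")
})

test_that("separable classes score perfect AUC and metrics recompute from the confusion matrix", {
  withr::local_seed(2)
  d <- suppressMessages(build_dataset(random_features(100, mu = 10, tag = "p"),
                                      random_features(100, mu = -10, tag = "n")))
  e <- run_experiment(d, n_trees = 200, seed = 5)
  expect_true(all(e$metrics$auc == 1))
  m <- e$metrics
  expect_equal(m$accuracy, (m$tp + m$tn) / (m$tp + m$tn + m$fp + m$fn))
  expect_equal(m$precision, m$tp / (m$tp + m$fp))
  expect_equal(m$recall, m$tp / (m$tp + m$fn))
  expect_true(all(m$n_test == m$tp + m$tn + m$fp + m$fn))
  g <- glance(e)
  expect_equal(g$auc_mean, 1)
  expect_identical(g$n, 200L)
  expect_equal(sum(e$importances$importance), 1)
  expect_length(e$top10, 10L)
  # curves end at (1, 1) for ROC and start at full precision for PR
  expect_equal(unlist(e$roc_curve[nrow(e$roc_curve), ]), c(fpr = 1, tpr = 1))
  expect_true(all(e$pr_curve$precision >= 0 & e$pr_curve$precision <= 1))
})

test_that("a single informative feature is recovered as top importance", {
  withr::local_seed(3)
  hits <- 0L
  for (rep in 1:5) {
    m <- matrix(stats::rnorm(300 * 15), 300, 15,
                dimnames = list(NULL, sprintf("F%02d", 1:15)))
    lab <- m[, 7] > stats::median(m[, 7])
    po <- dplyr::bind_cols(tibble::tibble(id = paste0("i", 1:300)),
                           tibble::as_tibble(m))
    pos <- po[lab, ]; neg <- po[!lab, ]
    attr(pos, "scheme") <- attr(neg, "scheme") <- "sequence_kmer"
    e <- run_experiment(suppressMessages(build_dataset(pos, neg)),
                        n_trees = 300, seed = rep)
    hits <- hits + (e$importances$feature[1] == "F07")
  }
  expect_gte(hits, 4L)
})

test_that("experiments are seed-reproducible and AUC survives monotone transforms", {
  withr::local_seed(4)
  d <- suppressMessages(build_dataset(random_features(40, mu = 1, tag = "p"),
                                      random_features(40, mu = -1, tag = "n")))
  e1 <- run_experiment(d, n_trees = 150, seed = 9)
  e2 <- run_experiment(d, n_trees = 150, seed = 9)
  expect_identical(e1$metrics, e2$metrics)
  expect_identical(e1$importances, e2$importances)
  expect_identical(e1$oof, e2$oof)
  # Strictly monotone transform of one feature: tree ensembles split on
  # order, so the cross-validated AUC is unchanged.
  dt <- d
  dt$F03 <- exp(dt$F03)
  attr(dt, "scheme") <- attr(d, "scheme")
  e3 <- run_experiment(dt, n_trees = 150, seed = 9)
  expect_equal(e3$metrics$auc, e1$metrics$auc, tolerance = 1e-12)
})

test_that("cross-application reports recognition fractions with guardrails", {
  withr::local_seed(6)
  pos <- random_features(80, mu = 3, tag = "p")
  neg <- random_features(80, mu = -3, tag = "n")
  e <- run_experiment(suppressMessages(build_dataset(pos, neg)),
                      n_trees = 200, seed = 2)
  self <- cross_apply(e, pos)
  expect_gte(self$fraction, 0.5)
  expect_identical(self$n, 80L)
  expect_identical(nrow(self$predictions), 80L)
  expect_equal(self$fraction, mean(self$predictions$prob >= 0.5))
  # The negative class itself is recognized (almost) never.
  expect_lte(cross_apply(e, neg)$fraction, 0.05)
  expect_error(cross_apply(e, pos[0, ]), "empty")
  wrong <- pos
  attr(wrong, "scheme") <- "structure_sl"
  expect_error(cross_apply(e, wrong), "Scheme mismatch")
  perm <- pos[, c("id", rev(setdiff(names(pos), "id")))]
  attr(perm, "scheme") <- "sequence_kmer"
  expect_error(cross_apply(e, perm), "names/order")
})

test_that("importance tallies split position:property and count across reports", {
  r1 <- experiment_stub(c("LS0:shift", "LS0:rise", "LS3:shift", "LP2:G"))
  r2 <- experiment_stub(c("LS3:shift", "LS6:hydrophilicity", "RB1:T"))
  s <- summarize_importances(list(r1, r2))
  expect_identical(s$n_reports, 2L)
  expect_identical(s$by_property$count[s$by_property$property == "shift"], 3L)
  expect_identical(s$by_position$count[s$by_position$position == "LS0"], 2L)
  expect_identical(s$by_position$count[s$by_position$position == "LS3"], 2L)
  expect_true(all(diff(s$by_property$count) <= 0))
  expect_error(summarize_importances(list(experiment_stub("AA", scheme = "sequence_kmer"))),
               "structure-based")
  expect_error(summarize_importances(list(experiment_stub("badname"))),
               "Malformed")
})

test_that("stratified CV refuses single-class-fold setups", {
  withr::local_seed(7)
  d <- suppressMessages(build_dataset(random_features(4, tag = "p"),
                                      random_features(40, tag = "n")))
  expect_error(run_experiment(d, n_trees = 50, cv_folds = 5, seed = 1),
               "fewer folds")
})
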