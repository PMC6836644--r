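test_that("majority_vote applies the tie-to-Active rule", {
  expect_equal(majority_vote(c("Active", "Active", "Inactive")), "Active")
  expect_equal(majority_vote(c("Active", "Inactive")), "Active")  # tie
  expect_equal(majority_vote(rep("Inactive", 3)), "Inactive")
  expect_error(majority_vote(character(0)), "empty")
})

test_that("majority_vote matches exhaustive enumeration for 3 and 5 voters", {
  for (n in c(3L, 5L)) {
    patterns <- expand.grid(rep(list(c("Active", "Inactive")), n),
                            stringsAsFactors = FALSE)
    for (i in seq_len(nrow(patterns))) {
      votes <- unlist(patterns[i, ], use.names = FALSE)
      brute <- if (sum(votes == "Active") >= n / 2) "Active" else "Inactive"
      expect_equal(majority_vote(votes), brute)
    }
  }
})

test_that("weighted_vote weighs probabilities with tie-to-Active", {
  expect_equal(weighted_vote(c(0.9, 0.9, 0.1)), "Active")
  expect_equal(weighted_vote(c(0.2, 0.99), weights = c(1, 0)), "Inactive")
  expect_equal(weighted_vote(c(0.5, 0.5, 0.5)), "Active")  # exact tie
  expect_error(weighted_vote(c(0.5, 0.5), weights = c(0, 0)), "zero")
  expect_error(weighted_vote(numeric(0)), "empty")
})

test_that("predict.mcs_model thresholds inner probabilities at exactly 0.5", {
  tab <- toy_table()
  fc <- cluster_features(tab, k = 3)

  model <- constant_model(c(1, 1, 1), clustering = fc)
  expect_true(all(predict(model, tab)$labels == "Active"))

  # (0.6, 0.4, 0.4): one Active vote of three -> Inactive
  pred <- predict(constant_model(c(0.6, 0.4, 0.4), clustering = fc), tab)
  expect_true(all(pred$labels == "Inactive"))
  expect_equal(unname(pred$probs[1, ]), c(0.6, 0.4, 0.4))

  # (0.6, 0.5, 0.4): 0.5 is Inactive, so votes (A, I, I) -> Inactive
  pred <- predict(constant_model(c(0.6, 0.5, 0.4), clustering = fc), tab)
  expect_true(all(pred$labels == "Inactive"))

  # (0.6, 0.6, 0.4) -> Active
  pred <- predict(constant_model(c(0.6, 0.6, 0.4), clustering = fc), tab)
  expect_true(all(pred$labels == "Active"))

  # schema mismatch names the missing columns
  bad <- compound_table("Z", matrix(1L, 1, 1, dimnames = list(NULL, "zz")))
  expect_error(predict(model, bad), "missing model feature column")
})

test_that("optimize_cluster_classifier honours roster, objective and seed", {
  out <- generate_dataset(small_signal_spec(seed = 31, n = 100))
  tab <- out$table
  x <- feature_matrix(tab)
  y <- tab$labels

  # single-spec, single-point roster is returned as-is
  one <- optimize_cluster_classifier(
    x, y, roster = list(classifier_spec("naive_bayes", list(laplace = 1))),
    seed = 5)
  expect_equal(one$family, "naive_bayes")
  expect_equal(one$params$laplace, 1)

  # strong signal: cross-validated MCC is high
  best <- optimize_cluster_classifier(x, y, objective = "mcc",
                                      roster = fast_roster(), seed = 5)
  expect_gte(best$cv_score, 0.9)

  # determinism: same seed -> same choice and score
  again <- optimize_cluster_classifier(x, y, objective = "mcc",
                                       roster = fast_roster(), seed = 5)
  expect_equal(again$family, best$family)
  expect_equal(again$params, best$params)
  expect_equal(again$cv_score, best$cv_score)

  expect_error(optimize_cluster_classifier(x, y, roster = list()), "empty")
  expect_error(optimize_cluster_classifier(x, rep("Active", nrow(x)),
                                           roster = fast_roster()),
               "both classes")
  expect_error(optimize_cluster_classifier(x, y, cv_folds = 1,
                                           roster = fast_roster()),
               "cv_folds")
})

test_that("permuted labels yield near-zero cross-validated MCC", {
  out <- generate_dataset(small_signal_spec(seed = 32, n = 200))
  tab <- out$table
  set.seed(99)
  y_perm <- sample(tab$labels)
  null_fit <- optimize_cluster_classifier(
    feature_matrix(tab), y_perm, objective = "mcc",
    roster = fast_roster(), seed = 5)
  expect_lte(abs(null_fit$cv_mcc), 0.2)
})

test_that("build_mcs trains one classifier per cluster and round-trips", {
  out <- generate_dataset(small_signal_spec(seed = 33, n = 80))
  tab <- out$table
  fc <- cluster_features(tab, k = 3)
  model <- build_mcs(tab, fc, objective = "mcc", roster = fast_roster(),
                     cv_folds = 3, seed = 4)
  expect_length(model$classifiers, 3)
  expect_equal(vapply(model$classifiers, function(x) x$cluster_index, 1L),
               1:3)

  pred <- predict(model, tab)
  expect_equal(dim(pred$probs), c(n_compounds(tab), 3))
  expect_true(all(pred$probs >= 0 & pred$probs <= 1))

  path <- withr::local_tempfile(fileext = ".rds")
  save_mcs(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  reloaded <- load_mcs(path)
  pred2 <- predict(reloaded, tab)
  expect_identical(pred2$labels, pred$labels)
  expect_identical(pred2$probs, pred$probs)

  # same seed -> identical chosen specs
  model2 <- build_mcs(tab, fc, objective = "mcc", roster = fast_roster(),
                      cv_folds = 3, seed = 4)
  expect_equal(lapply(model2$classifiers, function(x) list(x$family, x$params)),
               lapply(model$classifiers, function(x) list(x$family, x$params)))

  unlabeled <- tab
  unlabeled$labels <- rep("Unknown", n_compounds(tab))
  expect_error(build_mcs(unlabeled, fc, roster = fast_roster()),
               "fully labeled")
})

test_that("combine_meta implements the AND/OR truth tables", {
  ids <- c("a", "b", "c", "d")
  p <- matrix(0.6, 4, 2, dimnames = list(ids, c("m_c1", "m_c2")))
  a <- make_prediction(ids, c("Active", "Active", "Inactive", "Inactive"), p)
  b <- make_prediction(ids, c("Active", "Inactive", "Active", "Inactive"),
                       matrix(0.7, 4, 2, dimnames = list(ids, c("p_c1", "p_c2"))))

  fp <- combine_meta(a, b, "minimize_fp")
  fn <- combine_meta(a, b, "minimize_fn")
  expect_equal(unname(fp$labels),
               c("Active", "Inactive", "Inactive", "Inactive"))
  expect_equal(unname(fn$labels),
               c("Active", "Active", "Active", "Inactive"))
  # probabilities concatenated in documented order: pred_a then pred_b
  expect_equal(colnames(fp$probs), c("m_c1", "m_c2", "p_c1", "p_c2"))
  expect_equal(ncol(fp$probs), 4)

  other <- make_prediction(c("a", "b", "c", "e"), rep("Active", 4), p)
  expect_error(combine_meta(a, other, "minimize_fp"), "different compound")
})

test_that("meta-model confusion algebra holds exactly on random evaluations", {
  set.seed(13)
  for (i in 1:25) {
    n <- 60
    ids <- sprintf("c%03d", 1:n)
    truth <- sample(c("Active", "Inactive"), n, replace = TRUE)
    pa <- make_prediction(ids, sample(c("Active", "Inactive"), n, TRUE),
                          matrix(runif(n), n, 1, dimnames = list(ids, "a1")))
    pb <- make_prediction(ids, sample(c("Active", "Inactive"), n, TRUE),
                          matrix(runif(n), n, 1, dimnames = list(ids, "b1")))
    truth_v <- stats::setNames(truth, ids)

    cm_a <- evaluate_predictions(pa, truth_v)$confusion
    cm_b <- evaluate_predictions(pb, truth_v)$confusion
    cm_and <- evaluate_predictions(combine_meta(pa, pb, "minimize_fp"),
                                   truth_v)$confusion
    cm_or <- evaluate_predictions(combine_meta(pa, pb, "minimize_fn"),
                                  truth_v)$confusion

    expect_lte(cm_and$fp, min(cm_a$fp, cm_b$fp))
    expect_lte(cm_or$fn, min(cm_a$fn, cm_b$fn))
    expect_gte(cm_and$tn, max(cm_a$tn, cm_b$tn))
    expect_gte(cm_or$tp, max(cm_a$tp, cm_b$tp))
  }
})

test_that("a failing roster family is skipped with a warning, not fatally", {
  # knn with k far larger than any training fold cannot fit
  out <- generate_dataset(small_signal_spec(seed = 35, n = 30))
  x <- feature_matrix(out$table)
  roster <- list(classifier_spec("knn", list(k = 10000L)),
                 classifier_spec("naive_bayes", list(laplace = 1)))
  expect_warning(
    fit <- optimize_cluster_classifier(x, out$table$labels, roster = roster,
                                       seed = 2),
    "skipped")
  expect_equal(fit$family, "naive_bayes")
})
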