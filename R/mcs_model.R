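#' Stratified cross-validation folds
#'
#' @param labels `"Active"`/`"Inactive"` vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold index per observation.
#' @keywords internal
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  folds
}

#' Select the best classifier for one feature cluster
#'
#' Evaluates every (family, hyperparameter) candidate of the roster by
#' stratified cross-validation on the cluster's feature submatrix, scores
#' the pooled out-of-fold predictions with the chosen objective, and
#' refits the maximizer on all rows.
#'
#' Hard labels for scoring use the fixed threshold: Active iff
#' probability > 0.5. With `objective = "ppv"` a degeneracy guard is
#' applied: among candidates within `1e-6` of the best cross-validated
#' PPV, the one with the highest cross-validated MCC wins (PPV alone can
#' be maximized by predicting a single positive). Remaining ties go to
#' roster order, then grid order.
#'
#' @param x numeric feature matrix for one cluster (rows = compounds).
#' @param labels `"Active"`/`"Inactive"` vector; both classes required.
#' @param objective `"mcc"` or `"ppv"`.
#' @param roster list of [classifier_spec()] objects.
#' @param cv_folds number of stratified folds (>= 2, default 5).
#' @param seed integer seed controlling fold assignment.
#' @param cluster_index optional cluster index stored on the result.
#' @return an object of class `trained_cluster_classifier`.
#' @export
optimize_cluster_classifier <- function(x, labels,
                                        objective = c("mcc", "ppv"),
                                        roster = default_roster(),
                                        cv_folds = 5, seed = 1,
                                        cluster_index = NA_integer_) {
  objective <- match.arg(objective)
  if (length(roster) == 0) abort("classifier roster is empty")
  stopifnot(all(vapply(roster, inherits, TRUE, "classifier_spec")))
  if (!is_count(cv_folds) || cv_folds < 2) abort("cv_folds must be >= 2")
  labels <- unname(labels)
  check_labels(labels, allow_unknown = FALSE)
  if (length(unique(labels)) < 2) abort("both classes must be present")
  if (nrow(x) != length(labels)) abort("x and labels differ in length")

  folds <- stratified_folds(labels, cv_folds, seed)
  candidates <- list()
  for (spec in roster) {
    for (params in expand_spec_grid(spec)) {
      candidates[[length(candidates) + 1L]] <-
        list(family = spec$family, params = params)
    }
  }

  results <- lapply(candidates, function(cand) {
    oof <- rep(NA_real_, length(labels))
    ok <- tryCatch({
      for (f in seq_len(cv_folds)) {
        test <- folds == f
        fit <- fit_learner(cand$family, x[!test, , drop = FALSE],
                           labels[!test], cand$params)
        oof[test] <- predict_learner(cand$family, fit,
                                     x[test, , drop = FALSE])
      }
      TRUE
    }, error = function(e) {
      warning(sprintf("classifier %s skipped: %s", cand$family,
                      conditionMessage(e)), call. = FALSE)
      FALSE
    })
    if (!ok) return(NULL)
    pred <- ifelse(oof > 0.5, "Active", "Inactive")
    cm <- confusion_matrix(labels, pred)
    list(cand = cand, cv_mcc = mcc(cm),
         cv_ppv = suppressWarnings(ppv(cm)))
  })
  results <- Filter(Negate(is.null), results)
  if (length(results) == 0) abort("every roster candidate failed to fit")

  score <- vapply(results, function(r) {
    if (objective == "mcc") r$cv_mcc else r$cv_ppv
  }, numeric(1))
  if (objective == "ppv") {
    near <- which(score >= max(score) - 1e-6)
    cv_mccs <- vapply(results[near], function(r) r$cv_mcc, numeric(1))
    best <- near[which.max(cv_mccs)]   # which.max keeps earliest on ties
  } else {
    best <- which.max(score)
  }
  chosen <- results[[best]]

  final_fit <- fit_learner(chosen$cand$family, x, labels, chosen$cand$params)
  structure(
    list(cluster_index = cluster_index, family = chosen$cand$family,
         params = chosen$cand$params, fit = final_fit,
         objective = objective, cv_score = score[best],
         cv_mcc = chosen$cv_mcc, columns = colnames(x)),
    class = "trained_cluster_classifier"
  )
}

#' @export
print.trained_cluster_classifier <- function(x, ...) {
  cat(sprintf("<trained_cluster_classifier> cluster %s: %s (%s), CV %s = %.4f\n",
              x$cluster_index, x$family,
              paste(names(x$params), unlist(x$params), sep = "=",
                    collapse = ", "),
              toupper(x$objective), x$cv_score))
  invisible(x)
}

#' Build a measure-guided multiple classifier system
#'
#' Trains one classifier per feature cluster (selected with
#' [optimize_cluster_classifier()] against the chosen objective) and
#' assembles them with a voting scheme into a single screening model.
#'
#' @param table a labeled [compound_table()] (training rows only).
#' @param clustering a [cluster_features()] result covering the table's
#'   feature columns.
#' @param objective `"mcc"` or `"ppv"` — the measure guiding per-cluster
#'   classifier selection.
#' @param roster list of [classifier_spec()] objects.
#' @param cv_folds,seed passed to [optimize_cluster_classifier()].
#' @param voting `"majority"` (default) or `"weighted"`.
#' @return an object of class `mcs_model`.
#' @export
build_mcs <- function(table, clustering, objective = c("mcc", "ppv"),
                      roster = default_roster(), cv_folds = 5, seed = 1,
                      voting = c("majority", "weighted")) {
  objective <- match.arg(objective)
  voting <- match.arg(voting)
  stopifnot(inherits(table, "compound_table"),
            inherits(clustering, "feature_clustering"))
  labels <- table$labels
  if (any(labels == "Unknown")) abort("training table must be fully labeled")

  classifiers <- lapply(seq_len(clustering$k), function(i) {
    cols <- clustering$clusters[[i]]
    optimize_cluster_classifier(feature_matrix(table, cols), labels,
                                objective = objective, roster = roster,
                                cv_folds = cv_folds, seed = seed,
                                cluster_index = i)
  })

  structure(
    list(objective = objective, classifiers = classifiers,
         voting = voting, clustering = clustering,
         version = as.character(utils::packageVersion("mcscreen"))),
    class = "mcs_model"
  )
}

#' @export
print.mcs_model <- function(x, ...) {
  cat(sprintf("<mcs_model> objective=%s, %d inner classifiers, %s voting\n",
              toupper(x$objective), length(x$classifiers), x$voting))
  for (cl in x$classifiers) print(cl)
  invisible(x)
}

#' Majority vote over class labels
#'
#' The compound is classified Active whenever the number of Active votes
#' is greater than or equal to the number of Inactive votes (ties go to
#' Active).
#'
#' @param votes non-empty character vector of `"Active"`/`"Inactive"`.
#' @return `"Active"` or `"Inactive"`.
#' @export
#' @examples
#' majority_vote(c("Active", "Inactive"))  # tie -> Active
majority_vote <- function(votes) {
  if (length(votes) == 0) abort("empty vote vector")
  check_labels(votes, allow_unknown = FALSE, what = "vote")
  if (sum(votes == "Active") >= sum(votes == "Inactive")) "Active" else "Inactive"
}

#' Weighted vote over Active probabilities
#'
#' The winner is the class with the highest overall weighted value:
#' Active iff \eqn{\sum_i w_i p_i \ge \sum_i w_i (1 - p_i)} (ties go to
#' Active, consistent with [majority_vote()]).
#'
#' @param probabilities Active probabilities in \[0, 1\].
#' @param weights non-negative weights, same length, not all zero.
#' @return `"Active"` or `"Inactive"`.
#' @export
weighted_vote <- function(probabilities, weights = rep(1, length(probabilities))) {
  if (length(probabilities) == 0) abort("empty probability vector")
  if (length(probabilities) != length(weights)) {
    abort("probabilities and weights differ in length")
  }
  if (any(weights < 0)) abort("weights must be non-negative")
  if (all(weights == 0)) abort("weights must not all be zero")
  if (sum(weights * probabilities) >= sum(weights * (1 - probabilities))) {
    "Active"
  } else {
    "Inactive"
  }
}

#' Screen a compound table with an MCS model
#'
#' Records each inner classifier's Active probability per compound
#' (vector order = cluster index order), derives inner hard labels with
#' the fixed threshold (Active iff probability > 0.5), and combines them
#' with the model's voting scheme. Weighted voting uses the inner
#' classifiers' cross-validated objective scores (clamped at zero) as
#' weights.
#'
#' @param object an [build_mcs()] model.
#' @param table a [compound_table()] whose columns cover the model's
#'   feature clustering.
#' @param ... unused.
#' @return an object of class `prediction_result`: list with `ids`,
#'   `labels` (named character) and `probs` (numeric matrix, one column
#'   per inner classifier).
#' @export
predict.mcs_model <- function(object, table, ...) {
  stopifnot(inherits(table, "compound_table"))
  needed <- unlist(object$clustering$clusters)
  missing <- setdiff(needed, feature_names(table))
  if (length(missing) > 0) {
    abort("table is missing model feature column(s): %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }

  probs <- vapply(object$classifiers, function(cl) {
    x <- feature_matrix(table, cl$columns)
    predict_learner(cl$family, cl$fit, x)
  }, numeric(n_compounds(table)))
  if (n_compounds(table) == 1) probs <- matrix(probs, nrow = 1)
  colnames(probs) <- sprintf("%s_c%d", object$objective,
                             seq_along(object$classifiers))
  rownames(probs) <- table$ids

  inner <- ifelse(probs > 0.5, "Active", "Inactive")
  final <- if (object$voting == "majority") {
    apply(inner, 1, majority_vote)
  } else {
    w <- pmax(vapply(object$classifiers, function(cl) cl$cv_score, 1), 0)
    if (all(w == 0)) w <- rep(1, length(w))
    apply(probs, 1, weighted_vote, weights = w)
  }

  structure(list(ids = table$ids,
                 labels = stats::setNames(final, table$ids),
                 probs = probs),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %d compounds, %d Active, %d inner probabilities each\n",
              length(x$ids), sum(x$labels == "Active"), ncol(x$probs)))
  invisible(x)
}

#' Combine two MCS predictions into a meta-model prediction
#'
#' `minimize_fp` labels a compound Active only when **both** constituent
#' models predict Active (logical AND — fewer false positives, at the
#' price of discarding candidates). `minimize_fn` labels it Active when
#' **either** model predicts Active (logical OR — fewer false negatives,
#' at the price of extra trials). Probability vectors are concatenated in
#' the order given (`pred_a` columns first); by convention the
#' MCC-optimized model is passed first.
#'
#' @param pred_a,pred_b [predict.mcs_model()] results over the same
#'   compound ids.
#' @param rule `"minimize_fp"` (AND) or `"minimize_fn"` (OR).
#' @return a `prediction_result` with concatenated probability columns.
#' @export
combine_meta <- function(pred_a, pred_b, rule = c("minimize_fp", "minimize_fn")) {
  rule <- match.arg(rule)
  stopifnot(inherits(pred_a, "prediction_result"),
            inherits(pred_b, "prediction_result"))
  if (!setequal(pred_a$ids, pred_b$ids)) {
    abort("predictions cover different compound sets")
  }
  ord <- match(pred_a$ids, pred_b$ids)
  a_act <- pred_a$labels == "Active"
  b_act <- (pred_b$labels == "Active")[ord]
  act <- if (rule == "minimize_fp") a_act & b_act else a_act | b_act

  probs <- cbind(pred_a$probs, pred_b$probs[ord, , drop = FALSE])
  rownames(probs) <- pred_a$ids
  structure(list(ids = pred_a$ids,
                 labels = stats::setNames(ifelse(act, "Active", "Inactive"),
                                          pred_a$ids),
                 probs = probs, rule = rule),
            class = "prediction_result")
}

#' Persist and restore MCS models
#'
#' `save_mcs()` writes the fitted model to `path` (RDS) together with a
#' JSON metadata sidecar (`<path>.json`: package version, objective,
#' chosen family and hyperparameters per cluster). `load_mcs()` restores
#' the model.
#'
#' @param model an `mcs_model`.
#' @param path file path (conventionally `.rds`).
#' @return `path` (save) or the restored `mcs_model` (load).
#' @export
save_mcs <- function(model, path) {
  stopifnot(inherits(model, "mcs_model"))
  saveRDS(model, path)
  meta <- list(
    format_version = 1L,
    package_version = model$version,
    objective = model$objective,
    voting = model$voting,
    classifiers = lapply(model$classifiers, function(cl) {
      list(cluster = cl$cluster_index, family = cl$family,
           params = cl$params, cv_score = cl$cv_score)
    })
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_mcs
#' @export
load_mcs <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mcs_model")) abort("'%s' does not contain an mcs_model", path)
  model
}

#' Evaluate predictions against known labels
#'
#' @param pred a `prediction_result`.
#' @param truth named character vector of true labels (names = compound
#'   ids) or a labeled [compound_table()].
#' @return a [classification_report()] list.
#' @export
evaluate_predictions <- function(pred, truth) {
  stopifnot(inherits(pred, "prediction_result"))
  if (inherits(truth, "compound_table")) truth <- compound_labels(truth)
  missing <- setdiff(pred$ids, names(truth))
  if (length(missing) > 0) abort("no truth label for id %s", missing[1])
  classification_report(unname(truth[pred$ids]), unname(pred$labels[pred$ids]))
}
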