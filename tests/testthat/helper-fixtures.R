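# Shared fixtures: everything is generated in code, no data files.

# tiny hand-written table: 3 compounds, 4 bits, 2 descriptors
toy_table <- function(labels = c("Active", "Inactive", "Active")) {
  compound_table(
    ids = c("AAA", "BBB", "CCC"),
    bits = matrix(c(1, 0, 1,
                    0, 1, 1,
                    0, 0, 0,
                    1, 1, 0), nrow = 3,
                  dimnames = list(NULL, paste0("b", 1:4))),
    descriptors = matrix(c(3, 7, 5, 0.12, -1.5, 2.25), nrow = 3,
                         dimnames = list(NULL, c("hbd", "logp"))),
    descriptor_types = c("discrete", "continuous"),
    labels = labels
  )
}

# strong class signal, small enough for fast model tests
small_signal_spec <- function(seed = 11, n = 150) {
  synthetic_spec(n_active = n, n_inactive = n, n_bits = 64,
                 n_informative_bits = 16, p_active = 0.8, p_inactive = 0.2,
                 n_discrete = 4, n_continuous = 4, seed = seed)
}

# cheap roster for pipeline-level tests
fast_roster <- function() {
  list(classifier_spec("glmnet", list(alpha = 0, lambda = 0.01)),
       classifier_spec("naive_bayes", list(laplace = 1)))
}

# an mcs_model whose inner classifiers emit fixed probabilities
constant_model <- function(probs, objective = "mcc", voting = "majority",
                           clustering) {
  classifiers <- lapply(seq_along(probs), function(i) {
    structure(list(cluster_index = i, family = "constant",
                   params = list(prob = probs[i]),
                   fit = list(prob = probs[i]), objective = objective,
                   cv_score = 1, cv_mcc = 1,
                   columns = clustering$clusters[[i]]),
              class = "trained_cluster_classifier")
  })
  structure(list(objective = objective, classifiers = classifiers,
                 voting = voting, clustering = clustering,
                 version = "test"),
            class = "mcs_model")
}

# prediction_result built directly from labels + probability matrix
make_prediction <- function(ids, labels, probs) {
  rownames(probs) <- ids
  structure(list(ids = ids, labels = stats::setNames(labels, ids),
                 probs = probs),
            class = "prediction_result")
}

# independent MCC oracle: Pearson correlation of 0/1 label vectors built
# from the counts (undefined correlation maps to the 0 convention)
mcc_oracle <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  r <- suppressWarnings(stats::cor(truth, pred))
  if (is.na(r)) 0 else r
}

random_confusion <- function() {
  confusion_from_counts(sample(0:60, 1), sample(0:60, 1),
                        sample(0:60, 1), sample(0:60, 1))
}
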