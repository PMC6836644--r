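#' Classifier specifications and the default roster
#'
#' A `classifier_spec` names a learner family and a (non-empty) grid of
#' candidate hyperparameter values to be searched by cross-validation.
#' All families in the default roster natively expose a class probability
#' for `"Active"`, as required by the probability-product ranking.
#'
#' Available families:
#' * `"glmnet"` — regularized logistic regression (`alpha`, `lambda`);
#' * `"lda"` — linear discriminant analysis (zero-variance columns
#'   dropped before fitting);
#' * `"naive_bayes"` — naive Bayes with Bernoulli likelihoods for binary
#'   columns and Gaussian likelihoods otherwise (`laplace` smoothing);
#' * `"knn"` — k-nearest neighbours with vote-fraction probabilities
#'   (`k`, odd values recommended);
#' * `"constant"` — emits a fixed Active probability (`prob`); a test and
#'   documentation double, never part of the default roster.
#'
#' @param family family name (see above).
#' @param grid named list mapping hyperparameter names to candidate value
#'   vectors; every combination is evaluated.
#' @return an object of class `classifier_spec`.
#' @export
#' @examples
#' classifier_spec("glmnet", list(alpha = c(0, 1), lambda = c(0.01, 0.001)))
classifier_spec <- function(family, grid = list()) {
  stopifnot(is.character(family), length(family) == 1L)
  known <- c("glmnet", "lda", "naive_bayes", "knn", "constant")
  if (!family %in% known) {
    abort("unknown classifier family '%s' (available: %s)", family,
          paste(known, collapse = ", "))
  }
  if (length(grid) == 0) abort("hyperparameter grid must be non-empty")
  if (is.null(names(grid)) || any(!nzchar(names(grid)))) {
    abort("grid entries must be named")
  }
  structure(list(family = family, grid = grid), class = "classifier_spec")
}

#' @rdname classifier_spec
#' @param families subset of the default families to include.
#' @export
default_roster <- function(families = c("glmnet", "lda", "naive_bayes", "knn")) {
  all <- list(
    glmnet = classifier_spec("glmnet",
                             list(alpha = c(0, 1), lambda = c(0.01, 0.001))),
    lda = classifier_spec("lda", list(tol = 1e-4)),
    naive_bayes = classifier_spec("naive_bayes", list(laplace = 1)),
    knn = classifier_spec("knn", list(k = c(5L, 15L)))
  )
  bad <- setdiff(families, names(all))
  if (length(bad) > 0) abort("unknown roster family: %s", paste(bad, collapse = ", "))
  unname(all[families])
}

# expand a spec's grid into a list of single-point parameter lists
expand_spec_grid <- function(spec) {
  g <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

as_class_factor <- function(y) factor(y, levels = c("Inactive", "Active"))

# --- family implementations -------------------------------------------------
# Each returns a fit object; predict_learner() returns P(Active) per row.

fit_learner <- function(family, x, y, params) {
  y <- as_class_factor(y)
  switch(family,
    glmnet = {
      pad <- ncol(x) < 2
      xx <- if (pad) cbind(x, .pad = 0) else x
      fit <- glmnet::glmnet(xx, y, family = "binomial",
                            alpha = params$alpha, lambda = params$lambda)
      list(fit = fit, pad = pad, lambda = params$lambda)
    },
    lda = {
      keep <- which(apply(x, 2, stats::var) > 0)
      if (length(keep) == 0) abort("lda: all columns are constant")
      fit <- MASS::lda(x[, keep, drop = FALSE], grouping = y,
                       tol = params$tol)
      list(fit = fit, keep = keep)
    },
    naive_bayes = fit_naive_bayes(x, y, laplace = params$laplace),
    knn = {
      if (params$k >= length(y)) abort("knn: k must be smaller than n")
      list(x = x, y = y, k = as.integer(params$k))
    },
    constant = list(prob = params$prob),
    abort("unknown classifier family '%s'", family)
  )
}

predict_learner <- function(family, fit, x) {
  p <- switch(family,
    glmnet = {
      xx <- if (fit$pad) cbind(x, .pad = 0) else x
      as.numeric(stats::predict(fit$fit, newx = xx, type = "response",
                                s = fit$lambda))
    },
    lda = {
      post <- stats::predict(fit$fit, x[, fit$keep, drop = FALSE])$posterior
      as.numeric(post[, "Active"])
    },
    naive_bayes = predict_naive_bayes(fit, x),
    knn = {
      pred <- FNN::knn(train = fit$x, test = x, cl = fit$y, k = fit$k,
                       prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "Active", win, 1 - win)
    },
    constant = rep(fit$prob, nrow(x)),
    abort("unknown classifier family '%s'", family)
  )
  # floor at 1e-12: a hard zero would make the product-of-probabilities
  # ranking undefined for a compound voted Active by the other classifiers
  pmin(pmax(as.numeric(p), 1e-12), 1)
}

# Naive Bayes: Bernoulli likelihood for binary columns, Gaussian otherwise.
fit_naive_bayes <- function(x, y, laplace = 1) {
  classes <- levels(y)
  binary <- apply(x, 2, function(v) all(v %in% c(0, 1)))
  var_floor <- 1e-9
  per_class <- lapply(classes, function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    list(
      n = nrow(xc),
      p1 = (colSums(xc[, binary, drop = FALSE]) + laplace) /
        (nrow(xc) + 2 * laplace),
      mu = colMeans(xc[, !binary, drop = FALSE]),
      v = pmax(apply(xc[, !binary, drop = FALSE], 2,
                     function(v) mean((v - mean(v))^2)), var_floor)
    )
  })
  names(per_class) <- classes
  prior <- vapply(per_class, function(p) p$n, 1) / length(y)
  list(classes = classes, binary = binary, per_class = per_class,
       prior = prior)
}

predict_naive_bayes <- function(fit, x) {
  loglik <- vapply(fit$classes, function(cl) {
    pc <- fit$per_class[[cl]]
    ll <- rep(log(fit$prior[[cl]]), nrow(x))
    if (any(fit$binary)) {
      xb <- x[, fit$binary, drop = FALSE]
      ll <- ll + as.numeric(xb %*% log(pc$p1) + (1 - xb) %*% log(1 - pc$p1))
    }
    if (any(!fit$binary)) {
      xc <- x[, !fit$binary, drop = FALSE]
      ll <- ll + rowSums(
        -0.5 * log(2 * pi * rep(pc$v, each = nrow(xc))) -
          sweep(xc, 2, pc$mu)^2 / (2 * rep(pc$v, each = nrow(xc)))
      )
    }
    ll
  }, numeric(nrow(x)))
  if (nrow(x) == 1) loglik <- matrix(loglik, 1, dimnames = list(NULL, fit$classes))
  1 / (1 + exp(loglik[, "Inactive"] - loglik[, "Active"]))
}
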