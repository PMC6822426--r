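#' Root mean squared prediction error
#'
#' \deqn{RMSE = \sqrt{\sum_i (\hat y_i - y_i)^2 / n}}
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @return RMSE as a single nonnegative number.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed differ in length")
  if (!length(predicted)) stop("empty vectors")
  sqrt(mean((as.numeric(predicted) - as.numeric(observed))^2))
}

#' Exact two-sided binomial test
#'
#' P-value for observing `k` successes in `n` Bernoulli(p0) trials,
#' two-sided by the standard convention of summing the probabilities of all
#' outcomes no more likely than the observed one.  Used to compare
#' per-sample win counts between regression models.
#'
#' @param k Observed success count.
#' @param n Number of trials.
#' @param p0 Null success probability, in (0, 1).
#' @return Two-sided p-value.
#' @export
exact_binomial_test <- function(k, n, p0 = 0.5) {
  if (n < 0 || k < 0 || k > n || k != round(k) || n != round(n))
    stop("require integer 0 <= k <= n")
  if (!(p0 > 0 && p0 < 1)) stop("p0 must lie in (0, 1)")
  probs <- stats::dbinom(0:n, n, p0)
  obs <- probs[k + 1L]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# ---- baseline model fitting -------------------------------------------

baseline_names <- c("opls", "lasso_cv", "random_forest",
                    "svr_linear", "svr_quadratic")

# Fit one named baseline on (X, y) and return a prediction closure plus a
# description of the hyperparameters actually used.  All models consume the
# same autoscaled matrix as O-PLS.
fit_baseline <- function(name, X, y, seed = 1) {
  switch(
    name,
    opls = {
      folds <- min(7, nrow(X))
      m <- fit_opls(X, y, folds = folds, seed = seed)
      list(predict = function(Xn) unname(predict(m, Xn)),
           details = list(folds = folds,
                          n_orthogonal = m$n_orthogonal,
                          Q2Y = m$stats$Q2Y))
    },
    lasso_cv = {
      m <- withr::with_seed(seed, glmnet::cv.glmnet(
        X, y, alpha = 1, nfolds = 5, standardize = FALSE,
        lambda.min.ratio = 1e-6))
      list(predict = function(Xn)
             drop(predict(m, Xn, s = "lambda.min")),
           details = list(nfolds = 5, lambda_min = m$lambda.min))
    },
    random_forest = {
      seeds <- seed * 100 + 1:5
      fits <- lapply(seeds, function(s)
        withr::with_seed(s, randomForest::randomForest(X, y, ntree = 100)))
      list(predict = function(Xn) {
             preds <- vapply(fits, function(f) predict(f, Xn),
                             numeric(nrow(Xn)))
             if (is.null(dim(preds))) mean(preds) else rowMeans(preds)
           },
           details = list(ntree = 100, seeds = seeds))
    },
    svr_linear = {
      m <- e1071::svm(X, y, type = "eps-regression", kernel = "linear",
                      cost = 1, epsilon = 0.1, scale = FALSE)
      list(predict = function(Xn) unname(predict(m, Xn)),
           details = list(kernel = "linear", cost = 1, epsilon = 0.1))
    },
    svr_quadratic = {
      m <- e1071::svm(X, y, type = "eps-regression", kernel = "polynomial",
                      degree = 2, coef0 = 1, cost = 1, epsilon = 0.1,
                      scale = FALSE)
      list(predict = function(Xn) unname(predict(m, Xn)),
           details = list(kernel = "polynomial", degree = 2, coef0 = 1,
                          cost = 1, epsilon = 0.1))
    },
    stop("unknown model name: ", name)
  )
}

# Win counting with the tie rule: strict wins count 1, ties count 1/2, and
# the binomial test receives the rounded count.
win_count_vs_reference <- function(ref_err, other_err) {
  wins <- sum(ref_err < other_err) + 0.5 * sum(ref_err == other_err)
  list(wins = wins, ties = sum(ref_err == other_err),
       k = round(wins), n = length(ref_err))
}

#' Fit and evaluate regression baselines on a train/test split
#'
#' Fits each requested model on the training data (random forest averaged
#' over 5 seeds), predicts the held-out test set, and reports per-model
#' RMSE, per-sample predictions and absolute errors, plus win counts and
#' exact binomial p-values against a reference model.
#'
#' @param train,test Lists with elements `x` (autoscaled matrix or
#'   [feature_matrix]) and `y` (response), feature-aligned.
#' @param model_specs Character vector drawn from `"opls"`, `"lasso_cv"`,
#'   `"random_forest"`, `"svr_linear"`, `"svr_quadratic"`.
#' @param reference Model name used for win-count comparisons (default
#'   `"opls"` when present, else the first spec).
#' @param seed Seed controlling all stochastic fits.
#' @return A `comparison_report`: list with `models` (per-model results)
#'   and `vs_reference` (win counts and p-values).
#' @export
run_baselines <- function(train, test, model_specs = baseline_names,
                          reference = NULL, seed = 1) {
  if (!length(model_specs)) stop("empty model specification list")
  bad <- setdiff(model_specs, baseline_names)
  if (length(bad)) stop("unknown model name: ", paste(bad, collapse = ", "))
  if (is.null(reference))
    reference <- if ("opls" %in% model_specs) "opls" else model_specs[1]
  Xtr <- as_matrix_x(train$x); ytr <- as_numeric_y(train$y, rownames(Xtr))
  Xte <- as_matrix_x(test$x)[, colnames(Xtr), drop = FALSE]
  yte <- as_numeric_y(test$y, rownames(Xte))

  models <- lapply(model_specs, function(nm) {
    fit <- fit_baseline(nm, Xtr, ytr, seed = seed)
    pred <- as.numeric(fit$predict(Xte))
    list(name = nm, predictions = stats::setNames(pred, rownames(Xte)),
         abs_errors = stats::setNames(abs(pred - yte), rownames(Xte)),
         rmse = rmse(pred, yte), details = fit$details)
  })
  names(models) <- model_specs
  ref_err <- models[[reference]]$abs_errors
  vs <- lapply(models[setdiff(model_specs, reference)], function(m) {
    wc <- win_count_vs_reference(ref_err, m$abs_errors)
    wc$p_value <- exact_binomial_test(wc$k, wc$n, 0.5)
    wc
  })
  structure(list(models = models, reference = reference, vs_reference = vs,
                 n_test = length(yte)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d models, reference = %s, n = %d\n",
              length(x$models), x$reference, x$n_test))
  for (m in x$models)
    cat(sprintf("  %-14s RMSE = %.4f\n", m$name, m$rmse))
  invisible(x)
}

#' Leave-one-out model comparison with binomial win-count testing
#'
#' For every sample, each model is refitted on the remaining n-1 samples
#' (hyperparameters re-tuned per fold) and its absolute prediction error
#' on the held-out sample recorded.  Models are then compared with the
#' reference by counting the samples where the reference error is strictly
#' smaller (ties split as half-wins, rounded for the test) and attaching a
#' two-sided exact binomial p-value at p0 = 0.5.
#'
#' @param x Autoscaled matrix or [feature_matrix].
#' @param y Response aligned with `x`.
#' @param model_specs Models to compare (see [run_baselines()]).
#' @param reference Name of the reference model; must be in `model_specs`.
#' @param seed Seed controlling all stochastic fits.
#' @return A `comparison_report` whose errors are LOOCV errors.
#' @export
loocv_compare <- function(x, y, model_specs = c("opls", "svr_linear"),
                          reference = "opls", seed = 1) {
  if (!length(model_specs)) stop("empty model specification list")
  if (!reference %in% model_specs)
    stop("reference must be among model_specs")
  bad <- setdiff(model_specs, baseline_names)
  if (length(bad)) stop("unknown model name: ", paste(bad, collapse = ", "))
  X <- as_matrix_x(x); yv <- as_numeric_y(y, rownames(X))
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples for leave-one-out comparison")

  errs <- matrix(NA_real_, n, length(model_specs),
                 dimnames = list(rownames(X), model_specs))
  preds <- errs
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- yv[-i]
    Xte <- X[i, , drop = FALSE]
    for (nm in model_specs) {
      fit <- fit_baseline(nm, Xtr, ytr, seed = seed)
      p <- as.numeric(fit$predict(Xte))
      preds[i, nm] <- p
      errs[i, nm] <- abs(p - yv[i])
    }
  }
  models <- lapply(model_specs, function(nm)
    list(name = nm, predictions = preds[, nm], abs_errors = errs[, nm],
         rmse = rmse(preds[, nm], yv)))
  names(models) <- model_specs
  vs <- lapply(models[setdiff(model_specs, reference)], function(m) {
    wc <- win_count_vs_reference(errs[, reference], m$abs_errors)
    wc$p_value <- exact_binomial_test(wc$k, wc$n, 0.5)
    wc
  })
  structure(list(models = models, reference = reference, vs_reference = vs,
                 n_test = n, protocol = "loocv"),
            class = "comparison_report")
}

#' Write a comparison report as delimited text plus a JSON twin
#'
#' @param report A `comparison_report`.
#' @param path_tsv,path_json Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_comparison_report <- function(report, path_tsv, path_json) {
  tab <- do.call(rbind, lapply(report$models, function(m)
    data.frame(model = m$name, rmse = m$rmse,
               stringsAsFactors = FALSE)))
  for (nm in names(report$vs_reference)) {
    tab$wins_vs_reference[tab$model == nm] <- report$vs_reference[[nm]]$k
    tab$p_value[tab$model == nm] <- report$vs_reference[[nm]]$p_value
  }
  utils::write.table(tab, path_tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(unclass(report), path_json, digits = NA,
                       auto_unbox = TRUE, force = TRUE)
  invisible(list(tsv = path_tsv, json = path_json))
}
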