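#' Restrict a feature matrix and response vector to their common samples
#'
#' Mirrors the study-design step of intersecting the proteomic, mutation and
#' drug-sensitivity datasets: both outputs cover exactly the shared sample
#' ids, in identical order (the feature matrix's order of first appearance).
#'
#' @param x A [feature_matrix].
#' @param y A [response_vector].
#' @return A list with elements `x` and `y` over the intersection.
#' @export
intersect_datasets <- function(x, y) {
  common <- intersect(sample_ids(x), sample_ids(y))
  if (!length(common))
    stop("no samples in common between feature matrix and response")
  x2 <- x[common, ]
  y2 <- response_vector(common, y$auc[common])
  list(x = x2, y = y2)
}

#' Filter features by detection rate
#'
#' Retains exactly the features observed (non-missing) in at least
#' `min_fraction` of the samples, the inclusion rule applied to RPPA
#' level-4 data before modelling.  Feature order is preserved.
#'
#' @param x A [feature_matrix].
#' @param min_fraction Minimum non-missing fraction, inclusive; default 0.25.
#' @return The filtered [feature_matrix].
#' @export
filter_by_detection <- function(x, min_fraction = 0.25) {
  if (!(min_fraction > 0 && min_fraction <= 1))
    stop("min_fraction must lie in (0, 1]")
  frac <- colMeans(!is.na(x$values))
  keep <- frac >= min_fraction
  if (!any(keep)) stop("no feature reaches the detection threshold")
  x[, which(keep)]
}

#' Impute remaining missing measurements
#'
#' After detection filtering some features still carry missing entries.
#' `feature_mean` replaces each with the feature's observed mean (neutral
#' under subsequent mean-centering); `constant` replaces with a fixed value
#' (e.g. 0 on an already-autoscaled matrix, which is equivalent to
#' feature-mean imputation before scaling).
#'
#' @param x A [feature_matrix].
#' @param strategy `"feature_mean"` (default) or `"constant"`.
#' @param constant Fill value for `strategy = "constant"`.
#' @return A [feature_matrix] without missing entries; the imputed positions
#'   are recorded in `attr(, "imputed")` as a sample/feature id table.
#' @export
impute_missing <- function(x, strategy = c("feature_mean", "constant"),
                           constant = 0) {
  strategy <- match.arg(strategy)
  v <- x$values
  miss <- which(is.na(v), arr.ind = TRUE)
  if (nrow(miss)) {
    if (strategy == "feature_mean") {
      mu <- colMeans(v, na.rm = TRUE)
      none <- !is.finite(mu)
      if (any(none))
        stop("feature(s) with no observed value under feature_mean: ",
             paste(colnames(v)[none], collapse = ", "),
             " (apply filter_by_detection first)")
      v[miss] <- mu[miss[, "col"]]
    } else {
      v[miss] <- constant
    }
  }
  out <- feature_matrix(v, x$feature_meta, x$sample_meta)
  attr(out, "imputed") <- data.frame(
    sample_id = rownames(v)[miss[, "row"]],
    feature_id = colnames(v)[miss[, "col"]],
    stringsAsFactors = FALSE
  )
  out
}

#' Scaling parameters of an autoscaled matrix
#'
#' @param mean,sd Named per-feature centering and scaling constants; `sd`
#'   uses the n-1 (sample) standard deviation and is strictly positive for
#'   every retained feature.
#' @param dropped Ids of zero-variance features removed during scaling.
#' @return An object of class `scaling_params`.
#' @export
scaling_params <- function(mean, sd, dropped = character()) {
  if (!identical(names(mean), names(sd)))
    stop("mean and sd must be named identically")
  if (any(sd <= 0)) stop("standard deviations must be strictly positive")
  structure(list(mean = mean, sd = sd, dropped = dropped,
                 variance = "sample (n-1)"),
            class = "scaling_params")
}

#' @export
print.scaling_params <- function(x, ...) {
  cat(sprintf("<scaling_params> %d features (%s variance), %d dropped\n",
              length(x$mean), x$variance, length(x$dropped)))
  invisible(x)
}

#' Mean-center and unit-variance scale each feature
#'
#' Autoscaling (z-scoring) as used before every model fit: each retained
#' feature ends with mean 0 and sample variance 1.  Zero-variance features
#' cannot be scaled and are dropped with a warning, recorded in the
#' returned `scaling_params`.
#'
#' @param x A [feature_matrix] without missing entries.
#' @return A list with `x` (the scaled [feature_matrix]) and `scaling`
#'   (a [scaling_params]).
#' @export
autoscale <- function(x) {
  v <- x$values
  if (anyNA(v)) stop("autoscale requires a complete matrix; impute first")
  mu <- colMeans(v)
  sd <- apply(v, 2, stats::sd)
  drop <- sd <= 0 | !is.finite(sd)
  if (any(drop))
    warning("dropping zero-variance feature(s): ",
            paste(colnames(v)[drop], collapse = ", "))
  keep <- which(!drop)
  if (!length(keep)) stop("all features have zero variance")
  sc <- scaling_params(mu[keep], sd[keep], dropped = colnames(v)[drop])
  scaled <- sweep(sweep(v[, keep, drop = FALSE], 2, mu[keep], "-"),
                  2, sd[keep], "/")
  list(x = feature_matrix(scaled, x$feature_meta, x$sample_meta), scaling = sc)
}

#' Apply or invert stored scaling to a raw-scale matrix
#'
#' @param values Numeric matrix with feature column names.
#' @param scaling A [scaling_params].
#' @return The transformed matrix over the scaling's features.
#' @export
apply_scaling <- function(values, scaling) {
  feats <- names(scaling$mean)
  miss <- setdiff(feats, colnames(values))
  if (length(miss))
    stop("matrix lacks scaled feature(s): ", paste(miss, collapse = ", "))
  v <- values[, feats, drop = FALSE]
  sweep(sweep(v, 2, scaling$mean, "-"), 2, scaling$sd, "/")
}

#' @rdname apply_scaling
#' @export
invert_scaling <- function(values, scaling) {
  feats <- names(scaling$mean)
  v <- values[, feats, drop = FALSE]
  sweep(sweep(v, 2, scaling$sd, "*"), 2, scaling$mean, "+")
}

#' Label samples as resistant or sensitive
#'
#' Applies the strict AUC threshold used to dichotomize drug response:
#' `auc < threshold` is `"resistant"`, everything else `"sensitive"`.
#'
#' @param y A [response_vector].
#' @param threshold Resistance cutoff; default 0.2.
#' @return Named character vector of labels.
#' @export
classify_resistance <- function(y, threshold = 0.2) {
  ifelse(y$auc < threshold, "resistant", "sensitive")
}

#' Stratified train/test split over tumor-type x resistance strata
#'
#' The split is random but constrained, mirroring the study design: every
#' stratum formed by crossing the binary tumor-type group (melanoma vs
#' non-melanoma) with the resistance label must appear at least once in
#' both the training and the test set.
#'
#' @param x A [feature_matrix] whose `sample_meta$tumor_type` is set.
#' @param y A [response_vector] aligned with `x`.
#' @param test_n Number of test samples; must be at least the number of
#'   strata.
#' @param seed Integer seed making the draw reproducible.
#' @param threshold Resistance cutoff passed to [classify_resistance()].
#' @return An object of class `split_spec` with `train_ids`, `test_ids`
#'   and the per-sample `strata`.
#' @export
stratified_split <- function(x, y, test_n = 6, seed = 1, threshold = 0.2) {
  ids <- sample_ids(x)
  if (!identical(ids, sample_ids(y)))
    stop("x and y must cover identical samples in identical order")
  tt <- x$sample_meta$tumor_type
  if (anyNA(tt)) stop("tumor_type missing for some samples")
  grp <- ifelse(tt == "melanoma", "melanoma", "non-melanoma")
  res <- classify_resistance(y, threshold)
  strata <- stats::setNames(paste(grp, res, sep = "/"), ids)
  tab <- table(strata)
  small <- names(tab)[tab < 2]
  if (length(small))
    stop("stratum with fewer than 2 members: ", paste(small, collapse = ", "))
  if (test_n < length(tab))
    stop(sprintf("test_n (%d) smaller than number of strata (%d)",
                 test_n, length(tab)))
  if (test_n > length(ids) - length(tab))
    stop("test_n leaves some stratum unrepresented in training")

  withr::with_seed(seed, {
    test <- character()
    train <- character()
    for (s in names(tab)) {
      members <- sample(ids[strata == s])
      test <- c(test, members[1L])
      train <- c(train, members[2L])
    }
    pool <- setdiff(ids, c(test, train))
    extra <- test_n - length(tab)
    if (extra > 0) {
      more <- sample(pool, extra)
      test <- c(test, more)
      pool <- setdiff(pool, more)
    }
    train <- c(train, pool)
  })
  structure(list(train_ids = ids[ids %in% train],
                 test_ids = ids[ids %in% test],
                 strata = strata, seed = seed),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> %d train / %d test, %d strata (seed %d)\n",
              length(x$train_ids), length(x$test_ids),
              length(unique(x$strata)), x$seed))
  invisible(x)
}
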