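# Small in-code fixtures shared across test files.

# a tiny complete feature matrix with tumor-type metadata
small_fm <- function(n = 8, p = 4, seed = 42) {
  withr::with_seed(seed, {
    v <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("S%02d", 1:n), sprintf("F%02d", 1:p)))
  })
  feature_matrix(v, sample_meta = data.frame(
    sample_id = rownames(v),
    tumor_type = rep(c("melanoma", "non-melanoma"), length.out = n),
    stringsAsFactors = FALSE))
}

# autoscaled matrix + response with an exact linear relationship
linear_dataset <- function(n = 21, p = 5, seed = 1, noise_sd = 0) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("S%02d", 1:n), sprintf("F%02d", 1:p)))
    beta <- seq_len(p) / p
    y <- drop(X %*% beta) + rnorm(n, sd = noise_sd)
  })
  X <- scale(X)
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  # rescale y into [0,1] so it can double as a response_vector when needed
  y01 <- (y - min(y)) / diff(range(y))
  list(X = X, y = stats::setNames(y01, rownames(X)))
}

# curate a generated dataset down to a fitted-model-ready scaled matrix
curate_sim <- function(sim, min_fraction = 0.25) {
  al <- intersect_datasets(sim$x, sim$y)
  sc <- autoscale(impute_missing(filter_by_detection(al$x, min_fraction)))
  list(x = sc$x, scaling = sc$scaling, y = al$y)
}

expect_no_na <- function(x) testthat::expect_false(anyNA(x))
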