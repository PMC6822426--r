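#' Fit an O-PLS model restricted to receptor-flagged features
#'
#' Builds the receptor-only model used for in-silico inhibition: the
#' feature matrix is subset to features flagged `is_receptor` (total and
#' phospho forms), imputed, autoscaled, and fitted on all samples — no
#' held-out set, matching how the receptor model in the motivating study
#' was trained on every cell line.
#'
#' @param x Raw-scale [feature_matrix] whose `feature_meta$is_receptor`
#'   marks receptor features.
#' @param y [response_vector] covering the samples of `x`.
#' @param ... Passed to [fit_opls()] (e.g. `folds`, `seed`).
#' @return An `opls_model` over the receptor subset, with stored scaling
#'   and raw-scale training minima for perturbation.
#' @export
build_receptor_model <- function(x, y, ...) {
  keep <- which(x$feature_meta$is_receptor)
  if (!length(keep)) stop("no receptor-flagged features in matrix")
  xr <- x[, keep]
  aligned <- intersect_datasets(xr, y)
  sc <- autoscale(impute_missing(aligned$x))
  message(sprintf("receptor model: %d features, %d samples",
                  ncol(sc$x$values), nrow(sc$x$values)))
  fit_opls(sc$x, aligned$y, scaling = sc$scaling, ...)
}

#' Simulate target inhibition by clamping features to training minima
#'
#' In-silico inhibition: for each target sample the targeted features
#' (e.g. phosphorylated EGFR/HER2/HER3) are replaced by their per-feature
#' minimum over the model's training matrix, on the raw measurement scale,
#' and the model is re-applied.  Untargeted features are untouched.  A
#' positive delta (perturbed minus baseline predicted AUC) means the
#' simulated inhibition is predicted to sensitize the sample.
#'
#' @param model An `opls_model` fitted with stored scaling (so raw-scale
#'   minima are defined).
#' @param x Raw-scale [feature_matrix] containing the target samples.
#' @param target_samples Sample ids to perturb.
#' @param target_features Feature ids to clamp; all must be model features.
#' @return A data frame of class `perturbation_result` with `sample_id`,
#'   `baseline`, `perturbed` and `delta`, plus attributes
#'   `target_features` and `clamp_values`.
#' @export
simulate_inhibition <- function(model, x, target_samples, target_features) {
  if (is.null(model$feature_min))
    stop("model lacks raw-scale training minima (fit with scaling=)")
  bad_f <- setdiff(target_features, model$feature_ids)
  if (length(bad_f))
    stop("feature(s) not in model: ", paste(bad_f, collapse = ", "))
  bad_s <- setdiff(target_samples, sample_ids(x))
  if (length(bad_s))
    stop("sample(s) not in matrix: ", paste(bad_s, collapse = ", "))
  if (!length(target_features))
    warning("empty target feature list; perturbation is the identity")

  raw <- x$values[target_samples, model$feature_ids, drop = FALSE]
  baseline <- predict(model, raw)
  clamp <- model$feature_min[target_features]
  pert <- raw
  if (length(target_features))
    pert[, target_features] <- rep(clamp, each = nrow(pert))
  perturbed <- predict(model, pert)

  out <- data.frame(sample_id = target_samples,
                    baseline = as.numeric(baseline),
                    perturbed = as.numeric(perturbed),
                    delta = as.numeric(perturbed - baseline),
                    stringsAsFactors = FALSE)
  class(out) <- c("perturbation_result", "data.frame")
  attr(out, "target_features") <- target_features
  attr(out, "clamp_values") <- clamp
  out
}

#' Net linear coefficient vector of an O-PLS model
#'
#' The fitted model is linear in the scaled features; this returns the
#' coefficient vector c such that the predicted (original-scale) response
#' is `y_center + y_scale * (x_scaled %*% c)`.  Useful as an algebraic
#' oracle for perturbation deltas.
#'
#' @param model An `opls_model`.
#' @return Named numeric vector over the model's features.
#' @export
opls_coefficients <- function(model) {
  # prediction filters x through (I - w_o p_o') per component, then takes
  # b * <x, w>; compose the projectors on w from the right
  v <- model$w
  K <- model$n_orthogonal
  if (K > 0) {
    for (k in rev(seq_len(K))) {
      # x_k = x_{k-1}(I - w_o p_o') => x_K w = x (I - w_o1 p_o1')...(I-...) w
      v <- v - model$W_o[, k] * sum(model$P_o[, k] * v)
    }
  }
  stats::setNames(model$b * v, model$feature_ids)
}
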