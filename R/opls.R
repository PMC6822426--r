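# ---- internal helpers --------------------------------------------------

as_matrix_x <- function(x) {
  if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
}

as_numeric_y <- function(y, ids = NULL) {
  v <- if (inherits(y, "response_vector")) y$auc else y
  if (!is.null(ids)) {
    if (!is.null(names(v))) {
      miss <- setdiff(ids, names(v))
      if (length(miss))
        stop("response missing sample(s): ", paste(miss, collapse = ", "))
      v <- v[ids]
    } else if (length(v) != length(ids)) {
      stop("unnamed response of length ", length(v),
           " cannot align with ", length(ids), " samples")
    }
  }
  as.numeric(v)
}

# Core NIPALS O-PLS extraction on an autoscaled X and centered/scaled y.
# Returns predictive weights/loadings/scores and up to n_orthogonal
# orthogonal components; stops early when no orthogonal variation remains.
opls_core <- function(X, yc, n_orthogonal) {
  covxy <- drop(crossprod(X, yc))
  nrm <- sqrt(sum(covxy^2))
  if (nrm < 1e-12) stop("zero covariance between features and response")
  w <- covxy / nrm

  p_feat <- ncol(X)
  W_o <- matrix(0, p_feat, 0)
  P_o <- matrix(0, p_feat, 0)
  T_o <- matrix(0, nrow(X), 0)
  Xd <- X
  k <- 0L
  while (k < n_orthogonal) {
    t <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t)) / sum(t^2)
    w_o <- p - sum(w * p) * w
    n_o <- sqrt(sum(w_o^2))
    if (n_o < 1e-10) break               # no response-orthogonal variation left
    w_o <- w_o / n_o
    t_o <- drop(Xd %*% w_o)
    p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o)
    P_o <- cbind(P_o, p_o)
    T_o <- cbind(T_o, t_o)
    k <- k + 1L
  }
  t <- drop(Xd %*% w)
  p <- drop(crossprod(Xd, t)) / sum(t^2)
  b <- sum(t * yc) / sum(t^2)
  list(w = w, p = p, t = t, b = b, W_o = W_o, P_o = P_o, T_o = T_o,
       n_orthogonal = k)
}

# Filter orthogonal variation out of a scaled matrix and project onto the
# predictive component.
opls_project <- function(core, Xs) {
  K <- core$n_orthogonal
  T_o <- matrix(0, nrow(Xs), K)
  if (K > 0) {
    for (k in seq_len(K)) {
      t_o <- drop(Xs %*% core$W_o[, k])
      Xs <- Xs - tcrossprod(t_o, core$P_o[, k])
      T_o[, k] <- t_o
    }
  }
  list(t = drop(Xs %*% core$w), T_o = T_o)
}

# ---- PLS1 reference ----------------------------------------------------

#' Fit a plain NIPALS PLS1 regression
#'
#' Single-response partial least squares by NIPALS with unit-norm weight
#' vectors.  Serves as the reference model for the orthogonal-free limit of
#' O-PLS and, at full rank, coincides with ordinary least squares.
#'
#' @param x Autoscaled numeric matrix (or [feature_matrix]) without missing
#'   values.
#' @param y Numeric response (or [response_vector]) aligned with `x`.
#' @param n_components Number of latent components to extract.
#' @return A list of class `pls1_model` with per-component weights `W`,
#'   loadings `P`, scores `T`, inner coefficients `b`, and the response
#'   center `y_center`.
#' @export
fit_pls1 <- function(x, y, n_components = 1) {
  X <- as_matrix_x(x)
  yv <- as_numeric_y(y, rownames(X))
  if (stats::sd(yv) == 0) stop("zero-variance response")
  if (n_components < 1) stop("n_components must be >= 1")
  y_center <- mean(yv)
  yc <- yv - y_center
  x_center <- colMeans(X)
  Xd <- sweep(X, 2, x_center)
  W <- P <- matrix(0, ncol(X), 0)
  Tm <- matrix(0, nrow(X), 0)
  b <- numeric(0)
  for (m in seq_len(n_components)) {
    covxy <- drop(crossprod(Xd, yc))
    nrm <- sqrt(sum(covxy^2))
    if (nrm < 1e-12) break
    w <- covxy / nrm
    t <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t)) / sum(t^2)
    bm <- sum(t * yc) / sum(t^2)
    Xd <- Xd - tcrossprod(t, p)
    yc <- yc - bm * t
    W <- cbind(W, w); P <- cbind(P, p); Tm <- cbind(Tm, t)
    b <- c(b, bm)
  }
  structure(list(W = W, P = P, T = Tm, b = b, y_center = y_center,
                 x_center = x_center, feature_ids = colnames(X)),
            class = "pls1_model")
}

#' @export
predict.pls1_model <- function(object, newdata, ...) {
  X <- as_matrix_x(newdata)[, object$feature_ids, drop = FALSE]
  yhat <- rep(object$y_center, nrow(X))
  Xd <- sweep(X, 2, object$x_center)
  for (m in seq_along(object$b)) {
    t <- drop(Xd %*% object$W[, m])
    yhat <- yhat + object$b[m] * t
    Xd <- Xd - tcrossprod(t, object$P[, m])
  }
  stats::setNames(yhat, rownames(X))
}

# ---- O-PLS -------------------------------------------------------------

#' Cross-validated predictive power (Q2Y) of an O-PLS structure
#'
#' Computes `Q2Y = 1 - PRESS/TSS` over a seeded k-fold partition, refitting
#' the full component structure (one predictive plus `n_orthogonal`
#' orthogonal components) on each training fold and accumulating squared
#' out-of-fold prediction errors.  TSS is the total centered sum of squares
#' of the response.  Q2Y may be negative; no flooring is applied.
#'
#' @param x Autoscaled numeric matrix (or [feature_matrix]).
#' @param y Response vector aligned with `x`.
#' @param n_orthogonal Number of orthogonal components in the structure.
#' @param folds Number of cross-validation folds (default 7).
#' @param seed Integer seed fixing the fold partition.
#' @param scale_y Whether the response is unit-variance scaled inside each
#'   fold fit (predictions are always back on the original scale).
#' @return Q2Y as a single number.
#' @export
cross_validate_q2 <- function(x, y, n_orthogonal = 0, folds = 7, seed = 1,
                              scale_y = TRUE) {
  X <- as_matrix_x(x)
  yv <- as_numeric_y(y, rownames(X))
  n <- nrow(X)
  if (folds > n) stop("more folds than samples")
  if (stats::sd(yv) == 0) stop("zero-variance response")
  fold_id <- withr::with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  press <- 0
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (sum(tr) < 2) stop("fold with fewer than 2 training samples")
    y_tr <- yv[tr]
    yc_center <- mean(y_tr)
    yc_scale <- if (scale_y) stats::sd(y_tr) else 1
    if (yc_scale == 0) stop("zero-variance response within a training fold")
    # features are re-centered on each training fold, mirroring the refit
    mu <- colMeans(X[tr, , drop = FALSE])
    core <- opls_core(sweep(X[tr, , drop = FALSE], 2, mu),
                      (y_tr - yc_center) / yc_scale, n_orthogonal)
    proj <- opls_project(core, sweep(X[!tr, , drop = FALSE], 2, mu))
    yhat <- core$b * proj$t * yc_scale + yc_center
    press <- press + sum((yv[!tr] - yhat)^2)
  }
  tss <- sum((yv - mean(yv))^2)
  1 - press / tss
}

#' Fit an O-PLS regression with sequential orthogonal-component selection
#'
#' Orthogonal projections to latent structures for a scalar response: one
#' predictive component plus response-orthogonal components extracted by
#' NIPALS, each candidate retained only if it raises the k-fold
#' cross-validated Q2Y by more than `delta_q2` (default 0.05), stopping at
#' the first failure.  The response-orthogonal scores are uncorrelated with
#' the training response by construction, which is what lets the model
#' separate, e.g., tumor-type-driven protein variation from
#' sensitivity-predictive variation.
#'
#' @param x Autoscaled, imputed numeric matrix or [feature_matrix].
#' @param y Response ([response_vector] or named numeric) aligned with `x`.
#' @param max_orthogonal Maximum orthogonal components to consider.
#' @param folds Cross-validation folds for Q2Y (default 7).
#' @param delta_q2 Minimum Q2Y increase to retain an orthogonal component.
#' @param seed Seed for the cross-validation fold partition.
#' @param scale_y Also unit-variance scale the response internally
#'   (recorded in the model; predictions are returned on the original
#'   scale either way).
#' @param scaling Optional [scaling_params] used to produce `x`; when
#'   supplied, [predict.opls_model()] accepts raw-scale matrices, and
#'   per-feature raw-scale training minima are stored for perturbation
#'   analyses.
#' @return An object of class `opls_model` with predictive weights `w`,
#'   loadings `p`, scores `t`, inner coefficient `b`, orthogonal `W_o`,
#'   `P_o`, `T_o`, fit statistics (`R2Y`, `Q2Y`, `R2X_pred`, `R2X_orthog`,
#'   the Q2Y path) and the stored scaling.
#' @export
fit_opls <- function(x, y, max_orthogonal = 3, folds = 7, delta_q2 = 0.05,
                     seed = 1, scale_y = TRUE, scaling = NULL) {
  X <- as_matrix_x(x)
  if (anyNA(X)) stop("x contains missing values; impute first")
  yv <- as_numeric_y(y, rownames(X))
  if (nrow(X) < folds) stop("fewer samples than cross-validation folds")
  if (stats::sd(yv) == 0) stop("zero-variance response")

  yn <- stats::setNames(yv, rownames(X))
  q2_path <- cross_validate_q2(X, yn, 0, folds, seed, scale_y)
  K <- 0L
  while (K < max_orthogonal) {
    q2_next <- cross_validate_q2(X, yn, K + 1L, folds, seed, scale_y)
    q2_path <- c(q2_path, q2_next)
    if (q2_next - q2_path[K + 1L] > delta_q2) K <- K + 1L else break
  }

  y_center <- mean(yv)
  y_scale <- if (scale_y) stats::sd(yv) else 1
  yc <- (yv - y_center) / y_scale
  x_center <- colMeans(X)
  Xc <- sweep(X, 2, x_center)
  core <- opls_core(Xc, yc, K)
  if (core$n_orthogonal < K) K <- core$n_orthogonal

  fitted_sc <- core$b * core$t
  r2y <- 1 - sum((yc - fitted_sc)^2) / sum(yc^2)
  ssx <- sum(Xc^2)
  r2x_pred <- sum(tcrossprod(core$t, core$p)^2) / ssx
  r2x_orth <- if (K > 0) {
    sum(vapply(seq_len(K), function(k)
      sum(tcrossprod(core$T_o[, k], core$P_o[, k])^2), numeric(1))) / ssx
  } else 0

  feature_min <- NULL
  if (!is.null(scaling)) {
    raw <- invert_scaling(X, scaling)
    feature_min <- apply(raw, 2, min)
  }

  structure(list(
    feature_ids = colnames(X),
    sample_ids = rownames(X),
    w = stats::setNames(core$w, colnames(X)),
    p = stats::setNames(core$p, colnames(X)),
    t = stats::setNames(core$t, rownames(X)),
    b = core$b,
    n_orthogonal = K,
    W_o = core$W_o, P_o = core$P_o, T_o = core$T_o,
    x_center = stats::setNames(x_center, colnames(X)),
    y_center = y_center, y_scale = y_scale, scale_y = scale_y,
    y_resid = stats::setNames(yc - fitted_sc, rownames(X)),
    scaling = scaling, feature_min = feature_min,
    stats = list(R2Y = r2y, Q2Y = q2_path[K + 1L],
                 R2X_pred = r2x_pred, R2X_orthog = r2x_orth,
                 q2_path = q2_path),
    cv_config = list(folds = folds, delta_q2 = delta_q2, seed = seed,
                     max_orthogonal = max_orthogonal)
  ), class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(paste0("<opls_model> %d features, %d training samples, ",
                     "1 predictive + %d orthogonal component(s)\n"),
              length(x$feature_ids), length(x$sample_ids), x$n_orthogonal))
  cat(sprintf("  R2Y = %.3f, Q2Y = %.3f, R2X_pred = %.3f, R2X_orthog = %.3f\n",
              x$stats$R2Y, x$stats$Q2Y, x$stats$R2X_pred, x$stats$R2X_orthog))
  invisible(x)
}

# Scale incoming data with the model's stored parameters (identity when the
# model was fitted without a scaling record) and align features by id.
scale_newdata <- function(object, newdata) {
  X <- as_matrix_x(newdata)
  miss <- setdiff(object$feature_ids, colnames(X))
  if (length(miss))
    stop("newdata lacks model feature(s): ", paste(miss, collapse = ", "))
  Xs <- if (!is.null(object$scaling)) apply_scaling(X, object$scaling)
        else X[, object$feature_ids, drop = FALSE]
  # training-set column centers are removed exactly as during the fit
  sweep(Xs, 2, object$x_center)
}

#' Predict the response for new samples from a fitted O-PLS model
#'
#' Applies the model's stored feature scaling, removes the orthogonal
#' variation using the stored orthogonal weights/loadings, projects onto
#' the predictive component and returns predictions on the original
#' response scale.
#'
#' @param object An `opls_model`.
#' @param newdata [feature_matrix] or numeric matrix; raw (unscaled) values
#'   when the model stores scaling parameters.
#' @param ... Unused.
#' @return Named numeric vector of predicted responses.
#' @export
predict.opls_model <- function(object, newdata, ...) {
  Xs <- scale_newdata(object, newdata)
  proj <- opls_project(object, Xs)
  stats::setNames(object$b * proj$t * object$y_scale + object$y_center,
                  rownames(Xs))
}

#' Predictive and orthogonal score coordinates for samples
#'
#' The coordinates behind the classic O-PLS scores plot: the predictive
#' score `t` orders samples by predicted response while orthogonal scores
#' `t_o` capture response-independent structure (tumor type, in the
#' motivating study).
#'
#' @param model An `opls_model`.
#' @param x [feature_matrix] or matrix of samples to project.
#' @return Data frame with `sample_id`, `t`, and one `t_o<k>` column per
#'   orthogonal component.
#' @export
scores_projection <- function(model, x) {
  Xs <- scale_newdata(model, x)
  proj <- opls_project(model, Xs)
  out <- data.frame(sample_id = rownames(Xs), t = proj$t,
                    stringsAsFactors = FALSE)
  if (model$n_orthogonal > 0) {
    to <- as.data.frame(proj$T_o)
    names(to) <- paste0("t_o", seq_len(model$n_orthogonal))
    out <- cbind(out, to)
  }
  out
}

# ---- VIP ---------------------------------------------------------------

#' Variable importance in projection (VIP) scores
#'
#' For each feature j, over the predictive and all retained orthogonal
#' components m with unit-norm weights w_m and explained response-variance
#' fractions SS_m = SS(b_m t_m)/SS(y):
#' \deqn{VIP_j = \sqrt{p \, \sum_m w_{mj}^2 SS_m \, / \, \sum_m SS_m}}
#' Orthogonal components contribute essentially nothing because their
#' scores are uncorrelated with the response (SS_m ~ 0).  By construction
#' the mean of the squared VIP scores equals 1; features with VIP > 1 are
#' flagged as important.
#'
#' @param model A fitted `opls_model`.
#' @return A data frame of class `vip_table` with `feature_id`, `vip`,
#'   the signed predictive `weight`, and logical `above_threshold`
#'   (VIP > 1).
#' @export
compute_vip <- function(model) {
  t <- model$t
  yv <- model$b * t + residual_y(model)  # centered/scaled training response
  ss_y <- sum(yv^2)
  W <- cbind(model$w, model$W_o)
  ss <- numeric(ncol(W))
  ss[1] <- sum((model$b * t)^2) / ss_y
  if (model$n_orthogonal > 0) {
    for (k in seq_len(model$n_orthogonal)) {
      t_o <- model$T_o[, k]
      b_o <- sum(t_o * yv) / sum(t_o^2)
      ss[k + 1] <- sum((b_o * t_o)^2) / ss_y
    }
  }
  p <- length(model$feature_ids)
  vip <- sqrt(p * drop(W^2 %*% ss) / sum(ss))
  out <- data.frame(feature_id = model$feature_ids, vip = vip,
                    weight = as.numeric(model$w),
                    above_threshold = vip > 1,
                    stringsAsFactors = FALSE)
  class(out) <- c("vip_table", "data.frame")
  out
}

# Centered/scaled training residual y - b t, reconstructed from the stored
# fit (the model keeps y only through its center/scale and fitted scores).
residual_y <- function(model) {
  if (is.null(model$y_resid)) stop("model lacks training residuals")
  model$y_resid
}

# ---- serialization -----------------------------------------------------

#' Serialize a fitted O-PLS model to JSON
#'
#' Writes all weights, loadings, scores, scaling parameters, statistics and
#' configuration at full floating-point precision so that
#' save -> load -> predict reproduces predictions bit-for-bit.
#'
#' @param model An `opls_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_opls <- function(model, path) {
  obj <- unclass(model)
  # matrices are stored column-concatenated with explicit dimensions so
  # the round trip is exact regardless of JSON row/column conventions
  for (nm in c("W_o", "P_o", "T_o"))
    obj[[nm]] <- list(dim = dim(model[[nm]]), data = as.numeric(model[[nm]]))
  obj$scaling <- if (!is.null(model$scaling)) {
    list(feature_id = names(model$scaling$mean),
         mean = unname(model$scaling$mean),
         sd = unname(model$scaling$sd),
         dropped = model$scaling$dropped)
  } else NULL
  # 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_opls
#' @export
load_opls <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("w", "p", "t", "feature_min", "y_resid", "x_center"))
    if (!is.null(obj[[nm]])) obj[[nm]] <- unlist(obj[[nm]])
  names(obj$w) <- names(obj$p) <- names(obj$x_center) <- obj$feature_ids
  names(obj$t) <- names(obj$y_resid) <- obj$sample_ids
  if (!is.null(obj$feature_min)) names(obj$feature_min) <- obj$feature_ids
  for (nm in c("W_o", "P_o", "T_o")) {
    m <- obj[[nm]]
    obj[[nm]] <- matrix(as.numeric(unlist(m$data)), nrow = m$dim[1],
                        ncol = m$dim[2])
  }
  if (!is.null(obj$scaling) && length(obj$scaling)) {
    ids <- as.character(unlist(obj$scaling$feature_id))
    obj$scaling <- scaling_params(
      stats::setNames(as.numeric(unlist(obj$scaling$mean)), ids),
      stats::setNames(as.numeric(unlist(obj$scaling$sd)), ids),
      dropped = as.character(unlist(obj$scaling$dropped))
    )
  } else obj$scaling <- NULL
  structure(obj, class = "opls_model")
}
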