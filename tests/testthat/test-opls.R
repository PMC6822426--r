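test_that("PLS1 explains a rank-1 response-aligned matrix with one component", {
  withr::with_seed(1, {
    t <- rnorm(12)
    p <- rnorm(6)
  })
  t <- t - mean(t)                      # matrix arrives column-centered
  X <- tcrossprod(t, p)
  dimnames(X) <- list(sprintf("S%02d", 1:12), sprintf("F%02d", 1:6))
  m <- fit_pls1(X, stats::setNames(t, rownames(X)), n_components = 1)
  fitted <- predict(m, X)
  expect_equal(unname(fitted), t, tolerance = 1e-10)
  expect_error(fit_pls1(X, rep(1, 12)), "zero-variance response")
})

test_that("full-rank PLS1 predictions coincide with ordinary least squares", {
  withr::with_seed(7, {
    X <- matrix(rnorm(30), 10, 3,
                dimnames = list(sprintf("S%02d", 1:10), paste0("F", 1:3)))
    y <- rnorm(10)
  })
  X <- scale(X, scale = FALSE)          # centered, as the fit assumes
  m <- fit_pls1(X, stats::setNames(y, rownames(X)), n_components = 3)
  ols <- stats::lm.fit(cbind(1, X), y)
  expect_equal(unname(predict(m, X)), unname(ols$fitted.values),
               tolerance = 1e-8)
})

test_that("O-PLS retains no orthogonal component when none is planted", {
  # clear predictive signal, no confound, and a modest feature count so
  # chance structure cannot masquerade as an orthogonal component
  for (s in 1:5) {
    sim <- generate_rppa_like(synthetic_spec(
      n_features = 40, orth_idx = 11:20, receptor_idx = 25:40,
      orth_strength = 0, noise_sd = 0.2, missing_fraction = 0,
      frac_poorly_detected = 0, seed = s))
    sc <- curate_sim(sim)
    m <- fit_opls(sc$x, sc$y, max_orthogonal = 1, seed = 5)
    expect_equal(m$n_orthogonal, 0L)
    # the first orthogonal candidate fails the retention rule outright
    expect_lt(diff(m$stats$q2_path[1:2]), 0.05)
  }
})

test_that("O-PLS with no orthogonal components equals one-component PLS1", {
  for (s in 1:3) {
    d <- linear_dataset(n = 20, p = 8, seed = s, noise_sd = 0.3)
    m_opls <- fit_opls(d$X, d$y, max_orthogonal = 0, seed = s, scale_y = FALSE)
    m_pls <- fit_pls1(d$X, d$y, n_components = 1)
    expect_lt(max(abs(predict(m_opls, d$X) - predict(m_pls, d$X))), 1e-8)
  }
})

test_that("fitting is invariant to joint permutation of the samples", {
  sim <- generate_rppa_like(synthetic_preset("confounded", seed = 2))
  sc <- curate_sim(sim)
  m1 <- fit_opls(sc$x, sc$y, seed = 4)
  perm <- withr::with_seed(9, sample(sample_ids(sc$x)))
  m2 <- fit_opls(sc$x[perm, ], sc$y$auc[perm], max_orthogonal = m1$n_orthogonal,
                 seed = 4)
  expect_equal(m2$w, m1$w, tolerance = 1e-10)
  expect_equal(m2$p, m1$p, tolerance = 1e-10)
  expect_equal(m2$b, m1$b, tolerance = 1e-10)
})

test_that("prediction reproduces the training fit and centers at the mean sample", {
  sim <- generate_rppa_like(synthetic_preset("default", seed = 8))
  sc <- curate_sim(sim)
  m <- fit_opls(sc$x, sc$y, seed = 2)
  fitted <- m$b * m$t * m$y_scale + m$y_center
  expect_equal(predict(m, sc$x), fitted, tolerance = 1e-10)

  # a sample sitting at the feature means scales to zero -> mean response
  x0 <- matrix(0, 1, ncol(sc$x$values),
               dimnames = list("mean_sample", colnames(sc$x$values)))
  expect_equal(unname(predict(m, x0)), mean(sc$y$auc), tolerance = 1e-10)

  expect_error(predict(m, sc$x$values[, -1, drop = FALSE]), "lacks model feature")
})

test_that("orthogonal components carry no response information", {
  sim <- generate_rppa_like(synthetic_preset("confounded", seed = 6))
  sc <- curate_sim(sim)
  m <- fit_opls(sc$x, sc$y, seed = 1)
  expect_gte(m$n_orthogonal, 1L)
  for (k in seq_len(m$n_orthogonal))
    expect_lt(abs(cor(m$T_o[, k], as.numeric(sc$y$auc))), 1e-6)

  # displacing a sample along an orthogonal loading leaves its prediction alone
  x1 <- sc$x$values[3, , drop = FALSE]
  for (c_mult in c(-2, 0.5, 10)) {
    x2 <- x1 + c_mult * m$P_o[, 1]
    expect_lt(abs(predict(m, x2) - predict(m, x1)), 1e-8)
  }
})

test_that("Q2Y behaves on noiseless, shuffled, and repeated data", {
  # an exactly latent-linear response is predicted near-perfectly
  sim <- generate_rppa_like(synthetic_spec(
    n_samples = 21, n_features = 30, planted_idx = 1:5,
    planted_signs = c(1, 1, -1, 1, -1), orth_idx = 6:10, orth_strength = 0,
    receptor_idx = 15:30, noise_sd = 0, missing_fraction = 0,
    frac_poorly_detected = 0, seed = 10))
  Xs <- suppressWarnings(curate_sim(sim))
  expect_gt(cross_validate_q2(Xs$x, Xs$y, 0, folds = 7, seed = 1), 0.99)
  d <- linear_dataset(n = 21, p = 4, seed = 10, noise_sd = 0)
  expect_identical(cross_validate_q2(d$X, d$y, 0, folds = 7, seed = 3),
                   cross_validate_q2(d$X, d$y, 0, folds = 7, seed = 3))

  # permutation null: no predictive signal, Q2Y at or below zero in the median
  q2s <- vapply(1:20, function(s) {
    ysh <- withr::with_seed(100 + s, sample(d$y))
    names(ysh) <- names(d$y)
    cross_validate_q2(d$X, ysh, 0, folds = 7, seed = s)
  }, numeric(1))
  expect_lte(median(q2s), 0)
})

test_that("VIP reduces to sqrt(p)*|w| with the mean-square-one identity", {
  # all-equal weights: every VIP is exactly 1
  withr::with_seed(2, t <- rnorm(15))
  Xeq <- matrix(rep(t, 4), 15, 4,
                dimnames = list(sprintf("S%02d", 1:15), paste0("F", 1:4)))
  Xeq <- Xeq + 0 # identical columns => w_j = 1/2 each
  meq <- fit_opls(Xeq, stats::setNames((t - min(t)) / diff(range(t)),
                                       rownames(Xeq)),
                  max_orthogonal = 0, folds = 5)
  expect_equal(compute_vip(meq)$vip, rep(1, 4), tolerance = 1e-8)

  # w = (1, 0): VIP = (sqrt(2), 0)
  withr::with_seed(3, {
    y <- rnorm(20)
    z <- rnorm(20)
  })
  z_orth <- residuals(lm(z ~ y))             # exactly uncorrelated with y
  X2 <- cbind(F1 = y, F2 = z_orth)
  rownames(X2) <- sprintf("S%02d", 1:20)
  m2 <- fit_opls(scale(X2), stats::setNames((y - min(y)) / diff(range(y)),
                                            rownames(X2)),
                 max_orthogonal = 0, folds = 5)
  expect_equal(compute_vip(m2)$vip, c(sqrt(2), 0), tolerance = 1e-6)
})

test_that("sum of squared VIP equals the feature count on random fits", {
  for (s in 1:10) {
    sim <- generate_rppa_like(synthetic_spec(n_samples = 20, n_features = 40,
                                             orth_idx = 11:20, seed = s))
    sc <- curate_sim(sim)
    m <- fit_opls(sc$x, sc$y, seed = s)
    v <- compute_vip(m)
    expect_equal(sum(v$vip^2), length(m$feature_ids), tolerance = 1e-8)
  }
})

test_that("scores projection matches stored training scores", {
  sim <- generate_rppa_like(synthetic_preset("confounded", seed = 12))
  sc <- curate_sim(sim)
  m <- fit_opls(sc$x, sc$y, seed = 1)
  sp <- scores_projection(m, sc$x)
  expect_equal(sp$t, unname(m$t), tolerance = 1e-10)
  expect_equal(sp$t_o1, unname(m$T_o[, 1]), tolerance = 1e-10)

  x0 <- matrix(0, 1, length(m$feature_ids),
               dimnames = list("zero", m$feature_ids))
  sp0 <- scores_projection(m, x0)
  expect_equal(unlist(sp0[, -1]), c(t = 0, t_o1 = 0), tolerance = 1e-12,
               ignore_attr = TRUE)

  dup <- sc$x$values[c(2, 2), ]
  rownames(dup) <- c("a", "b")
  spd <- scores_projection(m, dup)
  expect_identical(spd$t[1], spd$t[2])
})

test_that("model JSON serialization round-trips predictions exactly", {
  sim <- generate_rppa_like(synthetic_preset("default", seed = 21))
  sc <- curate_sim(sim)
  m <- fit_opls(sc$x, sc$y, seed = 2, scaling = sc$scaling)
  path <- withr::local_tempfile(fileext = ".json")
  save_opls(m, path)
  m2 <- load_opls(path)
  raw <- invert_scaling(sc$x$values, sc$scaling)
  expect_identical(predict(m2, raw), predict(m, raw))
  expect_identical(m2$stats$Q2Y, m$stats$Q2Y)
})

test_that("degenerate inputs are rejected", {
  d <- linear_dataset(n = 10, p = 3, seed = 1)
  expect_error(fit_opls(d$X, rep(0.5, 10), seed = 1), "zero-variance")
  expect_error(fit_opls(d$X[1:5, ], d$y[1:5], folds = 7), "fewer samples")
  Xna <- d$X; Xna[1, 1] <- NA
  expect_error(fit_opls(Xna, d$y), "missing")
})
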