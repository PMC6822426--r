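# generator regime with predictive signal planted on receptor phospho
# features so the receptor-only model has something to find
receptor_planted_spec <- function(seed, signs = rep(-1, 8)) {
  synthetic_spec(n_samples = 26, n_features = 60,
                 planted_idx = 45:52, planted_signs = signs,
                 orth_idx = 10:25, receptor_idx = 45:60,
                 noise_sd = 0.3, missing_fraction = 0, seed = seed)
}

test_that("receptor model trains on exactly the flagged features", {
  sim <- generate_rppa_like(receptor_planted_spec(1))
  m <- suppressMessages(build_receptor_model(sim$x, sim$y, seed = 1))
  expect_setequal(m$feature_ids, sim$truth$receptor_features)
  expect_length(m$feature_ids, 16)
  # trained on every sample, no held-out set
  expect_length(m$sample_ids, 26)
})

test_that("receptor subset identical to the full matrix reproduces fit_opls", {
  sim <- generate_rppa_like(synthetic_spec(
    n_samples = 20, n_features = 12, planted_idx = 1:4,
    planted_signs = c(1, -1, 1, -1), orth_idx = 5:8,
    receptor_idx = 1:12, missing_fraction = 0, seed = 3))
  m_rec <- suppressMessages(build_receptor_model(sim$x, sim$y, seed = 2))
  sc <- curate_sim(sim)
  m_full <- fit_opls(sc$x, sc$y, seed = 2, scaling = sc$scaling)
  expect_equal(m_rec$w[m_full$feature_ids], m_full$w, tolerance = 1e-10)
  expect_equal(m_rec$b, m_full$b, tolerance = 1e-10)

  no_rec <- sim$x
  no_rec$feature_meta$is_receptor <- FALSE
  expect_error(build_receptor_model(no_rec, sim$y), "no receptor")
})

test_that("clamping an already-minimal sample changes nothing", {
  sim <- generate_rppa_like(receptor_planted_spec(5))
  m <- suppressMessages(build_receptor_model(sim$x, sim$y, seed = 1))
  targets <- sim$truth$planted_features[1:3]
  # construct a sample already sitting at the training minima for the targets
  x_min <- sim$x
  x_min$values[1, targets] <- m$feature_min[targets]
  res <- simulate_inhibition(m, x_min, sample_ids(x_min)[1], targets)
  expect_equal(res$delta, 0, tolerance = 1e-12)
  expect_equal(as.numeric(attr(res, "clamp_values")),
               as.numeric(m$feature_min[targets]))
})

test_that("min-clamping resistance-associated phospho receptors raises predicted AUC", {
  raised <- vapply(1:20, function(s) {
    sim <- generate_rppa_like(receptor_planted_spec(100 + s))
    m <- suppressMessages(build_receptor_model(sim$x, sim$y, seed = s))
    # clamp planted negative-loading receptor features for the 3 most
    # resistant samples, as in a simulated pan-receptor inhibition
    targets <- intersect(sim$truth$planted_features, m$feature_ids)
    lows <- names(sort(sim$y$auc))[1:3]
    res <- simulate_inhibition(m, sim$x, lows, targets)
    all(res$delta > 0)
  }, logical(1))
  expect_true(all(raised))
})

test_that("perturbation deltas equal the linear-coefficient oracle", {
  sim <- generate_rppa_like(receptor_planted_spec(9))
  m <- suppressMessages(build_receptor_model(sim$x, sim$y, seed = 4))
  targets <- sim$truth$planted_features[c(2, 5)]
  samples <- sample_ids(sim$x)[4:6]
  res <- simulate_inhibition(m, sim$x, samples, targets)

  coef <- opls_coefficients(m)
  raw <- sim$x$values[samples, m$feature_ids, drop = FALSE]
  pert <- raw
  pert[, targets] <- rep(m$feature_min[targets], each = length(samples))
  disp <- apply_scaling(pert, m$scaling) - apply_scaling(raw, m$scaling)
  oracle <- drop(disp %*% coef[colnames(disp)]) * m$y_scale
  expect_lt(max(abs(res$delta - oracle)), 1e-8)

  # pure function: bit-identical on repeat
  expect_identical(res, simulate_inhibition(m, sim$x, samples, targets))
})

test_that("lowering a negative-weight feature never lowers the prediction", {
  ok <- vapply(1:20, function(s) {
    sim <- generate_rppa_like(receptor_planted_spec(300 + s))
    m <- suppressMessages(build_receptor_model(sim$x, sim$y, seed = s))
    coef <- opls_coefficients(m)
    neg <- names(coef)[which.min(coef)]
    x1 <- sim$x$values[2, m$feature_ids, drop = FALSE]
    x2 <- x1; x2[, neg] <- x2[, neg] - (0.5 + s / 10)
    predict(m, x2) >= predict(m, x1) - 1e-12
  }, logical(1))
  expect_true(all(ok))
})

test_that("perturbation validates ids and handles empty target lists", {
  sim <- generate_rppa_like(receptor_planted_spec(2))
  m <- suppressMessages(build_receptor_model(sim$x, sim$y, seed = 1))
  expect_error(simulate_inhibition(m, sim$x, "nope", m$feature_ids[1]),
               "sample.*nope")
  expect_error(simulate_inhibition(m, sim$x, sample_ids(sim$x)[1], "ghost"),
               "feature.*ghost")
  expect_warning(
    res0 <- simulate_inhibition(m, sim$x, sample_ids(sim$x)[1], character()),
    "identity")
  expect_equal(res0$delta, 0)
})
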