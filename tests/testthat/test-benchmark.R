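test_that("rmse matches hand arithmetic and its invariances", {
  expect_equal(rmse(c(0.1, 0.3), c(0.2, 0.2)), 0.1)
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(1, 2, 3) + 0.25, c(1, 2, 3)), 0.25)
  perm <- c(3, 1, 2)
  expect_equal(rmse(c(1, 4, 2)[perm], c(2, 2, 2)[perm]),
               rmse(c(1, 4, 2), c(2, 2, 2)))
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("exact binomial test agrees with brute-force enumeration", {
  # oracle: enumerate all 2^n outcome sequences, sum the probability of
  # those whose success count is no more likely than the observed count
  brute <- function(k, n, p0) {
    counts <- vapply(0:(2^n - 1), function(b)
      sum(as.integer(intToBits(b))[1:n]), numeric(1))
    probs <- p0^counts * (1 - p0)^(n - counts)
    p_of_count <- vapply(0:n, function(kk) sum(probs[counts == kk]),
                         numeric(1))
    sum(p_of_count[p_of_count <= p_of_count[k + 1] * (1 + 1e-7)])
  }
  for (n in c(1, 4, 7, 12)) {
    for (k in 0:n) {
      expect_equal(exact_binomial_test(k, n, 0.5), brute(k, n, 0.5),
                   tolerance = 1e-12)
      expect_equal(exact_binomial_test(k, n, 0.3), brute(k, n, 0.3),
                   tolerance = 1e-12)
    }
  }
  # spot values derivable by hand
  expect_equal(exact_binomial_test(3, 4, 0.5), 0.625)
  expect_equal(exact_binomial_test(5, 10, 0.5), 1)
  expect_equal(exact_binomial_test(10, 10, 0.5), 2 / 1024)
  expect_equal(exact_binomial_test(26, 26, 0.5), 2 * 0.5^26)
  expect_error(exact_binomial_test(5, 4), "0 <= k <= n")
})

test_that("binomial test agrees with the stats implementation", {
  for (n in c(6, 11, 26)) for (k in c(0, 2, n %/% 2, n))
    expect_equal(exact_binomial_test(k, n, 0.5),
                 stats::binom.test(k, n, 0.5)$p.value, tolerance = 1e-12)
})

test_that("win counting handles strict wins and splits ties", {
  wc <- oplsense:::win_count_vs_reference
  ref <- c(0.1, 0.2, 0.3, 0.4)
  other <- c(0.2, 0.2, 0.5, 0.1)   # win, tie, win, loss
  out <- wc(ref, other)
  expect_equal(out$wins, 2.5)
  expect_equal(out$ties, 1)
  expect_equal(out$k, 2)           # round-half-to-even on 2.5
  expect_equal(out$n, 4)
  # all ties: half the samples counted as wins
  all_tie <- wc(ref, ref)
  expect_equal(all_tie$wins, 2)
  expect_equal(all_tie$ties, 4)
})

test_that("linear-family baselines nail an exactly linear response", {
  # exactly latent-linear: every feature proportional to one latent score,
  # so a single predictive direction carries the whole response
  withr::with_seed(5, {
    t <- rnorm(30)
    a <- c(1, -0.5, 0.25, 2, -1, 0.1)
  })
  X <- outer(t, a)
  dimnames(X) <- list(sprintf("S%02d", 1:30), paste0("F", 1:6))
  X <- scale(X); y <- t
  y <- (y - min(y)) / diff(range(y))
  names(y) <- rownames(X)
  tr <- 1:22; te <- 23:30
  rep <- run_baselines(
    train = list(x = X[tr, ], y = y[tr]),
    test = list(x = X[te, ], y = y[te]),
    model_specs = c("opls", "lasso_cv", "svr_linear"), seed = 2)
  for (nm in c("opls", "lasso_cv"))
    expect_lt(rep$models[[nm]]$rmse, 0.01)
  # the epsilon-insensitive tube (epsilon = 0.1) lets SVR leave residuals of
  # up to epsilon unpenalized even on noiseless data, so its floor is epsilon
  expect_lt(rep$models$svr_linear$rmse, 0.1)
})

test_that("baseline bookkeeping: random forest seeds, errors on bad specs", {
  d <- linear_dataset(n = 20, p = 4, seed = 6, noise_sd = 0.2)
  rep <- run_baselines(train = list(x = d$X[1:14, ], y = d$y[1:14]),
                       test = list(x = d$X[15:20, ], y = d$y[15:20]),
                       model_specs = c("opls", "random_forest"), seed = 3)
  expect_length(rep$models$random_forest$details$seeds, 5)
  expect_true(all(c("wins", "p_value") %in%
                    names(rep$vs_reference$random_forest)))
  expect_error(run_baselines(list(), list(), character()), "empty model")
  expect_error(run_baselines(list(x = d$X, y = d$y),
                             list(x = d$X, y = d$y), "ridge"),
               "unknown model")
})

test_that("LOOCV comparison produces aligned per-sample errors and p-values", {
  d <- linear_dataset(n = 12, p = 3, seed = 8, noise_sd = 0.1)
  rep <- loocv_compare(d$X, d$y, model_specs = c("opls", "svr_linear"),
                       reference = "opls", seed = 1)
  expect_equal(rep$protocol, "loocv")
  expect_length(rep$models$opls$abs_errors, 12)
  vs <- rep$vs_reference$svr_linear
  # win count recomputed from the reported per-sample errors
  manual <- sum(rep$models$opls$abs_errors < rep$models$svr_linear$abs_errors) +
    0.5 * sum(rep$models$opls$abs_errors == rep$models$svr_linear$abs_errors)
  expect_equal(vs$wins, manual)
  expect_equal(vs$p_value, exact_binomial_test(round(manual), 12, 0.5))
  expect_error(loocv_compare(d$X, d$y, "opls", reference = "svr_linear"),
               "reference")
})

test_that("O-PLS LOOCV error is competitive with linear SVR on confounded data", {
  med_err <- vapply(1:10, function(s) {
    sim <- generate_rppa_like(synthetic_spec(n_samples = 24, n_features = 80,
                                             orth_idx = 11:30,
                                             orth_strength = 3, seed = s))
    sc <- curate_sim(sim)
    rep <- loocv_compare(sc$x, sc$y, model_specs = c("opls", "svr_linear"),
                         reference = "opls", seed = s)
    c(opls = median(rep$models$opls$abs_errors),
      svr = median(rep$models$svr_linear$abs_errors))
  }, numeric(2))
  expect_lte(median(med_err["opls", ]), median(med_err["svr", ]))
})
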