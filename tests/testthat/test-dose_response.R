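doses10 <- 33 / 2^(9:0)

test_that("percent inhibition implements the blank/vehicle normalization", {
  plate <- data.frame(
    arm = "drug1",
    well_type = c("blank", "blank", "vehicle", "vehicle",
                  rep("treated", 4)),
    dose_uM = c(0, 0, 0, 0, 1, 1, 2, 2),
    signal = c(100, 100, 1100, 1100, 1100, 1100, 100, 100))
  out <- percent_inhibition(plate)
  expect_equal(attr(out, "A_min"), 1000)
  # treated at the vehicle level: 0%; at the blank level: 100%
  expect_equal(out$inhibition, c(0, 100))
  expect_equal(out$n_wells, c(2L, 2L))

  # growth stimulation shows as negative inhibition
  plate2 <- plate
  plate2$signal[5:6] <- 100 + 1.5 * 1000
  expect_equal(percent_inhibition(plate2)$inhibition[1], -50)

  # invariant to rescaling the whole plate
  plate3 <- plate; plate3$signal <- plate3$signal * 7.5
  expect_equal(percent_inhibition(plate3)$inhibition, out$inhibition)

  bad <- plate; bad$signal[3:4] <- 50   # vehicle below blank
  expect_error(percent_inhibition(bad), "uninterpretable")
})

test_that("Hill fitting recovers planted parameters", {
  # noise-free: parameters recovered to < 1e-3 relative error
  plate <- generate_dose_response(1, 1.5, doses10, noise_sd = 0, seed = 1)
  inh <- percent_inhibition(plate)
  fit <- fit_hill(inh$dose_uM, inh$inhibition)
  expect_true(fit$reliable)
  expect_lt(abs(fit$ic50 - 1) / 1, 1e-3)
  expect_lt(abs(fit$hill - 1.5) / 1.5, 1e-3)
  # the fitted curve passes 50% at its own IC50 by construction
  expect_equal(predict(fit, fit$ic50), 50)

  # at 2% noise the IC50 lands within 10% in the median over 50 seeds
  rel_err <- vapply(1:50, function(s) {
    p <- generate_dose_response(2.5, 1.2, doses10, noise_sd = 2, seed = s)
    i <- percent_inhibition(p)
    f <- fit_hill(i$dose_uM, i$inhibition)
    abs(f$ic50 - 2.5) / 2.5
  }, numeric(1))
  expect_lt(median(rel_err), 0.1)
})

test_that("uninformative curves are flagged unreliable", {
  flat <- fit_hill(doses10, rep(0, 10))
  expect_false(flat$reliable)
  expect_error(fit_hill(c(1, 2, 4), c(10, 50, 90)), "4 distinct")
  expect_error(fit_hill(doses10, c(rep(10, 9), 150)), "100")
})

test_that("normalized AUC matches analytic limits and is monotone", {
  rng <- range(doses10)
  # saturating / inert profiles
  prof <- data.frame(dose_uM = doses10, inhibition = rep(100, 10))
  expect_equal(auc_from_curve(prof, rng), 1)
  prof$inhibition <- 0
  expect_equal(auc_from_curve(prof, rng), 0)

  # near-step curve centered at the geometric mean of the range: AUC ~ 1/2
  step <- structure(list(ic50 = sqrt(prod(rng)), hill = 1000, reliable = TRUE),
                    class = "hill_fit")
  expect_equal(auc_from_curve(step, rng), 0.5, tolerance = 0.01)

  # pointwise-larger profiles never lose AUC
  withr::with_seed(13, base <- runif(10, 0, 80))
  p1 <- data.frame(dose_uM = doses10, inhibition = base)
  p2 <- data.frame(dose_uM = doses10, inhibition = base + 5)
  expect_gte(auc_from_curve(p2, rng), auc_from_curve(p1, rng))

  # with fixed slope, AUC strictly decreases as IC50 grows through the range
  aucs <- vapply(c(0.5, 1, 2, 4, 8, 16), function(ic) {
    auc_from_curve(structure(list(ic50 = ic, hill = 1.5, reliable = TRUE),
                             class = "hill_fit"), rng)
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))

  expect_error(auc_from_curve(prof, c(2, 1)), "min < max")
})

test_that("Loewe index computes additivity arithmetic and gating", {
  mk_fit <- function(ic50) structure(list(ic50 = ic50, hill = 1,
                                          reliable = TRUE),
                                     class = "hill_fit")
  # x1 = 0.25 X1 and x2 = 0.25 X2: index 0.5, synergy
  res <- loewe_index(mk_fit(4), mk_fit(8), mk_fit(1), ratio = c(1, 2))
  expect_equal(res$loewe_index, 0.5)
  expect_true(res$synergy)
  # x1 = X1, x2 = X2: index 2, no synergy
  res2 <- loewe_index(mk_fit(4), mk_fit(8), mk_fit(4), ratio = c(1, 2))
  expect_equal(res2$loewe_index, 2)
  expect_false(res2$synergy)

  unrel <- structure(list(ic50 = 4, hill = 1, reliable = FALSE),
                     class = "hill_fit")
  expect_error(loewe_index(unrel, mk_fit(8), mk_fit(1)), "unreliable")
})

test_that("combination round trip recovers the planted Loewe index", {
  run <- function(interaction, seed = 5) {
    exp <- generate_combo_experiment(
      mono1 = c(ic50 = 2, hill = 1.5), mono2 = c(ic50 = 6, hill = 1.2),
      interaction = interaction, noise_sd = 1, seed = seed)
    analyze_synergy(exp$plates)$synergy
  }
  sham <- run(1)          # a drug combined additively with its partner
  expect_equal(sham$loewe_index, 1, tolerance = 0.05)
  expect_true(run(0.5)$synergy)
  expect_false(run(2)$synergy)
})
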