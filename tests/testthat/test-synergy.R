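test_that("fraction affected normalises against the solvent control", {
  expect_equal(fraction_affected(25, 100), 0.75)
  expect_equal(fraction_affected(c(80, 20), c(100, 100)), c(0.2, 0.8))
  expect_warning(fa0 <- fraction_affected(100, 100), "clamped")
  expect_equal(fa0, 1e-6)
  expect_warning(fa_over <- fraction_affected(120, 100), "clamped")
  expect_equal(fa_over, 1e-6)
  expect_error(fraction_affected(-1, 100), "non-negative")
  expect_error(fraction_affected(1, 0), "positive")
})

test_that("two-point median-effect fit is exact", {
  fit <- median_effect_fit(data.frame(dose = c(2, 6), fa = c(0.5, 0.75)))
  expect_equal(fit$m, 1, tolerance = 1e-9)
  expect_equal(fit$Dm, 2, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-12)
})

test_that("noiseless fits recover arbitrary (m, Dm) to 1e-9 with r = 1", {
  for (pars in list(c(0.6, 0.4), c(1.2, 2), c(2.5, 7), c(4, 0.05))) {
    tab <- make_dose_response(dose_response_config(
      m_true = pars[[1]], Dm_true = pars[[2]], noise_sd = 0,
      n_replicates = 1))
    fit <- median_effect_fit(tab)
    expect_equal(fit$m, pars[[1]], tolerance = 1e-9)
    expect_equal(fit$Dm, pars[[2]], tolerance = 1e-9)
    expect_equal(fit$r, 1, tolerance = 1e-9)
  }
})

test_that("replicates are averaged in fa space before the transform", {
  tab <- data.frame(dose = c(2, 2, 6, 6), fa = c(0.4, 0.6, 0.7, 0.8))
  fit <- median_effect_fit(tab)
  ref <- median_effect_fit(data.frame(dose = c(2, 6), fa = c(0.5, 0.75)))
  expect_equal(fit$m, ref$m, tolerance = 1e-12)
  expect_equal(fit$Dm, ref$Dm, tolerance = 1e-12)
})

test_that("median-effect fit rejects degenerate inputs and flags m <= 0", {
  expect_error(median_effect_fit(data.frame(dose = c(2, 2), fa = c(0.3, 0.5))),
               "at least 2 distinct doses")
  expect_error(median_effect_fit(data.frame(dose = c(1, 2), fa = c(0.5, 0.5))),
               "no effect gradient")
  expect_error(median_effect_fit(data.frame(dose = c(1, 2), fa = c(0, 0.5))),
               "strictly in")
  expect_warning(
    flat <- median_effect_fit(data.frame(dose = c(1, 2, 4),
                                         fa = c(0.8, 0.5, 0.2))),
    "not cytotoxic")
  expect_false(flat$valid)
})

test_that("dose_for_effect inverts the median-effect equation", {
  expect_equal(dose_for_effect(list(m = 3.3, Dm = 1.7), 0.5), 1.7)
  expect_equal(dose_for_effect(list(m = 1, Dm = 2), 0.75), 6)
  expect_equal(dose_for_effect(list(m = 2, Dm = 1), 0.9), 3)
  expect_error(dose_for_effect(list(m = -1, Dm = 2), 0.5), "invalid")
  expect_error(dose_for_effect(list(m = 1, Dm = 2), 1), "strictly in")
})

test_that("fa -> Dx -> fa round trip is the identity", {
  fit <- list(m = 1.9, Dm = 3.4)
  fa <- seq(0.05, 0.95, by = 0.05)
  dx <- dose_for_effect(fit, fa)
  back <- connscreen:::median_effect_fa(dx, fit$m, fit$Dm)
  expect_equal(back, fa, tolerance = 1e-9)
})

test_that("combination index satisfies sham, boundary and inversion identities", {
  f <- list(m = 1.4, Dm = 2.2)
  for (fa in seq(0.1, 0.9, by = 0.1)) {
    dx <- dose_for_effect(f, fa)
    pt <- combination_index(dx / 2, dx / 2, fa, f, f)
    expect_equal(pt$CI, 1, tolerance = 1e-6)
    expect_identical(pt$call, "additive")
  }

  # single-agent boundary: d2 = 0 reduces to d1/Dx1
  f2 <- list(m = 1, Dm = 5)
  dx1 <- dose_for_effect(f, 0.6)
  pt <- combination_index(dx1, 0, 0.6, f, f2)
  expect_equal(pt$CI, 1, tolerance = 1e-12)

  # generator inversion: noiseless gamma = 0.5 data give CI = 0.5 everywhere
  cfg <- combination_config(f, f2, gamma = 0.5, noise_sd = 0,
                            n_replicates = 1)
  tab <- make_combination(cfg)
  for (i in seq_len(nrow(tab))) {
    pt <- combination_index(tab$d1[[i]], tab$d2[[i]], tab$fa[[i]], f, f2)
    expect_equal(pt$CI, 0.5, tolerance = 1e-6)
    expect_identical(pt$call, "synergism")
  }

  anti <- combination_index(dx1, dose_for_effect(f2, 0.6), 0.6, f, f2)
  expect_identical(anti$call, "antagonism")  # CI = 2 here
  expect_equal(anti$CI, 2, tolerance = 1e-12)
  # nonexclusive form adds the cross term
  nonex <- combination_index(dx1, dose_for_effect(f2, 0.6), 0.6, f, f2,
                             nonexclusive = TRUE)
  expect_equal(nonex$CI, 3, tolerance = 1e-12)
})

test_that("Fa-CI table sorts by fa and summarises mean +/- SD", {
  f1 <- list(m = 1, Dm = 2); f2 <- list(m = 1, Dm = 2)
  p1 <- combination_index(0.3, 0.3, 0.5, f1, f2)   # CI = 0.3
  p2 <- combination_index(0.6, 0.4, 0.5, f1, f2)   # CI = 0.5
  fc <- fa_ci_table(list(p2, p1))
  expect_equal(fc$summary$mean_ci, 0.4, tolerance = 1e-12)
  expect_equal(fc$summary$sd_ci, sqrt(0.02), tolerance = 1e-9)
  expect_equal(fc$summary$sd_ci, 0.1414, tolerance = 1e-3)
  expect_identical(fc$table$CI, c(0.3, 0.5))  # sorted by fa then dose

  single <- fa_ci_table(p1)
  expect_identical(single$summary$sd_ci, 0)
  expect_false(single$summary$sd_defined)

  same <- fa_ci_table(list(p1, p1))
  expect_identical(same$summary$sd_ci, 0)
  expect_true(same$summary$sd_defined)
})
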