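test_that("all three generators are bit-identical under equal seeds", {
  cfg <- collection_config(n_genes = 60, signature_size = c(10, 10),
                           drugs = stats::setNames(rep(2L, 5), letters[1:5]),
                           planted_reversers = c(a = 2), seed = 1)
  s1 <- make_collection(cfg)
  s2 <- make_collection(cfg)
  expect_identical(s1$collection$values, s2$collection$values)
  expect_identical(s1$signature, s2$signature)
  expect_identical(s1$truth, s2$truth)

  dcfg <- dose_response_config(seed = 7)
  expect_identical(make_dose_response(dcfg), make_dose_response(dcfg))

  ccfg <- combination_config(list(m = 1.2, Dm = 2), list(m = 1, Dm = 5),
                             seed = 7)
  expect_identical(make_combination(ccfg), make_combination(ccfg))

  s3 <- make_collection(collection_config(
    n_genes = 60, signature_size = c(10, 10),
    drugs = stats::setNames(rep(2L, 5), letters[1:5]),
    planted_reversers = c(a = 2), seed = 2))
  expect_false(identical(s1$collection$values, s3$collection$values))
})

test_that("without planted drugs no profile's tag means shift from background", {
  cfg <- collection_config(n_genes = 300, signature_size = c(100, 100),
                           drugs = c(a = 3L, b = 3L), seed = 42)
  sim <- make_collection(cfg)
  # across the 100-gene up set of each profile, mean z is consistent with 0
  for (pid in sim$collection$meta$profile_id) {
    z_up <- sim$collection$values[sim$signature$up, pid]
    expect_gt(stats::t.test(z_up)$p.value, 0.01)
  }
})

test_that("planted reverser shifts the up-tag mean by -delta (LLN check)", {
  cfg <- collection_config(n_genes = 500, signature_size = c(50, 50),
                           drugs = c(rev = 1L, bg = 1L),
                           planted_reversers = c(rev = 3), noise_sd = 1,
                           seed = 5)
  sim <- make_collection(cfg)
  z_up <- sim$collection$values[sim$signature$up, "rev:CELL1:1"]
  se <- 1 / sqrt(50)
  expect_lt(abs(mean(z_up) - (-3)), 3 * se)
  z_down <- sim$collection$values[sim$signature$down, "rev:CELL1:1"]
  expect_lt(abs(mean(z_down) - 3), 3 * se)
  expect_identical(sim$truth$role[sim$truth$drug == "rev"], "reverser")
})

test_that("collection config invariants are enforced", {
  expect_error(collection_config(n_genes = 50, signature_size = c(30, 30)),
               "smaller than the signature")
  expect_error(collection_config(drugs = c(a = 1L, 2L)), "uniquely named")
  expect_error(collection_config(planted_reversers = c(nodrug = 1)),
               "absent from the drug list")
  expect_error(collection_config(
    drugs = c(a = 1L), planted_reversers = c(a = 0)), "must be > 0")
  expect_error(collection_config(
    drugs = c(a = 1L), planted_reversers = c(a = 1),
    planted_mimickers = c(a = 1)), "both reverser and mimicker")
})

test_that("noiseless dose-response follows the median-effect equation", {
  fa <- function(m, Dm, D) {
    make_dose_response(dose_response_config(
      m_true = m, Dm_true = Dm, doses = D, noise_sd = 0,
      n_replicates = 1))$fa
  }
  expect_equal(fa(1, 2, 2), 0.5)        # definition of the median-effect dose
  expect_equal(fa(1, 2, 6), 0.75)       # fa/fu = (6/2)^1 = 3
  expect_equal(fa(2, 1, 1 / 3), 0.1)    # fa/fu = (1/3)^2 = 1/9
})

test_that("noiseless fa increases strictly with dose when m > 0", {
  for (m in c(0.5, 1, 2.7)) {
    tab <- make_dose_response(dose_response_config(
      m_true = m, Dm_true = 3, doses = 2^seq(-4, 4, 0.5), noise_sd = 0,
      n_replicates = 1))
    expect_true(all(diff(tab$fa) > 0))
  }
})

test_that("combination generator inverts the Loewe sum exactly", {
  f <- list(m = 1, Dm = 2)
  # identical drugs at gamma = 1, d1 = d2 = 1: 1/Dx + 1/Dx = 1 => Dx = 2 => fa = 0.5
  tab <- make_combination(combination_config(
    f, f, dose_pairs = data.frame(d1 = 1, d2 = 1), gamma = 1, noise_sd = 0,
    n_replicates = 1))
  expect_equal(tab$fa, 0.5, tolerance = 1e-9)

  # sham combination: drug with itself at (Dx(f0)/2, Dx(f0)/2) returns fa = f0
  fsham <- list(m = 1.7, Dm = 0.8)
  for (f0 in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    dx <- dose_for_effect(fsham, f0)
    tab <- make_combination(combination_config(
      fsham, fsham, dose_pairs = data.frame(d1 = dx / 2, d2 = dx / 2),
      gamma = 1, noise_sd = 0, n_replicates = 1))
    expect_equal(tab$fa, f0, tolerance = 1e-8)
  }
})

test_that("combination config validates interaction strength and doses", {
  f <- list(m = 1, Dm = 2)
  expect_error(combination_config(f, f, gamma = 0), "gamma")
  expect_error(combination_config(list(m = -1, Dm = 2), f), "m > 0")
  expect_error(combination_config(
    f, f, dose_pairs = data.frame(d1 = 0, d2 = 0)), "positive total")
})

test_that("viability TSV round trip preserves the generated tables", {
  dir <- withr::local_tempdir()
  tab <- make_dose_response(dose_response_config(seed = 3))
  p <- file.path(dir, "plate.tsv")
  write_viability(tab, p)
  back <- read_viability(p)
  expect_equal(back$fa, tab$fa, tolerance = 1e-12)
  expect_identical(back$drug, tab$drug)

  ctab <- make_combination(combination_config(
    list(m = 1.2, Dm = 2, drug = "A"), list(m = 1, Dm = 5, drug = "B"),
    seed = 3))
  pc <- file.path(dir, "combo.tsv")
  write_combination(ctab, pc)
  backc <- read_combination(pc)
  expect_equal(backc$fa, ctab$fa, tolerance = 1e-12)
  expect_identical(backc$drug1, ctab$drug1)
})
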