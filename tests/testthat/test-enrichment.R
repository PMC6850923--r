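test_that("enrichment score reproduces the enumerated prefix-sum example", {
  r <- ranked_profile_list(paste0("p", 1:5), c(5, 4, 3, 2, 1))
  es <- enrichment_score(r, c("p1", "p3"), w = 0)
  expect_equal(es$running_sum, c(1 / 2, 1 / 6, 2 / 3, 1 / 3, 0),
               tolerance = 1e-12)
  expect_equal(es$ES, 2 / 3, tolerance = 1e-12)
  expect_identical(es$peak_index, 3L)
})

test_that("maximal and minimal concentration give ES = +1 / -1 exactly", {
  r <- ranked_profile_list(paste0("p", 1:20), 20:1)
  expect_identical(enrichment_score(r, paste0("p", 1:4), w = 0)$ES, 1)
  expect_identical(enrichment_score(r, paste0("p", 17:20), w = 0)$ES, -1)
  # and with metric weighting too
  expect_identical(enrichment_score(r, paste0("p", 1:4), w = 1)$ES, 1)
})

test_that("enrichment score rejects degenerate hit sets", {
  r <- ranked_profile_list(paste0("p", 1:5), 5:1)
  expect_error(enrichment_score(r, character(0)), "non-empty proper subset")
  expect_error(enrichment_score(r, paste0("p", 1:5)), "non-empty proper subset")
  expect_error(enrichment_score(r, "nope"), "absent")
  expect_error(enrichment_score(r, c("p1", "p1")), "duplicate")
  rz <- ranked_profile_list(paste0("p", 1:5), c(1, 0, 0, 0, -1))
  expect_error(enrichment_score(rz, c("p2", "p3"), w = 1), "N_R = 0")
})

test_that("running sum ends at zero and the fast path matches the full walk", {
  set.seed(31)
  for (i in 1:50) {
    N <- sample(10:100, 1)
    metric <- sort(rnorm(N), decreasing = TRUE)
    r <- ranked_profile_list(sprintf("p%03d", 1:N), metric)
    n_h <- sample(1:(N - 1), 1)
    hits <- sample(r$ids, n_h)
    for (w in c(0, 1)) {
      es <- enrichment_score(r, hits, w = w)
      expect_lt(abs(es$running_sum[[N]]), 1e-12)
      pos <- sort.int(match(hits, r$ids))
      fast <- connscreen:::es_from_positions(pos, abs(r$metric[pos])^w, N)
      expect_equal(fast$ES, es$ES, tolerance = 1e-12)
    }
  }
})

test_that("weighted enrichment agrees with the fgsea reference", {
  skip_if_not_installed("fgsea")
  set.seed(17)
  for (i in 1:25) {
    N <- sample(20:80, 1)
    metric <- sort(rnorm(N), decreasing = TRUE)
    r <- ranked_profile_list(sprintf("p%03d", 1:N), metric)
    pos <- sort.int(sample(N, sample(2:8, 1)))
    es <- enrichment_score(r, r$ids[pos], w = 1)
    ref <- fgsea::calcGseaStat(metric, selectedStats = pos, gseaParam = 1)
    expect_equal(es$ES, ref, tolerance = 1e-10)
  }
})

test_that("w = 0 enrichment depends only on hit positions", {
  set.seed(5)
  N <- 40
  pos <- sort.int(sample(N, 6))
  es_vals <- sapply(1:5, function(i) {
    metric <- sort(rnorm(N), decreasing = TRUE)
    r <- ranked_profile_list(sprintf("p%02d", 1:N), metric)
    enrichment_score(r, r$ids[pos], w = 0)$ES
  })
  expect_equal(max(es_vals) - min(es_vals), 0, tolerance = 1e-14)
})

test_that("permutation null is seed-deterministic and degenerate at N_h = N - 1", {
  r <- ranked_profile_list(sprintf("p%02d", 1:30), sort(rnorm(30), TRUE))
  n1 <- permutation_null(r, 3, w = 1, n_perm = 200, seed = 9)
  n2 <- permutation_null(r, 3, w = 1, n_perm = 200, seed = 9)
  expect_identical(n1, n2)
  expect_false(identical(n1, permutation_null(r, 3, w = 1, n_perm = 200,
                                              seed = 10)))
  # only N distinct hit sets exist when N_h = N - 1
  big <- permutation_null(r, 29, w = 0, n_perm = 500, seed = 1)
  expect_lte(length(unique(big)), 30L)
  expect_error(permutation_null(r, 30, n_perm = 10), "n_h < N")
})

test_that("NES and permutation p follow the stated conventions", {
  res <- normalize_and_test(0.6, c(0.3, 0.3, -0.5))
  expect_equal(res$NES, 2)

  # add-one rule: ES above all 999 same-sign permutations gives p = 1/1000
  null <- c(seq(0.001, 0.5, length.out = 999), -0.4)
  res2 <- normalize_and_test(0.9, null)
  expect_equal(res2$p_perm, 1 / 1000)

  res3 <- normalize_and_test(0, rnorm(100))
  expect_identical(res3$NES, 0)
  expect_identical(res3$p_perm, 1)

  res4 <- normalize_and_test(-0.5, c(0.1, 0.2))
  expect_identical(res4$NES, -Inf)
  expect_equal(res4$p_perm, 1 / 3)

  res5 <- normalize_and_test(0.2, c(0.1, 0.4, -0.3))
  expect_equal(res5$p_perm, (1 + 1) / (1 + 2))
  expect_true(sign(res5$NES) == sign(0.2))
})

test_that("screen ranks a dominant drug first and is reproducible", {
  sim <- make_collection(collection_config(
    n_genes = 200, signature_size = c(30, 30),
    drugs = stats::setNames(rep(3L, 10), sprintf("d%02d", 1:10)),
    planted_reversers = c(d05 = 3), seed = 2))
  rk <- screen_drugs(sim$collection, sim$signature, w = 1, n_perm = 200,
                     seed = 2, reverse_query = TRUE)
  expect_identical(rk$drug[[1]], "d05")
  expect_true(all(rk$p_perm > 0 & rk$p_perm <= 1))
  expect_true(all(sign(rk$NES) == sign(rk$ES) |
                    (rk$ES == 0 & rk$NES == 0)))
  rk2 <- screen_drugs(sim$collection, sim$signature, w = 1, n_perm = 200,
                      seed = 2, reverse_query = TRUE)
  expect_identical(rk, rk2, ignore_attr = TRUE)

  # a planted mimicker lands at the bottom of the reverse-query screen
  simm <- make_collection(collection_config(
    n_genes = 200, signature_size = c(30, 30),
    drugs = stats::setNames(rep(3L, 10), sprintf("d%02d", 1:10)),
    planted_mimickers = c(d03 = 3), seed = 3))
  rkm <- screen_drugs(simm$collection, simm$signature, w = 1, n_perm = 200,
                      seed = 3, reverse_query = TRUE)
  expect_identical(rkm$drug[[nrow(rkm)]], "d03")

  one <- make_collection(collection_config(
    n_genes = 50, signature_size = c(5, 5), drugs = c(a = 3L), seed = 1))
  expect_error(screen_drugs(one$collection, one$signature),
               "at least 2 distinct perturbagens")
})

test_that("a drug occupying all top ranks attains ES = 1 in the screen", {
  sim <- make_collection(collection_config(
    n_genes = 300, signature_size = c(50, 50),
    drugs = c(strong = 3L, inert = 3L),
    planted_reversers = c(strong = 4), seed = 6))
  rk <- screen_drugs(sim$collection, sim$signature, w = 0, n_perm = 200,
                     seed = 6, reverse_query = TRUE)
  expect_identical(rk$ES[rk$drug == "strong"], 1)
})
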