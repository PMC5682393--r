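test_that("observed mismatch equals brute-force pair enumeration", {
  # monomorphic -> point mass at 0
  hs <- toy_hapset(matrix(4L, 1, 1, dimnames = list("P1", "H1")), "AAAA")
  om <- observed_mismatch(hs, matrix(0L, 1, 1))
  expect_equal(om$freq, 1)

  # two copies at distance 3 -> point mass at 3
  hs2 <- toy_hapset(matrix(c(1L, 1L), 1, 2,
                           dimnames = list("P1", c("H1", "H2"))),
                    c("AAAA", "TTTA"))
  expect_equal(observed_mismatch(hs2, hamming_matrix(hs2))$freq,
               c(0, 0, 0, 1))

  # 6-copy toy vs enumeration over all 15 pairs
  m <- rand_poly_aln(6, 20, n_var = 6, seed = 55)
  hs3 <- quick_hapset(m)
  om3 <- observed_mismatch(hs3, hamming_matrix(hs3))
  diffs <- c()
  for (i in 1:5) for (j in (i + 1):6) diffs <- c(diffs, sum(m[i, ] != m[j, ]))
  want <- tabulate(diffs + 1, nbins = max(diffs) + 1) / 15
  expect_equal(om3$freq, want)
  expect_equal(om3$mean_diff, mean(diffs))
})

test_that("expected mismatch has its closed forms and normalizes", {
  # tau = 0, theta0 = theta1 = 1: F_i = 1/2^(i+1)
  em <- expected_mismatch(0, 1, 1, 10)
  expect_equal(em$prob, 1 / 2^(1:11), tolerance = 1e-12)

  # theta0 = theta1 = theta is the equilibrium for any tau
  em2 <- expected_mismatch(7, 2, 2, 15)
  expect_equal(em2$prob, 2^(0:15) / 3^(1:16), tolerance = 1e-10)

  # wave crest near tau when theta0 = 0 and theta1 large
  for (tau in c(3, 5, 8)) {
    em3 <- expected_mismatch(tau, 0, 5000, 30)
    expect_lte(abs(which.max(em3$prob) - 1 - tau), 1)
  }

  # probabilities + tail sum to one for random parameter draws
  set.seed(13)
  for (r in 1:1000) {
    th <- sort(runif(2, 0, 30))
    em4 <- expected_mismatch(runif(1, 0, 20), th[1], th[2], 40)
    expect_lt(abs(sum(em4$prob) + em4$tail - 1), 1e-9)
    expect_true(all(em4$prob >= 0))
  }

  expect_error(expected_mismatch(-1, 0, 1, 5), "tau")
  expect_error(expected_mismatch(1, 2, 1, 5), "theta")
})

test_that("the least-squares fit recovers noise-free model curves", {
  for (tau in c(2, 5, 10)) {
    curve <- expected_mismatch(tau, 1, 50, 35)$prob
    fit <- fit_sudden_expansion(curve)
    expect_lte(abs(fit$tau - tau), 0.5)
    expect_lt(fit$ssd, 1e-4)
  }
  # monomorphic -> boundary flag
  fit0 <- fit_sudden_expansion(c(1))
  expect_true(fit0$degenerate)
  expect_equal(fit0$tau, 0)
})

test_that("strong expansion drives the fitted theta1 to the open cap", {
  hits <- 0
  for (r in 1:10) {
    sim <- simulate_coalescent(n = 30, theta = 50,
                               expansion = list(growth = 5000, tau = 3),
                               seed = 950 + r)
    hs <- collapse_haplotypes(filter_sites(sim$alignment), sim$popmap)
    fit <- fit_sudden_expansion(observed_mismatch(hs, hamming_matrix(hs))$freq)
    if (fit$theta1 >= 99999) hits <- hits + 1
  }
  expect_gte(hits, 5)
})

test_that("raggedness follows the direct sum with trailing zero", {
  # two-point alternating distribution {0.5, 0, 0.5}:
  # (0-.5)^2 + (.5-0)^2 + (0-.5)^2 = 0.75 by hand enumeration
  expect_equal(raggedness(c(0.5, 0, 0.5)), 0.75)
  # smooth geometric curve is much less ragged
  expect_lt(raggedness(expected_mismatch(0, 3, 3, 20)$prob), 0.1)
  expect_equal(raggedness(c(1)), 1)  # point mass at 0 drops straight to 0
})

test_that("mismatch bootstrap p-values behave and are seeded", {
  sim <- simulate_coalescent(n = 25, theta = 10,
                             expansion = list(growth = 200, tau = 5),
                             seed = 4242)
  hs <- collapse_haplotypes(filter_sites(sim$alignment), sim$popmap)
  d <- hamming_matrix(hs)
  expect_warning(r1 <- mismatch_test(hs, d, n_boot = 60, seed = 3), "coarse")
  expect_warning(r2 <- mismatch_test(hs, d, n_boot = 60, seed = 3), "coarse")
  expect_identical(r1$p_SSD, r2$p_SSD)
  expect_identical(r1$tau_ci, r2$tau_ci)
  # data simulated under the fitted family should not reject it
  expect_gt(r1$p_SSD, 0.05)
  expect_equal(r1$modality, "unimodal")
})

test_that("expansion-time dating reproduces the published conversion", {
  et <- expansion_time(2.46, mu = c(1e-9, 3e-9), k = 1605, g = 3)
  expect_equal(et$t[1], 127725.9, tolerance = 1e-6)
  expect_equal(et$t[2], 42575.29, tolerance = 1e-6)
  et2 <- expansion_time(1.0, mu = 1e-9, k = 1605, g = 3)
  expect_equal(et2$t, 51921.08, tolerance = 1e-6)
  expect_equal(expansion_time(0)$t, c(0, 0))

  # t(mu) * mu constant; tripling the rate divides the age by three exactly
  grid <- expansion_time(3.3, mu = c(1e-9, 2e-9, 3e-9), k = 1200, g = 3)
  expect_equal(grid$t * grid$mu, rep(grid$t[1] * grid$mu[1], 3))
  expect_equal(grid$t[3], grid$t[1] / 3)
  expect_error(expansion_time(1, mu = 0), "positive")
})

test_that("expansion histories look unimodal, ancient splits bimodal", {
  uni <- 0; dneg <- 0; n_rep <- 25
  for (r in 1:n_rep) {
    sim <- simulate_coalescent(n = 25, theta = 10,
                               expansion = list(growth = 200, tau = 5),
                               seed = 10000 + r)
    flt <- filter_sites(sim$alignment)
    hs <- collapse_haplotypes(flt, sim$popmap)
    om <- observed_mismatch(hs, hamming_matrix(hs))
    if (mismatch_modality(om$freq)$modality == "unimodal") uni <- uni + 1
    if (isTRUE(tajimas_d(flt)$D < 0)) dneg <- dneg + 1
  }
  expect_gte(uni / n_rep, 0.8)
  expect_gte(dneg / n_rep, 0.8)

  bim <- vapply(1:15, function(r) {
    fix <- make_structured_fixture("two_clades", seed = 11000 + r)
    hs <- collapse_haplotypes(filter_sites(fix$alignment), fix$popmap)
    mismatch_modality(observed_mismatch(hs, hamming_matrix(hs))$freq)$modality
  }, "")
  expect_gte(mean(bim == "multimodal"), 0.6)
})
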