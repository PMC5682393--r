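test_that("unbiased gene diversity reproduces printed per-population values", {
  # internally consistent rows of the published per-population table
  cases <- list(list(c(8, 2), 0.36),              # D
                list(c(5, 7), 0.53),              # G
                list(c(2, 4, 2, 2), 0.80),        # J, cpDNA
                list(c(2, 2, 1), 0.80),           # U
                list(c(7, 3), 0.47),              # LC
                list(c(1, 9, 5), 0.56),           # LE
                list(c(2, 3), 0.60),              # LP
                list(c(3, 3), 0.60),              # KZ
                list(c(1, 2, 3, 1, 2, 1), 0.89))  # J, ITS
  for (cs in cases)
    expect_equal(round(haplotype_diversity(cs[[1]])$Hd, 2), cs[[2]])

  expect_equal(haplotype_diversity(c(10))$Hd, 0)
  expect_error(haplotype_diversity(c(1)), "at least 2")
  # invariant to label permutation; zero iff monomorphic
  set.seed(3)
  for (i in 1:20) {
    cts <- sample(1:6, sample(2:5, 1), replace = TRUE)
    expect_equal(haplotype_diversity(cts)$Hd,
                 haplotype_diversity(sample(cts))$Hd)
    expect_gt(haplotype_diversity(cts)$Hd, 0)
  }
})

test_that("nucleotide diversity equals the brute-force pairwise average", {
  # single pair differing at 1 of 10 sites
  hs <- toy_hapset(matrix(c(1L, 1L), 1, 2,
                          dimnames = list("P1", c("H1", "H2"))),
                   c("AAAAAAAAAA", "AAAAAAAAAT"))
  expect_equal(nucleotide_diversity(haplotype_counts(hs),
                                    hamming_matrix(hs), 10)$pi, 0.1)
  # monomorphic
  expect_equal(nucleotide_diversity(c(5), matrix(0, 1, 1), 10)$pi, 0)

  for (seed in 1:100) {
    n <- sample(4:10, 1)
    m <- rand_poly_aln(n, 25, n_var = sample(3:8, 1), seed = seed)
    hs <- quick_hapset(m)
    got <- nucleotide_diversity(haplotype_counts(hs), hamming_matrix(hs),
                                ncol(m))$pi
    expect_equal(got, brute_pi(m), tolerance = 1e-12)
  }
})

test_that("Pons-Petit estimators match an independent transcription", {
  # two populations fixed for different haplotypes: hS = 0, GST = 1
  cts <- matrix(c(6L, 0L, 0L, 6L), 2, 2, byrow = TRUE,
                dimnames = list(c("P1", "P2"), c("H1", "H2")))
  pp <- pons_petit(cts)
  expect_equal(pp$hS, 0)
  expect_equal(pp$coef, 1)

  # identical composition everywhere: GST near 0
  cts2 <- matrix(rep(c(10L, 10L), 3), 3, 2, byrow = TRUE,
                 dimnames = list(paste0("P", 1:3), c("H1", "H2")))
  expect_lt(abs(pons_petit(cts2)$coef), 0.05)

  # random toys against the line-by-line reference, ordered and unordered
  set.seed(11)
  for (rep in 1:100) {
    K <- sample(3:6, 1); H <- sample(3:6, 1)
    cts <- matrix(rpois(K * H, 2), K, H,
                  dimnames = list(paste0("P", 1:K), paste0("H", 1:H)))
    cts[rowSums(cts) < 2, 1] <- 2L
    storage.mode(cts) <- "integer"
    dm <- as.matrix(stats::dist(matrix(rnorm(H * 3), H)))
    got_g <- pons_petit(cts)
    ref_g <- pp_reference(cts, 1 - diag(H))
    expect_equal(got_g$hS, ref_g$vS, tolerance = 1e-9)
    expect_equal(got_g$hT, ref_g$vT, tolerance = 1e-9)
    expect_equal(got_g$coef, ref_g$coef, tolerance = 1e-9)
    got_n <- pons_petit(cts, dm)
    ref_n <- pp_reference(cts, dm)
    expect_equal(got_n$coef, ref_n$coef, tolerance = 1e-9)
  }

  # populations of 1 copy are excluded
  cts3 <- rbind(P1 = c(3L, 3L), P2 = c(1L, 0L), P3 = c(0L, 4L))
  colnames(cts3) <- c("H1", "H2")
  expect_equal(pons_petit(cts3)$K, 2)
  expect_error(pons_petit(cts3[1:2, ]), ">= 2 populations")
})

test_that("NST collapses to GST under equidistant haplotypes", {
  set.seed(21)
  for (rep in 1:20) {
    K <- sample(3:5, 1); H <- sample(3:5, 1)
    cts <- matrix(rpois(K * H, 3) + 1L, K, H,
                  dimnames = list(paste0("P", 1:K), paste0("H", 1:H)))
    storage.mode(cts) <- "integer"
    star <- matrix(2, H, H); diag(star) <- 0
    expect_lt(abs(pons_petit(cts, star)$coef - pons_petit(cts)$coef), 1e-12)
  }
})

test_that("the NST > GST permutation test detects phylogeographic structure", {
  fix <- make_structured_fixture("two_clades", seed = 101)
  hs <- collapse_haplotypes(filter_sites(fix$alignment), fix$popmap)
  d <- hamming_matrix(hs)
  res <- nst_gst_permutation_test(hs, d, n_perm = 300, seed = 5)
  expect_gt(res$NST, res$GST)
  expect_lt(res$p, 0.05)
  # determinism under seed
  res2 <- nst_gst_permutation_test(hs, d, n_perm = 300, seed = 5)
  expect_identical(res$p, res2$p)
  expect_identical(res$U, res2$U)
  expect_warning(nst_gst_permutation_test(hs, d, n_perm = 50, seed = 1),
                 "coarse")
})

test_that("structure is detected in most independent two-clade replicates", {
  hits <- 0
  n_rep <- 50
  for (r in seq_len(n_rep)) {
    fix <- make_structured_fixture("two_clades", seed = 1000 + r)
    hs <- collapse_haplotypes(filter_sites(fix$alignment), fix$popmap)
    d <- hamming_matrix(hs)
    p <- nst_gst_permutation_test(hs, d, n_perm = 200, seed = r)$p
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("the diversity table mirrors the published layout", {
  hct <- read_haplotype_count_table(
    system.file("extdata", "table2_cpdna.csv", package = "notophylo"))
  hs <- hapset_from_count_table(hct)
  d <- hamming_matrix(hs)
  tab <- diversity_table(hs, d, ncol(hs$seq))
  expect_setequal(unique(tab$level), c("population", "species", "total"))
  expect_equal(sum(tab$level == "population"), 74)
  expect_equal(round(tab$Hd[tab$name == "D"], 2), 0.36)
  expect_equal(round(tab$Hd[tab$name == "G"], 2), 0.53)
  # pooled total row agrees with a direct pooled-count computation
  pooled <- haplotype_diversity(colSums(hs$counts))
  expect_equal(tab$Hd[tab$level == "total"], pooled$Hd)
  expect_equal(tab$n[tab$level == "total"], 546)
})
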