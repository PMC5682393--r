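#' Unbiased haplotype (gene) diversity
#'
#' Nei's unbiased estimator `Hd = n (1 - sum p_i^2) / (n - 1)` with its
#' sampling standard deviation (Nei 1987, eq. 8.4/8.12).
#'
#' @param counts integer vector of haplotype copy counts (n = sum >= 2).
#' @return list with `Hd`, `sd`, `n`.
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("need at least 2 copies to estimate Hd", call. = FALSE)
  p <- counts / n
  s2 <- sum(p^2)
  hd <- n * (1 - s2) / (n - 1)
  # sampling variance of the unbiased estimator
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - s2^2) + s2 - s2^2)
  list(Hd = hd, sd = sqrt(max(v, 0)), n = n)
}

#' Nucleotide diversity from haplotype counts and distances
#'
#' Unbiased mean number of pairwise differences per site,
#' `pi = n/(n-1) * sum_{i != j} p_i p_j d_ij / L`, identical to the average
#' Hamming distance over all C(n,2) sequence pairs divided by L. The
#' reported standard deviation is the standard no-recombination sampling SD
#' of pi (Nei 1987, eq. 10.7).
#'
#' @param counts haplotype copy counts.
#' @param d haplotype distance matrix ([hamming_matrix()]), ordered as
#'   `counts`.
#' @param L number of sites.
#' @return list with `pi`, `pi_total` (per sequence, not per site), `sd`,
#'   `n`.
#' @export
nucleotide_diversity <- function(counts, d, L) {
  stopifnot(L >= 1, length(counts) == nrow(d))
  keep <- counts > 0
  counts <- counts[keep]; d <- d[keep, keep, drop = FALSE]
  n <- sum(counts)
  if (n < 2) stop("need at least 2 copies to estimate pi", call. = FALSE)
  p <- counts / n
  pi_total <- n / (n - 1) * as.numeric(t(p) %*% d %*% p)
  pi <- pi_total / L
  v <- (n + 1) / (3 * (n - 1)) * pi / L +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(pi = pi, pi_total = pi_total, sd = sqrt(max(v, 0)), n = n)
}

# Generic Pons & Petit estimator machinery. With d_ij = 1 - delta_ij the
# within/total diversities are gene diversities (hS, hT, GST); with observed
# haplotype distances they are the ordered-allele analogs (vS, vT, NST).
# counts: population x haplotype matrix; only populations with n_k >= 2
# enter. hT uses the harmonic-mean sample-size correction.
pp_core <- function(counts, dmat) {
  nk <- rowSums(counts)
  counts <- counts[nk >= 2, , drop = FALSE]
  nk <- nk[nk >= 2]
  K <- nrow(counts)
  if (K < 2) stop("need >= 2 populations with n >= 2", call. = FALSE)
  P <- sweep(counts, 1, nk, "/")
  vk <- vapply(seq_len(K), function(k) {
    p <- P[k, ]
    nk[k] / (nk[k] - 1) * as.numeric(t(p) %*% dmat %*% p)
  }, 0)
  vS <- mean(vk)
  ntilde <- K / sum(1 / nk)          # harmonic mean sample size
  pbar <- colMeans(P)
  vT <- as.numeric(t(pbar) %*% dmat %*% pbar) + vS / (ntilde * K)
  list(vS = vS, vT = vT, G = if (vT > 0) 1 - vS / vT else NA_real_, K = K)
}

#' Pons-Petit differentiation estimators
#'
#' Unbiased within-population (`hS`/`vS`) and total (`hT`/`vT`) diversities
#' and the differentiation coefficient `GST = 1 - hS/hT` (unordered alleles,
#' `d = NULL`) or `NST = 1 - vS/vT` (ordered alleles, with pairwise
#' haplotype distances). The total diversity uses the Pons & Petit
#' harmonic-mean sample-size correction. Populations with fewer than two
#' copies are excluded. Standard errors are delete-one-population
#' jackknives.
#'
#' @param hs a `haplotype_set` (its `counts` matrix is used), or a
#'   population x haplotype count matrix.
#' @param d optional haplotype distance matrix; `NULL` gives the unordered
#'   (GST) estimator.
#' @return list with `hS`, `hT`, `coef` (GST or NST), their `se_*` jackknife
#'   SEs, `ordered` flag and `K` populations used.
#' @export
pons_petit <- function(hs, d = NULL) {
  counts <- if (inherits(hs, "haplotype_set")) hs$counts else hs
  H <- ncol(counts)
  ordered <- !is.null(d)
  dmat <- if (ordered) d else 1 - diag(H)
  est <- pp_core(counts, dmat)
  keep <- rowSums(counts) >= 2
  cc <- counts[keep, , drop = FALSE]
  jk <- if (nrow(cc) > 2) {
    vapply(seq_len(nrow(cc)), function(k) {
      e <- pp_core(cc[-k, , drop = FALSE], dmat)
      c(e$vS, e$vT, e$G)
    }, numeric(3))
  } else NULL
  se <- if (is.null(jk)) rep(NA_real_, 3) else {
    K <- ncol(jk)
    sqrt((K - 1) / K * rowSums((jk - rowMeans(jk))^2))
  }
  list(hS = est$vS, hT = est$vT, coef = est$G,
       se_hS = se[1], se_hT = se[2], se_coef = se[3],
       ordered = ordered, K = est$K)
}

#' Permutation test for phylogeographic structure (NST > GST)
#'
#' Recomputes NST after randomly permuting haplotype identities in the
#' distance matrix (`n_perm` times); GST is unaffected by the permutation.
#' The one-sided p-value is the fraction of permuted `NST - GST` values at
#' least as large as observed (with the +1 continuity correction), and `U`
#' is the observed difference divided by the SD of the permutation
#' distribution.
#'
#' @param hs a `haplotype_set`.
#' @param d haplotype distance matrix.
#' @param n_perm number of permutations (default 1000; fewer than 100 draws
#'   a warning).
#' @param seed integer seed.
#' @return list with `GST`, `NST`, `diff`, `U`, `p`, `n_perm`.
#' @export
nst_gst_permutation_test <- function(hs, d, n_perm = 1000, seed = 1) {
  if (n_perm < 100) warning("n_perm < 100: p-value will be coarse")
  g <- pons_petit(hs)
  nst <- pons_petit(hs, d)
  obs <- nst$coef - g$coef
  counts <- hs$counts
  H <- ncol(counts)
  perm_diff <- local_rng(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(H)
      pp_core(counts, d[idx, idx])$G - g$coef
    }, 0)
  })
  p <- (sum(perm_diff >= obs - 1e-12) + 1) / (n_perm + 1)
  u <- obs / stats::sd(perm_diff)
  list(GST = g$coef, NST = nst$coef, diff = obs, U = u, p = p,
       n_perm = n_perm)
}

#' Per-population and per-species diversity table
#'
#' Mirrors the layout of a published gene-diversity table: per population,
#' the number of copies, unbiased Hd (SD), pi (SD), and the haplotype
#' composition; plus one pooled row per species and a pooled total.
#'
#' @param hs a `haplotype_set`.
#' @param d haplotype distance matrix.
#' @param L alignment length in sites.
#' @return data frame with columns `level`, `name`, `species`, `n`, `Hd`,
#'   `Hd_sd`, `pi`, `pi_sd`, `n_haplotypes`, `haplotypes`.
#' @export
diversity_table <- function(hs, d, L) {
  one <- function(cts, name, species, level) {
    cts <- cts[cts > 0]
    n <- sum(cts)
    if (n < 2) {
      hd <- c(Hd = NA_real_, sd = NA_real_)
      pv <- list(pi = NA_real_, sd = NA_real_)
    } else {
      hdl <- haplotype_diversity(cts)
      hd <- c(Hd = hdl$Hd, sd = hdl$sd)
      full <- stats::setNames(rep(0L, ncol(hs$counts)), colnames(hs$counts))
      full[names(cts)] <- cts
      pv <- nucleotide_diversity(full, d, L)
    }
    data.frame(level = level, name = name, species = species, n = n,
               Hd = hd[["Hd"]], Hd_sd = hd[["sd"]],
               pi = pv$pi, pi_sd = pv$sd,
               n_haplotypes = length(cts),
               haplotypes = paste(sprintf("%s(%d)", names(cts), cts),
                                  collapse = " "),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (pop in rownames(hs$counts)) {
    cts <- hs$counts[pop, ]
    names(cts) <- colnames(hs$counts)
    rows[[length(rows) + 1]] <-
      one(cts, pop, hs$pop_species[[pop]], "population")
  }
  for (sp in unique(hs$pop_species)) {
    pops <- names(hs$pop_species)[hs$pop_species == sp]
    cts <- colSums(hs$counts[pops, , drop = FALSE])
    rows[[length(rows) + 1]] <- one(cts, sp, sp, "species")
  }
  rows[[length(rows) + 1]] <-
    one(colSums(hs$counts), "Total", "-", "total")
  do.call(rbind, rows)
}
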