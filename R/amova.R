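# Sums of squared distances within groups of individuals, computed from
# haplotype indices: for a set A, SS(A) = (1/|A|) sum_{i<j in A} delta^2_ij.
ss_within <- function(hap_idx, d2) {
  n <- length(hap_idx)
  if (n < 2) return(0)
  tab <- tabulate(hap_idx, nbins = nrow(d2))
  as.numeric(t(tab) %*% d2 %*% tab) / 2 / n
}

#' Hierarchical analysis of molecular variance
#'
#' Partitions squared pairwise haplotype distances among species (groups),
#' among populations within species, and within populations, with the
#' standard n-coefficient variance-component expectations and
#' Phi-statistics. Distances enter squared (the haplotype-AMOVA convention
#' of the tool family this mirrors); for Hamming steps pass
#' [hamming_matrix()] output directly.
#'
#' @param hs a `haplotype_set`.
#' @param d haplotype distance matrix (unsquared; squared internally).
#' @param popmap a `hap_popmap` (only used for species membership of
#'   populations; `hs$pop_species` is the fallback).
#' @param levels `"three"` (species/populations/within) or `"two"`
#'   (populations/within, ignoring species).
#' @return list of class `amova_result`: `table` (df, SS, MS per source),
#'   `sigma2` (variance components, as computed, possibly negative),
#'   `percent` (components truncated at 0 for display), `phi`
#'   (`PhiCT`, `PhiSC`, `PhiST` as applicable), `degenerate` flag.
#' @export
amova <- function(hs, d, popmap = NULL, levels = c("three", "two")) {
  levels <- match.arg(levels)
  u <- amova_units(hs)
  amova_core(u$hap, u$pop, u$grp, d, levels)
}

# Expand a haplotype_set into per-copy vectors of haplotype index,
# population, and species.
amova_units <- function(hs) {
  counts <- hs$counts
  hap <- integer(0); pop <- character(0)
  for (k in seq_len(nrow(counts))) {
    for (h in which(counts[k, ] > 0)) {
      hap <- c(hap, rep(h, counts[k, h]))
      pop <- c(pop, rep(rownames(counts)[k], counts[k, h]))
    }
  }
  list(hap = hap, pop = pop, grp = unname(hs$pop_species[pop]))
}

amova_core <- function(hap, pop, grp, d, levels) {
  d2 <- d^2
  N <- length(hap)
  pops <- unique(pop)
  P <- length(pops)
  if (P < 2) stop("AMOVA needs at least 2 populations", call. = FALSE)
  ss_tot <- ss_within(hap, d2)
  ss_wp <- sum(vapply(pops, function(p) ss_within(hap[pop == p], d2), 0))
  np <- as.numeric(table(factor(pop, levels = pops)))
  if (levels == "two") {
    df_ap <- P - 1; df_wp <- N - P
    ss_ap <- ss_tot - ss_wp
    ms_ap <- ss_ap / df_ap; ms_wp <- ss_wp / df_wp
    nc <- (N - sum(np^2) / N) / (P - 1)
    s2_c <- ms_wp
    s2_b <- (ms_ap - ms_wp) / nc
    sig <- c(among_populations = s2_b, within_populations = s2_c)
    tot <- sum(sig)
    degenerate <- !is.finite(tot) || tot <= 0
    phi <- c(PhiST = if (degenerate) NA_real_ else s2_b / tot)
    tab <- data.frame(
      source = c("among populations", "within populations", "total"),
      df = c(df_ap, df_wp, N - 1),
      SS = c(ss_ap, ss_wp, ss_tot),
      MS = c(ms_ap, ms_wp, NA))
  } else {
    grps <- unique(grp)
    G <- length(grps)
    if (G < 2) stop("three-level AMOVA needs >= 2 species", call. = FALSE)
    ss_wg <- sum(vapply(grps, function(g) ss_within(hap[grp == g], d2), 0))
    ss_ap <- ss_wg - ss_wp          # among populations within groups
    ss_ag <- ss_tot - ss_wg         # among groups
    df_ag <- G - 1; df_ap <- P - G; df_wp <- N - P
    if (df_ap < 1) stop("each species needs >= 2 populations", call. = FALSE)
    ms_ag <- ss_ag / df_ag; ms_ap <- ss_ap / df_ap; ms_wp <- ss_wp / df_wp
    ng <- as.numeric(table(factor(grp, levels = grps)))
    pop_grp <- tapply(grp, pop, `[`, 1)[pops]
    sum_np2_over_ng <- sum(vapply(seq_along(grps), function(gi) {
      sum(np[pop_grp == grps[gi]]^2) / ng[gi]
    }, 0))
    n1 <- (N - sum_np2_over_ng) / (P - G)
    n2 <- (sum_np2_over_ng - sum(np^2) / N) / (G - 1)
    n3 <- (N - sum(ng^2) / N) / (G - 1)
    s2_c <- ms_wp
    s2_b <- (ms_ap - s2_c) / n1
    s2_a <- (ms_ag - s2_c - n2 * s2_b) / n3
    sig <- c(among_species = s2_a, among_populations = s2_b,
             within_populations = s2_c)
    tot <- sum(sig)
    degenerate <- !is.finite(tot) || tot <= 0
    phi <- if (degenerate) {
      c(PhiCT = NA_real_, PhiSC = NA_real_, PhiST = NA_real_)
    } else {
      c(PhiCT = s2_a / tot,
        PhiSC = s2_b / (s2_b + s2_c),
        PhiST = (s2_a + s2_b) / tot)
    }
    tab <- data.frame(
      source = c("among species", "among populations within species",
                 "within populations", "total"),
      df = c(df_ag, df_ap, df_wp, N - 1),
      SS = c(ss_ag, ss_ap, ss_wp, ss_tot),
      MS = c(ms_ag, ms_ap, ms_wp, NA))
  }
  disp <- pmax(sig, 0)
  pct <- if (isTRUE(sum(disp) > 0)) 100 * disp / sum(disp)
         else rep(NA_real_, length(sig))
  structure(list(table = tab, sigma2 = sig, percent = pct, phi = phi,
                 degenerate = degenerate, levels = levels),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", x$levels, "-level)\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("Phi: ", paste(sprintf("%s = %.4f", names(x$phi), x$phi),
                     collapse = ", "), "\n")
  invisible(x)
}

#' Permutation p-values for AMOVA Phi-statistics
#'
#' Permutation schemes follow the standard hierarchical conventions:
#' `PhiST` permutes individuals among populations across the whole system,
#' `PhiSC` permutes individuals among populations within species, and
#' `PhiCT` permutes whole populations among species. p =
#' (count >= observed + 1) / (n_perm + 1).
#'
#' @param hs a `haplotype_set`.
#' @param d haplotype distance matrix.
#' @param statistic which Phi to test.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param levels AMOVA design, as in [amova()].
#' @return list with `observed`, `p`, `n_perm`.
#' @export
amova_permutation <- function(hs, d, statistic = c("PhiST", "PhiSC", "PhiCT"),
                              n_perm = 1000, seed = 1,
                              levels = c("three", "two")) {
  statistic <- match.arg(statistic)
  levels <- match.arg(levels)
  if (levels == "two" && statistic != "PhiST")
    stop("two-level AMOVA only has PhiST", call. = FALSE)
  u <- amova_units(hs)
  obs <- amova_core(u$hap, u$pop, u$grp, d, levels)$phi[[statistic]]
  if (!is.finite(obs)) stop("observed statistic is degenerate", call. = FALSE)
  pops <- unique(u$pop)
  pop_grp <- tapply(u$grp, u$pop, `[`, 1)[pops]
  stat_perm <- local_rng(seed, vapply(seq_len(n_perm), function(b) {
    if (statistic == "PhiST") {
      pop_b <- sample(u$pop)
      grp_b <- if (levels == "two") u$grp else unname(pop_grp[pop_b])
      amova_core(u$hap, pop_b, grp_b, d, levels)$phi[[statistic]]
    } else if (statistic == "PhiSC") {
      pop_b <- u$pop
      for (g in unique(u$grp)) {
        idx <- which(u$grp == g)
        pop_b[idx] <- sample(u$pop[idx])
      }
      amova_core(u$hap, pop_b, u$grp, d, levels)$phi[[statistic]]
    } else {
      grp_of_pop <- sample(unname(pop_grp))
      names(grp_of_pop) <- pops
      amova_core(u$hap, u$pop, unname(grp_of_pop[u$pop]), d,
                 levels)$phi[[statistic]]
    }
  }, 0))
  stat_perm <- stat_perm[is.finite(stat_perm)]
  p <- (sum(stat_perm >= obs - 1e-12) + 1) / (length(stat_perm) + 1)
  list(observed = obs, p = p, n_perm = length(stat_perm))
}
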