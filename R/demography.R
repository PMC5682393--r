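#' Observed mismatch distribution
#'
#' Relative frequency of pairwise sequence differences over all C(n,2)
#' copy pairs, weighted by haplotype copy counts.
#'
#' @param hs a `haplotype_set` (or a copy-count vector with `d` ordered to
#'   match).
#' @param d haplotype distance matrix.
#' @return list with `freq` (classes 0..d_max), `n` copies, `mean_diff`.
#' @export
observed_mismatch <- function(hs, d) {
  cts <- if (inherits(hs, "haplotype_set")) haplotype_counts(hs) else hs
  stopifnot(length(cts) == nrow(d))
  n <- sum(cts)
  if (n < 2) stop("need at least 2 copies", call. = FALSE)
  dmax <- max(d)
  w <- numeric(dmax + 1)
  w[1] <- sum(choose(cts, 2))           # identical-copy pairs
  H <- length(cts)
  if (H > 1) {
    for (i in seq_len(H - 1)) for (j in (i + 1):H) {
      w[d[i, j] + 1] <- w[d[i, j] + 1] + cts[i] * cts[j]
    }
  }
  freq <- w / sum(w)
  list(freq = freq, n = n,
       mean_diff = sum((0:dmax) * freq))
}

mismatch_equilibrium <- function(theta, i_max) {
  i <- 0:i_max
  if (theta == 0) return(c(1, rep(0, i_max)))
  exp(i * log(theta) - (i + 1) * log1p(theta))
}

#' Expected mismatch distribution under sudden expansion
#'
#' Transient distribution of pairwise differences for a population that
#' jumped from scaled size `theta0` to `theta1` at mutational time `tau`
#' before present, built on the equilibrium form
#' `F_i(theta) = theta^i / (1 + theta)^(i+1)`:
#' `F_j(tau) = F_j(theta1) + exp(-tau (theta1 + 1)/theta1) *
#'   sum_{i<=j} (F_i(theta0) - F_i(theta1)) tau^(j-i)/(j-i)!`.
#' At `tau = 0` this is the `theta0` equilibrium; with `theta0 = theta1` it
#' is the equilibrium for all `tau`.
#'
#' @param tau expansion age in mutational time units (>= 0).
#' @param theta0,theta1 scaled sizes before/after (0 <= theta0 <= theta1).
#' @param i_max largest difference class returned.
#' @return list with `prob` (classes 0..i_max) and `tail` mass.
#' @export
expected_mismatch <- function(tau, theta0, theta1, i_max) {
  if (tau < 0 || theta0 < 0 || theta1 < theta0)
    stop("need tau >= 0 and 0 <= theta0 <= theta1", call. = FALSE)
  if (theta1 == 0) {
    prob <- c(1, rep(0, i_max))
    return(list(prob = prob, tail = 0))
  }
  f1 <- mismatch_equilibrium(theta1, i_max)
  f0 <- mismatch_equilibrium(theta0, i_max)
  pois <- if (tau == 0) c(1, rep(0, i_max))
          else exp((0:i_max) * log(tau) - lgamma(1:(i_max + 1)))
  conv <- vapply(0:i_max, function(j) {
    sum((f0[1:(j + 1)] - f1[1:(j + 1)]) * rev(pois[1:(j + 1)]))
  }, 0)
  prob <- f1 + exp(-tau * (theta1 + 1) / theta1) * conv
  prob <- pmax(prob, 0)
  list(prob = prob, tail = max(0, 1 - sum(prob)))
}

# Expected curves for one (theta0, theta1) across a whole tau grid at once:
# columns are tau values. Used by the grid fit.
expected_mismatch_grid <- function(taus, theta0, theta1, i_max) {
  f1 <- mismatch_equilibrium(theta1, i_max)
  f0 <- mismatch_equilibrium(theta0, i_max)
  delta <- f0 - f1
  Lmat <- matrix(0, i_max + 1, i_max + 1)
  for (j in 0:i_max) Lmat[j + 1, 1:(j + 1)] <- rev(delta[1:(j + 1)])
  Pmat <- vapply(taus, function(tau) {
    if (tau == 0) c(1, rep(0, i_max))
    else exp((0:i_max) * log(tau) - lgamma(1:(i_max + 1)))
  }, numeric(i_max + 1))
  decay <- exp(-taus * (theta1 + 1) / theta1)
  pmax(f1 + sweep(Lmat %*% Pmat, 2, decay, "*"), 0)
}

THETA1_CAP <- 99999  # open-ended growth convention for the fitted theta1

#' Least-squares fit of the sudden-expansion model
#'
#' Minimizes `SSD = sum_i (x_i - F_i)^2` over the observed difference
#' classes on a coarse grid (`tau` in [0, 25] step 0.25; `theta0` in
#' [0, 20]; `theta1` on a log-spaced grid capped at 99999, the open-ended
#' growth convention), then refines locally. Monomorphic input is flagged
#' degenerate with parameters at the boundary.
#'
#' @param observed mismatch relative frequencies (classes 0..d_max), e.g.
#'   `observed_mismatch(...)$freq`.
#' @param refine run the local refinement pass (default TRUE).
#' @return list with `theta0`, `theta1`, `tau`, `ssd`, `expected`,
#'   `degenerate`.
#' @export
fit_sudden_expansion <- function(observed, refine = TRUE) {
  stopifnot(is.numeric(observed), all(observed >= 0))
  i_max <- length(observed) - 1
  if (i_max < 1 || observed[1] >= 1 - 1e-12)
    return(list(theta0 = 0, theta1 = 0, tau = 0, ssd = 0,
                expected = c(1, rep(0, max(i_max, 0))), degenerate = TRUE))
  taus <- seq(0, 25, by = 0.25)
  th0s <- c(seq(0, 10, by = 0.5), 12, 15, 20)
  th1s <- c(0.5, 1, 2, 3, 5, 8, 12, 20, 50, 100, 500, 1000, THETA1_CAP)
  best <- list(ssd = Inf)
  for (t1 in th1s) for (t0 in th0s[th0s <= t1]) {
    Fm <- expected_mismatch_grid(taus, t0, t1, i_max)
    ssd <- colSums((observed - Fm)^2)
    k <- which.min(ssd)
    if (ssd[k] < best$ssd)
      best <- list(theta0 = t0, theta1 = t1, tau = taus[k], ssd = ssd[k])
  }
  if (refine) {
    taus2 <- seq(max(0, best$tau - 0.3), best$tau + 0.3, by = 0.02)
    th0s2 <- unique(pmax(0, best$theta0 + seq(-0.6, 0.6, by = 0.1)))
    th1s2 <- unique(c(best$theta1 * c(0.5, 0.75, 1, 1.5, 2), THETA1_CAP))
    th1s2 <- pmin(th1s2, THETA1_CAP)
    for (t1 in th1s2) for (t0 in th0s2[th0s2 <= t1]) {
      Fm <- expected_mismatch_grid(taus2, t0, t1, i_max)
      ssd <- colSums((observed - Fm)^2)
      k <- which.min(ssd)
      if (ssd[k] < best$ssd)
        best <- list(theta0 = t0, theta1 = t1, tau = taus2[k], ssd = ssd[k])
    }
  }
  ex <- expected_mismatch(best$tau, best$theta0, best$theta1, i_max)
  c(best[c("theta0", "theta1", "tau", "ssd")],
    list(expected = ex$prob, degenerate = FALSE))
}

#' Harpending's raggedness index
#'
#' `r = sum_{i=1}^{d+1} (x_i - x_{i-1})^2` with the convention
#' `x_{d+1} = 0`, so a trailing drop to zero counts.
#'
#' @param observed mismatch relative frequencies (classes 0..d).
#' @return the raggedness index.
#' @export
raggedness <- function(observed) {
  x <- c(observed, 0)
  sum(diff(x)^2)
}

#' Peak count of a mismatch distribution
#'
#' Local maxima of the curve after a +/-1 moving-average smooth, counted
#' with a prominence rule: a non-global maximum only counts as a separate
#' peak if the valley connecting it to higher ground drops to half its own
#' height or less. This keeps the sampling bump at the zero-difference
#' class (identical copies within families) from splitting a single
#' expansion wave, while genuinely separated waves — e.g. the within- and
#' between-clade modes of an old split — still register. One peak is
#' reported as `"unimodal"`, more as `"multimodal"`.
#'
#' @param observed mismatch relative frequencies.
#' @return list with `n_peaks` and `modality`.
#' @export
mismatch_modality <- function(observed) {
  x <- observed
  n <- length(x)
  sm <- vapply(seq_len(n), function(i) {
    mean(x[max(1, i - 1):min(n, i + 1)])
  }, 0)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i == 1) -Inf else sm[i - 1]
    right <- if (i == n) -Inf else sm[i + 1]
    sm[i] > left && sm[i] >= right
  }, TRUE)
  peaks <- which(is_max)
  keep <- vapply(peaks, function(p) {
    h <- sm[p]
    saddle <- -Inf
    for (side in c(-1, 1)) {
      j <- p + side
      vmin <- Inf
      while (j >= 1 && j <= n) {
        if (sm[j] > h) { saddle <- max(saddle, vmin); break }
        vmin <- min(vmin, sm[j])
        j <- j + side
      }
    }
    !is.finite(saddle) || saddle <= h / 2  # global max, or prominent enough
  }, TRUE)
  n_peaks <- sum(keep)
  list(n_peaks = n_peaks,
       modality = if (n_peaks <= 1) "unimodal" else "multimodal")
}

#' Mismatch analysis with parametric-bootstrap significance
#'
#' Fits the sudden-expansion model to the observed mismatch distribution,
#' then simulates `n_boot` coalescent samples of the same size under the
#' fitted expansion, refits each, and reports
#' `p_SSD = P(SSD_sim >= SSD_obs)` and Harpending's raggedness with
#' `p_rag = P(r_sim >= r_obs)`, plus a percentile bootstrap CI for `tau`
#' from the refitted replicates.
#'
#' @param hs a `haplotype_set`.
#' @param d haplotype distance matrix.
#' @param n_boot bootstrap replicates (fewer than 100 draws a warning).
#' @param seed integer seed.
#' @return list with `observed` (frequencies), `fit`, `rag`, `p_SSD`,
#'   `p_rag`, `tau_ci`, `modality`, `n`.
#' @export
mismatch_test <- function(hs, d, n_boot = 1000, seed = 1) {
  if (n_boot < 100) warning("n_boot < 100: p-values will be coarse")
  obs <- observed_mismatch(hs, d)
  fit <- fit_sudden_expansion(obs$freq)
  rag <- raggedness(obs$freq)
  out <- list(observed = obs$freq, fit = fit, rag = rag,
              modality = mismatch_modality(obs$freq)$modality, n = obs$n)
  if (fit$degenerate || n_boot == 0) {
    out$p_SSD <- NA_real_; out$p_rag <- NA_real_
    out$tau_ci <- c(NA_real_, NA_real_)
    return(out)
  }
  th0 <- fit$theta0; th1 <- max(fit$theta1, 1e-3)
  growth <- th1 / max(th0, th1 * 1e-6)
  stats <- vapply(seq_len(n_boot), function(b) {
    sim <- simulate_coalescent(n = obs$n, theta = th1,
                               expansion = list(growth = max(growth, 1),
                                                tau = fit$tau),
                               L = 5000, seed = derive_seed(seed, b))
    aln <- sim$alignment
    hsb <- collapse_haplotypes(aln, sim$popmap)
    ob <- observed_mismatch(hsb, hamming_matrix(hsb))
    fb <- fit_sudden_expansion(ob$freq, refine = FALSE)
    c(ssd = fb$ssd, rag = raggedness(ob$freq), tau = fb$tau)
  }, numeric(3))
  out$p_SSD <- mean(stats["ssd", ] >= fit$ssd)
  out$p_rag <- mean(stats["rag", ] >= rag)
  out$tau_ci <- unname(stats::quantile(stats["tau", ], c(0.025, 0.975)))
  out
}

#' Expansion time from the fitted mismatch parameter
#'
#' Applies the composite dating formula as printed in the source tool
#' chain: `tau = 2 u t` with `u = 2 mu k g`, i.e. `t = tau / (4 mu k g)`
#' years, where `mu` is the substitution rate per site per year, `k` the
#' sequence length in bp and `g` the generation time in years. (A
#' conventional derivation with `u` per sequence per generation would give
#' `t = tau / (2 mu k)` years instead; the composite form is kept
#' deliberately — see the methods vignette.) `t` is evaluated over the
#' whole rate grid; `t(mu) * mu` is constant.
#'
#' @param tau fitted expansion age (mutational units).
#' @param mu substitution rate(s) per site per year (default the angiosperm
#'   chloroplast range 1e-9 and 3e-9).
#' @param k sequence length (bp).
#' @param g generation time in years (default 3).
#' @param tau_ci optional length-2 CI for `tau`, propagated to `t`.
#' @return data frame with columns `mu`, `u`, `t` (years) and, when
#'   `tau_ci` is given, `t_lower`, `t_upper`.
#' @export
expansion_time <- function(tau, mu = c(1e-9, 3e-9), k = 1605, g = 3,
                           tau_ci = NULL) {
  if (tau < 0 || any(mu <= 0) || k <= 0 || g <= 0)
    stop("tau must be >= 0 and mu, k, g positive", call. = FALSE)
  u <- 2 * mu * k * g
  out <- data.frame(mu = mu, u = u, t = tau / (2 * u))
  if (!is.null(tau_ci)) {
    out$t_lower <- tau_ci[1] / (2 * u)
    out$t_upper <- tau_ci[2] / (2 * u)
  }
  out
}
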