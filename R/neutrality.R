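# Per-sample summaries used by the neutrality statistics. Columns holding
# anything other than A/C/G/T are ignored (apply complete deletion first).
# pi_total here is the mean number of pairwise differences per sequence
# pair (NOT per site), the scale the statistics are defined on.
aln_summary <- function(aln) {
  m <- if (inherits(aln, "hap_alignment")) aln$seq else aln
  n <- nrow(m)
  ok <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, ok, drop = FALSE]
  S <- 0L; eta <- 0L; eta_s <- 0L; pi_sum <- 0
  npairs <- n * (n - 1) / 2
  for (j in seq_len(ncol(m))) {
    tab <- tabulate(factor(m[, j], levels = c("A", "C", "G", "T")), 4)
    tab <- tab[tab > 0]
    if (length(tab) < 2) next
    S <- S + 1L
    eta <- eta + length(tab) - 1L
    # singleton mutations: alleles seen once, at most (#alleles - 1) per site
    eta_s <- eta_s + min(sum(tab == 1), length(tab) - 1L)
    pi_sum <- pi_sum + (npairs - sum(choose(tab, 2)))
  }
  key <- apply(m, 1, paste, collapse = "")
  list(n = n, S = S, eta = eta, eta_s = eta_s,
       pi_total = pi_sum / npairs, k_hap = length(unique(key)))
}

harmonic <- function(n, pow = 1) if (n < 1) 0 else sum(1 / seq_len(n)^pow)

#' Tajima's D
#'
#' `D = (pi_total - S/a1) / sqrt(e1 S + e2 S (S-1))` with the standard
#' a1, a2, b1, b2, c1, c2, e1, e2 constants. Undefined (flagged `NA`) when
#' there are no segregating sites.
#'
#' @param aln a [hap_alignment()] (gap-free columns are used) or the
#'   summary list from internal helpers.
#' @return list with `D`, `S`, `pi_total`, `n`, `defined`.
#' @export
tajimas_d <- function(aln) {
  s <- if (is.list(aln) && !inherits(aln, "hap_alignment")) aln
       else aln_summary(aln)
  n <- s$n; S <- s$S
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  if (S == 0)
    return(list(D = NA_real_, S = 0L, pi_total = 0, n = n, defined = FALSE))
  a1 <- harmonic(n - 1); a2 <- harmonic(n - 1, 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  num <- s$pi_total - S / a1
  den <- sqrt(e1 * S + e2 * S * (S - 1))
  # n = 2 collapses both the numerator and the variance to zero: D = 0
  D <- if (den == 0) {
    if (abs(num) < 1e-12) 0 else NaN
  } else num / den
  list(D = D, S = S, pi_total = s$pi_total, n = n, defined = TRUE)
}

#' Fu and Li's F* (no outgroup)
#'
#' Uses total mutations `eta` and singleton mutations `eta_s`, with the
#' corrected variance constants of Simonsen, Churchill & Aquadro (1995):
#' numerator `pi_total - ((n-1)/n) eta_s`, denominator
#' `sqrt(u_F eta + v_F eta^2)` where
#' `v_F = [(2n^3 + 110n^2 - 255n + 153)/(9n^2(n-1)) + 2(n-1)a_n/n^2 -
#' 8 b_n/n] / (a_n^2 + b_n)` and
#' `u_F = [(4n^2 + 19n + 3 - 12(n+1)a_{n+1}) / (3n(n-1))] / a_n - v_F`,
#' with `a_n`, `b_n` the first/second-order harmonic numbers of `n - 1`.
#'
#' @param aln a [hap_alignment()].
#' @return list with `F_star`, `eta`, `eta_s`, `n`, `defined`.
#' @export
fu_li_f_star <- function(aln) {
  s <- if (is.list(aln) && !inherits(aln, "hap_alignment")) aln
       else aln_summary(aln)
  n <- s$n; eta <- s$eta
  if (n < 4) stop("F* needs n >= 4", call. = FALSE)
  if (eta == 0)
    return(list(F_star = NA_real_, eta = 0L, eta_s = s$eta_s, n = n,
                defined = FALSE))
  an <- harmonic(n - 1); bn <- harmonic(n - 1, 2)
  an1 <- an + 1 / n  # a_{n+1}
  vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
           2 * (n - 1) * an / n^2 - 8 * bn / n) / (an^2 + bn)
  uF <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
           (3 * n * (n - 1))) / an - vF
  Fs <- (s$pi_total - (n - 1) / n * s$eta_s) / sqrt(uF * eta + vF * eta^2)
  list(F_star = Fs, eta = eta, eta_s = s$eta_s, n = n, defined = TRUE)
}

# log of unsigned Stirling numbers of the first kind, row n (k = 0..n),
# by the recursion |s(n,k)| = |s(n-1,k-1)| + (n-1)|s(n-1,k)| carried in
# log space so n in the hundreds stays finite.
log_stirling_row <- function(n) {
  row <- c(0)  # |s(0,0)| = 1
  if (n == 0) return(row)
  for (m in seq_len(n)) {
    prev <- row
    row <- rep(-Inf, m + 1)
    row[m + 1] <- prev[m]                     # |s(m,m)| = |s(m-1,m-1)| = 1
    for (k in seq_len(m - 1)) {               # k ranges 1..m-1 -> index k+1
      a <- if (k >= 2) prev[k] else -Inf      # |s(m-1, k-1)|
      b <- log(m - 1) + prev[k + 1]           # (m-1) |s(m-1, k)|
      row[k + 1] <- logaddexp(a, b)
    }
  }
  row
}

logaddexp <- function(a, b) {
  if (a == -Inf) return(b)
  if (b == -Inf) return(a)
  m <- max(a, b)
  m + log1p(exp(min(a, b) - m))
}

# P(K >= k_obs | theta, n) under the Ewens sampling formula,
# P(K = k) = |s(n,k)| theta^k / (theta)_n, evaluated in log space.
ewens_tail <- function(n, k_obs, theta) {
  lrow <- log_stirling_row(n)
  lpoch <- sum(log(theta + 0:(n - 1)))
  lp <- lrow[2:(n + 1)] + (1:n) * log(theta) - lpoch
  sum(exp(lp[k_obs:n]))
}

#' Fu's Fs
#'
#' With `theta_hat = pi_total`, computes `S' = P(K >= k_obs | theta_hat, n)`
#' from the Ewens sampling formula (unsigned Stirling numbers of the first
#' kind, evaluated in log space) and `Fs = ln(S'/(1 - S'))`. Monomorphic
#' samples are flagged undefined; `S' = 1` (a single haplotype) gives
#' `+Inf`, `S' = 0` gives `-Inf`.
#'
#' @param aln a [hap_alignment()].
#' @return list with `Fs`, `S_prime`, `k_hap`, `theta_hat`, `n`, `defined`.
#' @export
fus_fs <- function(aln) {
  s <- if (is.list(aln) && !inherits(aln, "hap_alignment")) aln
       else aln_summary(aln)
  n <- s$n
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  if (s$pi_total <= 0)
    return(list(Fs = NA_real_, S_prime = NA_real_, k_hap = s$k_hap,
                theta_hat = 0, n = n, defined = FALSE))
  # K >= 1 is certain; computing the full tail sum would only accumulate
  # rounding error on what is exactly 1
  sp <- if (s$k_hap <= 1) 1 else ewens_tail(n, s$k_hap, s$pi_total)
  fs <- if (sp >= 1) Inf else if (sp <= 0) -Inf else log(sp / (1 - sp))
  list(Fs = fs, S_prime = sp, k_hap = s$k_hap, theta_hat = s$pi_total,
       n = n, defined = TRUE)
}

# --- fixed-S coalescent null ------------------------------------------------

# One neutral constant-size coalescent replicate conditioned on S mutations,
# placed multinomially on branches by length. Returns the per-replicate
# pi_total, eta_s and haplotype count needed by the three statistics.
sim_fixed_s <- function(n, S) {
  act <- as.list(seq_len(n))           # active lineages as tip sets
  t <- 0
  lens <- list(); descs <- list()      # finished branch lengths/tip sets
  cur_born <- rep(0, n)
  while (length(act) > 1) {
    k <- length(act)
    t <- t + stats::rexp(1, rate = k * (k - 1) / 2)
    pair <- sample.int(k, 2)
    for (ix in pair) {
      lens[[length(lens) + 1]] <- t - cur_born[ix]
      descs[[length(descs) + 1]] <- act[[ix]]
    }
    merged <- c(act[[pair[1]]], act[[pair[2]]])
    act <- c(act[-pair], list(merged))
    cur_born <- c(cur_born[-pair], t)
  }
  lens <- unlist(lens)
  if (S == 0) return(list(pi_total = 0, eta_s = 0L, k_hap = 1L, S = 0L))
  branch <- sample.int(length(lens), S, replace = TRUE,
                       prob = lens / sum(lens))
  dcount <- vapply(branch, function(b) length(descs[[b]]), 0L)
  npairs <- n * (n - 1) / 2
  pi_total <- sum(dcount * (n - dcount)) / npairs
  # a mutation subtending 1 or n-1 tips leaves an allele carried by exactly
  # one sequence, matching the site-based singleton count
  eta_s <- sum(dcount == 1L | dcount == n - 1L)
  # haplotype identity: tips keyed by the set of mutations above them
  mut_of_tip <- lapply(seq_len(n), function(tip) {
    which(vapply(branch, function(b) tip %in% descs[[b]], TRUE))
  })
  k_hap <- length(unique(vapply(mut_of_tip, paste, "", collapse = ",")))
  list(pi_total = pi_total, eta_s = eta_s, k_hap = k_hap, S = S)
}

#' Coalescent null p-values for the neutrality statistics
#'
#' Simulates `n_sims` constant-size coalescent replicates conditional on the
#' observed number of segregating sites (fixed-S placement of mutations on
#' the genealogy), recomputes D, F* and Fs on each, and reports two-sided
#' p-values for D and F* and a one-sided (lower-tail, expansion-signal)
#' p-value for Fs. With `n_sims = 0` only the statistics are returned.
#'
#' @param aln a [hap_alignment()].
#' @param n_sims number of null replicates.
#' @param seed integer seed.
#' @return list with the three statistic lists plus `p_D`, `p_F_star`,
#'   `p_Fs` (absent if `n_sims = 0`).
#' @export
neutrality_pvalues <- function(aln, n_sims = 1000, seed = 1) {
  s <- aln_summary(aln)
  out <- list(D = tajimas_d(s),
              F_star = if (s$n >= 4) fu_li_f_star(s) else NULL,
              Fs = fus_fs(s))
  if (n_sims == 0 || s$S == 0) return(out)
  n <- s$n
  sims <- local_rng(seed, lapply(seq_len(n_sims), function(i) {
    r <- sim_fixed_s(n, s$S)
    r$eta <- r$S
    r$n <- n
    c(D = tajimas_d(r)$D,
      F_star = if (n >= 4) fu_li_f_star(r)$F_star else NA_real_,
      Fs = if (r$pi_total > 0) fus_fs(r)$Fs else NA_real_)
  }))
  sims <- do.call(rbind, sims)
  two_sided <- function(obs, null) {
    null <- null[is.finite(null)]
    if (!is.finite(obs) || !length(null)) return(NA_real_)
    mean(abs(null - mean(null)) >= abs(obs - mean(null)))
  }
  out$p_D <- two_sided(out$D$D, sims[, "D"])
  out$p_F_star <- if (!is.null(out$F_star))
    two_sided(out$F_star$F_star, sims[, "F_star"]) else NA_real_
  fsn <- sims[, "Fs"][is.finite(sims[, "Fs"])]
  out$p_Fs <- if (is.finite(out$Fs$Fs) && length(fsn))
    mean(fsn <= out$Fs$Fs) else NA_real_
  out$n_sims <- n_sims
  out
}
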