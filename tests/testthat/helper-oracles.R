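# Independent oracles, deliberately written as plain loops over explicit
# sequence pairs so they share no code path with the package internals.

# random gap-free alignment matrix
rand_aln_matrix <- function(n, L, seed) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  rownames(m) <- sprintf("r%02d", seq_len(n))
  m
}

# alignment with limited polymorphism (more realistic haplotype structure)
rand_poly_aln <- function(n, L, n_var, seed) {
  set.seed(seed)
  m <- matrix("A", n, L)
  for (s in sample.int(L, n_var)) {
    carriers <- sample.int(n, sample(seq_len(n - 1), 1))
    m[carriers, s] <- sample(c("C", "G", "T"), 1)
  }
  rownames(m) <- sprintf("r%02d", seq_len(n))
  m
}

# mean pairwise difference per site over all explicit sequence pairs
brute_pi <- function(m) {
  n <- nrow(m)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) tot <- tot + sum(m[i, ] != m[j, ])
  tot / choose(n, 2) / ncol(m)
}

brute_mean_pairwise <- function(m) brute_pi(m) * ncol(m)

# haplotype_set built directly from a counts matrix and sequence strings
toy_hapset <- function(counts, seqs, species = NULL) {
  seqm <- do.call(rbind, strsplit(seqs, ""))
  rownames(seqm) <- colnames(counts)
  if (is.null(species)) species <- rep("sp", nrow(counts))
  prov <- lapply(seq_len(ncol(counts)), function(h)
    sprintf("%s_%d", colnames(counts)[h], seq_len(sum(counts[, h]))))
  names(prov) <- colnames(counts)
  structure(list(seq = seqm, counts = counts, provenance = prov,
                 pop_species = stats::setNames(species, rownames(counts)),
                 ploidy_factor = 1),
            class = "haplotype_set")
}

# Pons & Petit estimators transcribed separately: explicit double loops,
# harmonic-mean correction written out
pp_reference <- function(counts, dmat) {
  nk <- rowSums(counts)
  use <- which(nk >= 2)
  counts <- counts[use, , drop = FALSE]
  nk <- nk[use]
  K <- length(nk)
  H <- ncol(counts)
  vk <- numeric(K)
  for (k in 1:K) {
    acc <- 0
    for (i in 1:H) for (j in 1:H)
      acc <- acc + (counts[k, i] / nk[k]) * (counts[k, j] / nk[k]) * dmat[i, j]
    vk[k] <- nk[k] / (nk[k] - 1) * acc
  }
  vS <- sum(vk) / K
  nh <- K / sum(1 / nk)
  pbar <- numeric(H)
  for (i in 1:H) pbar[i] <- mean(counts[, i] / nk)
  acc <- 0
  for (i in 1:H) for (j in 1:H) acc <- acc + pbar[i] * pbar[j] * dmat[i, j]
  vT <- acc + vS / (nh * K)
  list(vS = vS, vT = vT, coef = 1 - vS / vT)
}

# Tajima's D transcribed step by step from the published constant pipeline
tajima_reference <- function(m) {
  n <- nrow(m)
  S <- 0
  for (s in 1:ncol(m)) if (length(unique(m[, s])) > 1) S <- S + 1
  k_bar <- brute_mean_pairwise(m)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_bar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Fu & Li F* via the published constant definitions, coded independently
fu_li_reference <- function(m) {
  n <- nrow(m)
  eta <- 0; eta_s <- 0
  for (s in 1:ncol(m)) {
    tab <- table(m[, s])
    if (length(tab) < 2) next
    eta <- eta + length(tab) - 1
    eta_s <- eta_s + min(sum(tab == 1), length(tab) - 1)
  }
  k_bar <- brute_mean_pairwise(m)
  an <- sum(1 / (1:(n - 1)))
  bn <- sum(1 / (1:(n - 1))^2)
  an1 <- an + 1 / n
  vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
           2 * (n - 1) * an / n^2 - 8 * bn / n) / (an^2 + bn)
  uF <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
           (3 * n * (n - 1))) / an - vF
  (k_bar - (n - 1) / n * eta_s) / sqrt(uF * eta + vF * eta^2)
}

# AMOVA sums of squares from explicit pairwise loops, textbook coefficients
brute_amova3 <- function(m, pop, grp) {
  n <- nrow(m)
  d2 <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    d2[i, j] <- d2[j, i] <- sum(m[i, ] != m[j, ])^2
  ssd <- function(idx) {
    if (length(idx) < 2) return(0)
    acc <- 0
    for (i in idx) for (j in idx) acc <- acc + d2[i, j]
    acc / 2 / length(idx)
  }
  ss_tot <- ssd(1:n)
  pops <- unique(pop); grps <- unique(grp)
  ss_wp <- sum(sapply(pops, function(p) ssd(which(pop == p))))
  ss_wg <- sum(sapply(grps, function(g) ssd(which(grp == g))))
  P <- length(pops); G <- length(grps)
  np <- sapply(pops, function(p) sum(pop == p))
  ng <- sapply(grps, function(g) sum(grp == g))
  pop_grp <- sapply(pops, function(p) grp[pop == p][1])
  msAG <- (ss_tot - ss_wg) / (G - 1)
  msAP <- (ss_wg - ss_wp) / (P - G)
  msWP <- ss_wp / (n - P)
  spng <- sum(sapply(grps, function(g) sum(np[pop_grp == g]^2) / ng[g == grps]))
  n1 <- (n - spng) / (P - G)
  n2 <- (spng - sum(np^2) / n) / (G - 1)
  n3 <- (n - sum(ng^2) / n) / (G - 1)
  sc <- msWP
  sb <- (msAP - sc) / n1
  sa <- (msAG - sc - n2 * sb) / n3
  list(sigma = c(sa, sb, sc),
       phi = c(CT = sa / (sa + sb + sc), SC = sb / (sb + sc),
               ST = (sa + sb) / (sa + sb + sc)))
}

# collapse an alignment matrix with a trivial one-population popmap
quick_hapset <- function(m, pop = rep("P1", nrow(m)), species = rep("sp", nrow(m))) {
  aln <- hap_alignment(m)
  pm <- as_popmap(data.frame(sample = rownames(m), population = pop,
                             species = species, stringsAsFactors = FALSE))
  collapse_haplotypes(aln, pm)
}

write_fasta_tmp <- function(named_seqs) {
  f <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(named_seqs), function(nm)
    c(paste0(">", nm), named_seqs[[nm]]))), f)
  f
}
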