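#' Seeded coalescent sequence simulator
#'
#' Structured coalescent with infinite-sites mutation, used to generate
#' alignments with known truth for every stage of the pipeline. Demes follow
#' an island model with per-lineage migration rate `migration`; a sudden
#' expansion is an instantaneous size change at depth `tau / theta`
#' (coalescent units of twice the current size), where the pre-expansion
#' relative size is `1 / growth`; `split_time` merges all demes into one
#' ancestral pool at that depth (clean-split scenarios). Mutations are
#' Poisson on branches at rate `theta / 2` per unit length and mapped to
#' distinct uniformly chosen sites, so simulated data are homoplasy-free.
#'
#' @param n sequences per deme (scalar or length-`demes` vector, each >= 1;
#'   at least 2 in total).
#' @param demes number of demes K.
#' @param migration per-lineage migration rate (island model; ignored when
#'   `demes = 1`).
#' @param theta scaled mutation rate per sequence of the current
#'   (post-expansion) population.
#' @param expansion `NULL`, or `list(growth = theta1/theta0, tau = ...)`
#'   with `tau` the expansion age in mutational time units.
#' @param L sites available for mutations; enlarged (with a warning) if a
#'   replicate generates more mutations than sites.
#' @param seed integer seed (mandatory for pipeline use).
#' @param split_time depth at which all demes merge into deme 1, or `NULL`.
#' @param rel_size optional per-deme relative sizes (refugium-style demes).
#' @return list with `alignment` ([hap_alignment()]), `popmap`
#'   (`hap_popmap`, populations `P1..PK`, one species `sim`), and `truth`
#'   (parameters, segregating-site count `S`, `tmrca`, total tree length).
#' @export
simulate_coalescent <- function(n = 20, demes = 1, migration = 0, theta = 5,
                                expansion = NULL, L = 1000, seed = 1,
                                split_time = NULL, rel_size = NULL) {
  if (length(n) == 1) n <- rep(n, demes)
  stopifnot(length(n) == demes, sum(n) >= 2, theta > 0, L >= 1,
            migration >= 0)
  if (!is.null(expansion))
    stopifnot(expansion$growth >= 1, expansion$tau >= 0)
  if (is.null(rel_size)) rel_size <- rep(1, demes)
  if (demes > 1 && migration == 0 && is.null(split_time))
    stop("isolated demes never coalesce: set migration or split_time",
         call. = FALSE)
  local_rng(seed, {
    ntot <- sum(n)
    deme_of <- rep(seq_len(demes), n)
    act <- as.list(seq_len(ntot))
    cur_born <- rep(0, ntot)
    lens <- list(); descs <- list()
    t <- 0
    t_exp <- if (is.null(expansion)) Inf else expansion$tau / theta
    shrink <- if (is.null(expansion)) 1 else 1 / expansion$growth
    t_split <- if (is.null(split_time)) Inf else split_time
    merged <- FALSE
    while (length(act) > 1) {
      size_fac <- if (t >= t_exp) shrink else 1
      kd <- tabulate(deme_of, demes)
      coal_rate <- sum(kd * (kd - 1) / 2 / (rel_size * size_fac))
      mig_rate <- if (demes > 1 && !merged) length(act) * migration else 0
      rate <- coal_rate + mig_rate
      if (rate <= 0) {  # wait for the next epoch boundary
        nxt <- c(if (t_exp > t) t_exp, if (t_split > t) t_split)
        if (!length(nxt) || !any(is.finite(nxt)))
          stop("coalescent cannot complete", call. = FALSE)
        t <- min(nxt[is.finite(nxt)])
        if (t >= t_split && !merged) { deme_of[] <- 1L; merged <- TRUE }
        next
      }
      dt <- stats::rexp(1, rate)
      boundary <- min(if (t < t_exp) t_exp else Inf,
                      if (t < t_split) t_split else Inf)
      if (t + dt > boundary) {
        t <- boundary
        if (t >= t_split && !merged) { deme_of[] <- 1L; merged <- TRUE }
        next
      }
      t <- t + dt
      if (stats::runif(1) < coal_rate / rate) {
        w <- kd * (kd - 1) / 2 / (rel_size * size_fac)
        dm <- sample.int(demes, 1, prob = w)
        here <- which(deme_of == dm)
        pair <- here[sample.int(length(here), 2)]
        for (ix in pair) {
          lens[[length(lens) + 1]] <- t - cur_born[ix]
          descs[[length(descs) + 1]] <- act[[ix]]
        }
        act[[pair[1]]] <- c(act[[pair[1]]], act[[pair[2]]])
        cur_born[pair[1]] <- t
        act <- act[-pair[2]]
        cur_born <- cur_born[-pair[2]]
        deme_of <- deme_of[-pair[2]]
      } else {
        ix <- sample.int(length(act), 1)
        others <- setdiff(seq_len(demes), deme_of[ix])
        deme_of[ix] <- if (length(others) == 1) others
                       else others[sample.int(length(others), 1)]
      }
    }
    lens <- unlist(lens)
    total_len <- sum(lens)
    n_mut <- stats::rpois(1, theta / 2 * total_len)
    Luse <- L
    if (n_mut > L) {
      warning("more mutations (", n_mut, ") than sites (", L,
              "); alignment length enlarged")
      Luse <- n_mut
    }
    m <- matrix("A", nrow = ntot, ncol = Luse,
                dimnames = list(sprintf("s%03d", seq_len(ntot)), NULL))
    if (n_mut > 0) {
      branch <- sample.int(length(lens), n_mut, replace = TRUE,
                           prob = lens / total_len)
      sites <- sample.int(Luse, n_mut)
      for (i in seq_len(n_mut)) {
        derived <- sample(c("C", "G", "T"), 1)
        m[descs[[branch[i]]], sites[i]] <- derived
      }
    }
    popmap <- as_popmap(data.frame(
      sample = rownames(m),
      population = paste0("P", rep(seq_len(demes), n)),
      species = "sim", stringsAsFactors = FALSE))
    list(alignment = hap_alignment(m, "sim"),
         popmap = popmap,
         truth = list(n = n, demes = demes, migration = migration,
                      theta = theta, expansion = expansion, L = Luse,
                      seed = seed, S = n_mut, tmrca = t,
                      total_length = total_len))
  })
}

#' Named structured scenarios used across the test-suite
#'
#' Deterministic (seeded) fixtures emulating the study's qualitative
#' regimes: `panmictic` is one well-mixed pool split arbitrarily into four
#' labelled populations (no real structure); `two_clades` is two species
#' that split cleanly long ago (strong phylogeographic structure,
#' NST > GST); `refugium` has two large, diverse refugial demes and two
#' small ones, re-drawn deterministically from seed-derived subseeds until
#' the refugial demes jointly carry at least twice as many private
#' haplotypes as the non-refugial demes.
#'
#' @param style scenario name.
#' @param seed integer seed.
#' @return list with `alignment`, `popmap`, `truth` (as
#'   [simulate_coalescent()]), plus `style`.
#' @export
make_structured_fixture <- function(style = c("panmictic", "two_clades",
                                              "refugium"), seed = 1) {
  style <- match.arg(style)
  out <- switch(style,
    panmictic = {
      sim <- simulate_coalescent(n = 40, demes = 1, theta = 4, seed = seed)
      sim$popmap$population <- paste0("P", rep(1:4, each = 10))
      sim
    },
    two_clades = {
      sim <- simulate_coalescent(n = c(16, 16), demes = 2, migration = 0,
                                 theta = 3, split_time = 6, seed = seed)
      deme <- as.integer(sub("P", "", sim$popmap$population))
      # arbitrary within-clade split so each species has two populations
      sim$popmap$population <- paste0(c("A", "B")[deme],
                                      rep(rep(1:2, each = 8), 2))
      sim$popmap$species <- c("A", "B")[deme]
      sim
    },
    refugium = {
      for (try in 0:99) {
        sim <- simulate_coalescent(n = c(10, 10, 10, 10), demes = 4,
                                   migration = 0, theta = 6, split_time = 3,
                                   rel_size = c(4, 4, 0.25, 0.25),
                                   seed = derive_seed(seed, try))
        hs <- collapse_haplotypes(filter_sites(sim$alignment), sim$popmap)
        priv <- private_hap_count(hs)
        if (sum(priv[c("P1", "P2")]) >= 2 * max(1, sum(priv[c("P3", "P4")])))
          break
      }
      sim$truth$refugial <- c("P1", "P2")
      sim
    })
  out$style <- style
  out
}

# haplotypes confined to a single population, counted per population
private_hap_count <- function(hs) {
  occ <- hs$counts > 0
  priv <- colSums(occ) == 1
  stats::setNames(vapply(seq_len(nrow(occ)),
                         function(k) sum(occ[k, ] & priv), 0L),
                  rownames(hs$counts))
}
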