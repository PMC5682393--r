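---
title: "Methods: haplotype-based phylogeography with notophylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-based phylogeography with notophylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notophylo)
```

notophylo implements the standard chloroplast/ITS phylogeographic workflow
for samples structured into populations and species, built around the four
endangered *Notopterygium* herbs of the Qinghai–Tibetan Plateau region:
haplotype inference, diversity and differentiation, hierarchical AMOVA,
neutrality tests, mismatch-distribution demographic inference with
expansion dating, median-joining networks, and a strict-clock divergence
surrogate. This vignette documents the models, the numerical choices, and
the boundaries of what the test-suite does and does not establish.

## Data model and haplotype inference

Alignments are character matrices over `A C G T`, the six IUPAC
heterozygote codes `R Y M K S W`, `N`, and the gap `-`; all sequences of a
locus must be equal length (inputs are pre-aligned; the package never
aligns). Chloroplast loci are concatenated per sample (`concatenate_loci()`,
in the order supplied — the locus order is configurable because nothing in
the statistics depends on it). Internally all site indices are 0-based
half-open; only printed reports (e.g. the changed-site lists on network
edges) use 1-based positions.

Nuclear (ITS) individuals carrying heterozygote codes are split into two
pseudo-haplotype copies by `phase_ambiguities()`. The rule is a
deterministic heuristic, not statistical phasing: the first ambiguous site
sends the alphabetically smaller base to copy `_a`; every later ambiguous
site tries both base-to-copy assignments and keeps the one minimizing the
summed Hamming distance of the two partial copies to their nearest fully
resolved neighbours in the sample, breaking ties alphabetically. This
reproduces the common practice of resolving double peaks toward observed
resolved sequences while remaining reproducible; it will differ from
EM/MCMC phasing exactly where the data are genuinely ambiguous, which is
why collapsed ITS haplotype counts — not phase assignments — are the unit
used downstream. Chloroplast data are haploid (one copy per individual);
phased ITS contributes two copies per individual.

Statistics use `complete_deletion` site filtering by default: every column
with `-` or `N` in any sequence is dropped, giving one deterministic
alignment length for π and the mismatch classes. The `pairwise` policy
keeps all columns and skips missing sites pair-by-pair in
`hamming_matrix()`; it changes effective length per pair and is therefore
not used for π.

## Diversity and differentiation

Per-population haplotype diversity is Nei's unbiased estimator
$H_d = \frac{n}{n-1}\,(1 - \sum_i p_i^2)$ with its sampling SD; nucleotide
diversity is the unbiased mean pairwise difference per site
$\pi = \frac{n}{n-1} \sum_{i \ne j} p_i p_j d_{ij} / L$, identical to the
average over all $\binom{n}{2}$ sequence pairs. The reported SD of π is
the standard no-recombination sampling SD. The $n/(n-1)$ corrections match
the estimator family used throughout.

Differentiation uses the Pons–Petit estimators through one generic core:
within-population diversity $v_S$ (mean of per-population unbiased
diversities) and total diversity $v_T$ with the harmonic-mean sample-size
correction $v_T = \bar{p}' D \bar{p} + v_S/(\tilde n K)$. With the trivial
distance ($d_{ij} = 1 - \delta_{ij}$) this yields $h_S, h_T, G_{ST}$;
with observed haplotype distances it yields the ordered-allele analogues
and $N_{ST}$. Under equidistant haplotypes $N_{ST} = G_{ST}$ to machine
precision, which the suite asserts. Populations contributing fewer than
two copies are excluded, as the estimators require. Standard errors are
delete-one-population jackknives: the analytic variance expressions add
nothing downstream (no statistic consumes them), and the jackknife is both
transparent and consistent for these ratio estimators; note that on a
fixed configuration with no differentiation the unbiased estimators give a
small *negative* $G_{ST}$ of order $1/(n-1) - 1/(\tilde n K)$ — reported
as computed, never truncated.

The permutation U-test for phylogeographic structure permutes haplotype
identities in the distance matrix (default 1000 permutations), leaving
$G_{ST}$ untouched, and reports the one-sided
$p = \Pr(N_{ST}^{perm} - G_{ST} \ge N_{ST}^{obs} - G_{ST})$ with a +1
continuity correction, plus $U$ = observed difference / permutation SD.
One-sided because the scientific claim being tested is directional
(related haplotypes co-occurring within populations).

## AMOVA

`amova()` decomposes squared pairwise distances (Hamming steps entered
squared, the haplotype-AMOVA convention of the Arlequin family) into
among-species, among-populations-within-species and within-population
components using the standard sums-of-squares identities
$SS(A) = \frac{1}{|A|}\sum_{i<j \in A}\delta_{ij}^2$ and the textbook
n-coefficients for unequal sample sizes, then forms
$\Phi_{CT}, \Phi_{SC}, \Phi_{ST}$. The identity
$(1-\Phi_{ST}) = (1-\Phi_{SC})(1-\Phi_{CT})$ holds on every input and is
property-tested. Negative variance components are reported as computed and
truncated at zero only for the percentage display. Permutation schemes are
the conventional ones per statistic — individuals across the whole system
for $\Phi_{ST}$, individuals within species for $\Phi_{SC}$, whole
populations among species for $\Phi_{CT}$ — with
$p = (\#\{\ge obs\} + 1)/(B + 1)$. With few populations the $\Phi_{CT}$
permutation space is small and p-values are correspondingly coarse; that
is a property of the design, not the implementation.

## Neutrality tests

`tajimas_d()` uses the standard constants; at $n = 2$ both the numerator
and the variance vanish and the statistic is returned as its analytic
limit 0. `fu_li_f_star()` is the no-outgroup $F^*$ built from total
mutations $\eta$ and singleton mutations $\eta_s$ (alleles carried by
exactly one sequence, capped at one fewer than the alleles at the site),
with the corrected variance constants of Simonsen–Churchill–Aquadro; the
constants are spelled out in the code and cross-checked in the tests
against an independent transcription. `fus_fs()` evaluates
$S' = \Pr(K \ge k_{obs} \mid \hat\theta = \pi, n)$ by the Ewens sampling
formula with unsigned Stirling numbers of the first kind computed by their
recursion in log space (stable into the hundreds of sequences), and
$F_S = \ln(S'/(1-S'))$; $k_{obs} = 1$ returns $+\infty$ by definition
rather than a rounded tail sum. π here is the mean pairwise difference per
*sequence*, the scale these statistics are defined on.

Significance comes from fixed-S coalescent simulation: constant-size
genealogies with the observed number of segregating sites placed
multinomially on branches by length — the convention that conditions on
the observed data size. D and $F^*$ are tested two-sided (absolute
deviation from the null mean), $F_S$ one-sided low, the direction that
signals expansion.

## Mismatch distributions and expansion dating

The sudden-expansion model uses the equilibrium form
$F_i(\theta) = \theta^i/(1+\theta)^{i+1}$ and the transient distribution

$$F_j(\tau) = F_j(\theta_1) + e^{-\tau(\theta_1+1)/\theta_1}
  \sum_{i \le j}\left[F_i(\theta_0) - F_i(\theta_1)\right]
  \frac{\tau^{\,j-i}}{(j-i)!},$$

which reduces to the $\theta_0$ equilibrium at $\tau = 0$ and to a
Poisson wave crest near $\tau$ for $\theta_0 = 0$, $\theta_1$ large —
both asserted in the tests, as is normalization to 1 within $10^{-9}$
over random parameter draws. Fitting minimizes the SSD over the observed
difference classes on a coarse grid (τ in [0, 25] step 0.25; θ0 in
[0, 20]; θ1 log-spaced and capped at 99999, the open-ended-growth
convention of the tool family this mirrors) followed by a local
refinement pass; noise-free model curves recover τ within ±0.5.
Significance is parametric bootstrap: samples of the same size simulated
under the fitted expansion, each refitted, with
$p_{SSD} = \Pr(SSD_{sim} \ge SSD_{obs})$ and Harpending's raggedness
$r = \sum (x_i - x_{i-1})^2$ (trailing zero convention) tested the same
way; the τ CI is the percentile interval of the refitted bootstrap τ.

The modality flag smooths the observed histogram with a ±1 moving average
and counts local maxima with a prominence rule: a secondary peak only
counts if the valley toward higher ground drops to at most half its
height. Without the rule, the sampling bump at the zero-difference class
(identical copies within families) would split a single expansion wave
into two "peaks" in a large fraction of simulated expansions.

Expansion ages apply the composite conversion exactly as the source tool
chain prints it: $t = \tau/(2u)$ with $u = 2\mu k g$ (μ per site per
year, k sequence length in bp, g generation time in years; defaults
k = 1605, g = 3, μ ∈ {1, 3} × 10⁻⁹). A conventional derivation — τ = 2ut
with u per sequence per *generation* — would instead give
$t_{years} = \tau/(2\mu k)$; the composite form divides this by $2g$. The
formula is kept verbatim deliberately so the published table reproduces;
the discrepancy is a property of the source convention and is surfaced
here rather than silently "fixed". Since $t(\mu)\,\mu$ is constant, the
paired rate columns always differ by exactly the rate ratio.

## Median-joining networks and strict-clock dating

`median_joining_network()` follows the median-joining construction:
iterate a minimum spanning network over the current node set (all links
within ε of minimal; ε = 0 default, the published default), propose the
per-site majority consensus of every connected triplet, accept — in
deterministic lexicographic order — median vectors whose addition strictly
lowers the network cost, and finally prune any median whose removal does
not raise the cost. Ties in the consensus resolve toward the first
sequence of the triplet in lexicographic order, making the whole
construction deterministic. On homoplasy-free (infinite-sites) data the
result is a tree whose total steps equal the number of segregating sites;
the 3-haplotype star toy recovers its hand-enumerated optimum with exactly
one median. Exports: edge-list CSV (with 1-based changed-site lists) and
GraphML with node frequency, median flag and per-population counts.

`strict_clock_ages()` is a deliberately simple surrogate for Bayesian node
dating, clearly not a reimplementation of it: per-site net divergence
$d_A = d_{XY} - (d_X + d_Y)/2$ converted as $T = d_A/(2\mu)$ per rate.
Within-group diversities use the plug-in (frequency) form so identical
groups give exactly $d_A = 0$. Distances are uncorrected Hamming
proportions — intraspecific divergences here are far from saturation, so
a multiple-hit correction would move third digits at most; this is a
documented limitation, as is the site-bootstrap CI, which captures
mutational but not genealogical variance and therefore under-covers when
the split is recent relative to within-species coalescent times.

## The coalescent generator and what the tests show

`simulate_coalescent()` is a standard structured coalescent: exponential
waiting times, island-model migration at a per-lineage rate, sudden
expansion as an instantaneous size change at depth τ/θ (time in units of
twice the current size; pre-expansion relative size 1/growth), an optional
clean split (all demes merging into one ancestral pool at a stated depth),
and infinite-sites mutation — Poisson on branches at rate θ/2, mapped to
distinct uniformly drawn sites, so simulated data are homoplasy-free by
construction (which is what makes the network tree-property test exact).
If a replicate draws more mutations than sites the alignment is enlarged
with a warning rather than silently re-using sites. Calibration checks:
E[S] = θ·a₁ at n = 20 within Monte-Carlo error, mean pairwise difference
θ at n = 2, FST strictly decreasing in migration across a 4-point grid,
Tajima's D centred on 0 (±0.1) over 2000 neutral replicates, and round-trip
recovery of τ = 5 (median within ±1.5 over 200 expansion replicates with
growth 100, n = 20, θ₁ = 100, L = 2000 — sizes chosen to emulate a strong
Pleistocene expansion while each replicate stays millisecond-scale).

The named fixtures define the study conditions used across the suite:
`panmictic` (one pool of 40 arbitrarily labelled as 4 populations — the
null for AMOVA calibration), `two_clades` (two species of 16 copies each,
split at depth 6, θ = 3, each clade arbitrarily split into two
populations — the alternative for NST > GST and ΦCT), and `refugium`
(four demes, two large/diverse and two small, merged at depth 3; re-drawn
deterministically from seed-derived subseeds until the refugial demes
carry at least twice the private haplotypes of the others, making the
advertised property by-construction). What passing these tests shows is
that the estimators and their permutation/bootstrap machinery behave
correctly on data from the generating models the methods assume. Real
chloroplast data add homoplasy, indels, rate variation across sites and
non-equilibrium structure that the generator deliberately omits, so the
tests validate the implementation, not the biological adequacy of the
models.

## Pipeline and reproducibility

`run_pipeline()` chains every stage from a single config (YAML file or
list) and writes one CSV per stage plus a provenance table of all
settings. A single master seed drives everything: stage seeds are derived
by fixed offsets, so re-running a config reproduces every output file
byte-for-byte (asserted in the tests). Replicate counts below 100 warn
but run, for exploration; published analyses should use the defaults
(1000 permutations/bootstraps).

## Known limitations

- Phasing is heuristic; genuinely ambiguous double peaks phase
  deterministically, not probabilistically.
- The Pons–Petit SEs are jackknife, not the closed-form variances; both
  are asymptotic and neither enters any test statistic here.
- The mismatch fit is least-squares on class frequencies (not GLS), like
  the tool family it mirrors; bootstrap p-values inherit that choice.
- The strict-clock surrogate ignores rate variation and multiple hits and
  its CI ignores genealogical variance; it reproduces the *structure* of
  paired-rate age tables, not a posterior.
- Indels are filtered, never coded as characters.
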