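---
title: "Models and methods behind armdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind armdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armdyn)
```

`armdyn` implements the statistical machinery for asking two questions
about chromosome arm evolution in malaria mosquitoes (and any system with
comparable physical maps):

1. Do polymorphic inversions on homologous arms of *different* species
   capture the same homologous genes more often than chance placement
   would predict?
2. Do chromosome arms differ in how fast conserved gene order is
   disrupted over evolutionary time?

Both questions are answered from ordered marker maps: per species and arm,
a list of DNA markers with megabase positions and homology-group labels,
plus the coordinates of the polymorphic inversions on each arm. No
sequence data are involved.

## Data model and conventions

All coordinates are megabases on a per-arm axis starting at 0, and all
intervals are half-open `[start, end)`. A marker sitting exactly on a
region's start belongs to it; one on the end does not. Inversions may
overlap (the nested 2R inversion systems of these species do), and a
marker inside two overlapping inversions counts in both, so region counts
carry no partition constraint. Each arm also carries a single aggregate
*outside* region: the complement of the union of its inversions,
represented by its total length rather than as a set of intervals. Markers
are single-copy per species (at most one marker per homology group), and
markers without a homolog in the partner species are dropped from pairwise
analyses — they carry no sharing information.

## The sharing test

For a pair of homologous arms from two species with `N` shared homologous
markers, let `f_i` and `f_j` be the fractional lengths of region `i` on
arm 1 and region `j` on arm 2. If markers fall uniformly and independently
on both arms, the expected number co-located in the pair `(i, j)` is

    E_ij = N * f_i * f_j.

The test statistic sums the discrepancy `(O_ij - E_ij)^2 / E_ij` over
inversion-by-inversion pairs. The statistic's scope is deliberately
restricted to inversion pairs — the outside region enters only the
Bayesian model below — because the scientific question is about
inversions, and the aggregate outside region would otherwise dominate the
sum.

Two p-values are reported. The asymptotic one uses the upper chi-squared
tail; because no parameters are estimated and overlapping regions impose
no sum constraint, the degrees of freedom default to the number of
included inversion pairs (a `df` argument overrides this, since other
conventions are defensible). The asymptotic law is unreliable at the
study's marker counts (`N` of order 100–230 spread over ~20 region
pairs), so the primary p-value is simulated: every homolog pair is
repositioned uniformly and independently on its two arms, the counts are
re-tallied (with the same overlap rules), and the statistic is recomputed
against the *original* expected counts. The p-value is the plain
proportion of draws whose statistic reaches the observed one; ties count
as exceedances, and a reported 0 is printed as `< 1/n_draws`. With a fixed
seed the draw sequence, and hence the p-value, is exactly reproducible.

## The Bayesian sharing-intensity model

The test says *whether* sharing is nonrandom; the hierarchical model says
*where* and *by how much*. For every region pair, including the outside
regions,

    O_ij ~ Binomial(N, pi_ij),   pi_ij = f_i * f_j * gamma_ij,
    gamma_ij = lambda_i^(1) * lambda_j^(2) + mu_ij.

`gamma_ij` is the multiplicative sharing intensity: 1 means chance-level
sharing, 6 means six-fold excess. It decomposes into a product of
per-region marginal intensities — regions sharing a row or column are not
independent, and the product form lets a generally "sticky" region raise
all its pairs — plus a random effect `mu_ij` for genuinely hot or cold
pairs. The random effect has a three-component mixture prior: a point
mass at zero with weight `p0 = 0.99`, a positive-truncated normal
(mean `mu_H > 0`, spread `sigma`) with weight `pH = 0.005`, and a
negative-truncated normal (mean `mu_C < 0`) with weight `pC = 0.005`.
The small component weights mean only large deviations from the neutral
model get declared hot or cold. The weights are fixed constants, not
estimated.

Identifiability: an overall scale can move freely between the two
marginal sets, so the first region of species 1 is anchored at
`lambda == 1` and marginal intensities are interpreted only through
ratios. Each cell carries a Jeffreys-type reference term
`pi^(-1/2) (1 - pi)^(-1/2)` on its binomial proportion; the hot/cold means
have flat priors, bounded to `(0, 50]` and `[-50, 0)` purely so the
conditional stays proper when no pair occupies a component (the bound is
far outside any plausible intensity and has no practical effect).
`sigma` is a fixed constant (default 1): with at most a handful of active
random effects there is essentially no information to estimate it, and
freeing it mostly adds chain wander.

### Sampling

The posterior is explored by Metropolis-within-Gibbs, written in C++:

* adaptive random walks on the log marginal intensities (one region at a
  time; proposals making any `pi` leave `(0, 1)` or any `gamma` negative
  are rejected, which keeps the binomial well-defined);
* a mixture-allocation move per pair: the component is proposed
  *uniformly* over {neutral, hot, cold} with `mu` drawn from the proposed
  component's conditional prior; the component densities cancel against
  the proposal and the mixture weights appear in the acceptance ratio.
  Proposing the component from its prior weights would target the same
  posterior but visit the 0.005-weight components too rarely to mix at
  practical chain lengths;
* a within-component random walk refining an active `mu`;
* random walks on `mu_H` and `mu_C` (drawn uniformly from their bounded
  support when their component is empty; the truncated-normal
  normalisation constants are included otherwise).

Proposal scales adapt toward ~44% acceptance during burn-in only, so the
retained chain is a fixed-kernel Markov chain. Multiple chains start from
dispersed marginal intensities; convergence is summarised by split-chain
R-hat per pair, and a fit exceeding the threshold is flagged (with a
warning), never silently discarded. A fixed seed and chain count give
bit-identical results.

Default chain sizes (20k burn-in, 20k retained per chain, 4 chains) are a
desk-scale compromise; the `burnin`/`samples` arguments scale up to
reference-quality runs. With `pH = pC = 0` the model collapses exactly to
the pure product-intensity form, which the test suite uses as an
invariant.

### Hotspots and the connectivity ratio

`hot_probability()` reports `Pr(gamma_ij > 1 | data)` as the fraction of
retained samples above 1. `connectivity_ratio()` compares sharing outside
inversions to sharing inside: per posterior sample, the unweighted mean of
`gamma` over pairs involving an outside region (there are `N1 + N2 + 1`
of them for `N1`, `N2` inversions on the two arms) divided by the
unweighted mean over inversion pairs. Ratios below 1 mean the material
outside inversions is under-connected relative to the inversions. The
means are unweighted by region length — a weighted variant is equally
defensible, but the unweighted form matches the interpretation of the
intensities as already length-corrected quantities.

## Conserved blocks and their classification

A conserved block between two species is a maximal run of at least two
shared markers that is (a) consecutive among shared markers on both arms
(no intervening shared marker on either side), (b) colinear in identical
or fully reversed order, and (c) distance-conserved: each adjacent gap
pair satisfies `|g_A - g_B| <= rel_tol * max(g_A, g_B)`. Physical
distances never match exactly across species, so "same distance" needs a
tolerance; the default `rel_tol = 0.5` accepts up to a two-fold gap
discrepancy, and `rel_tol = Inf` reduces the criterion to pure
colinearity. Two-marker blocks are allowed, and a reversed run counts as
conserved.

One boundary subtlety: a truly maximal forward run and reversed run can
share their boundary marker. Blocks are required to be disjoint in marker
membership, so ties break left-to-right — the earlier-starting block
keeps the marker and the remainder survives if it still has two markers.
The test suite checks the scanner against an independent brute-force
enumeration of maximal valid intervals under the same documented
tie-break.

With three species, a run contained in a block of *every* pairwise
comparison (over a common homolog universe) is *fully conserved*; the
remainders of pairwise blocks after fully conserved runs are removed are
*partially conserved*, labelled with the pair in which they survive —
these are blocks that were disrupted in the third lineage. Spans and
lengths are measured on a designated reference species. Summary counts
include partial blocks only for pairs involving the reference species,
mirroring how such comparisons are tabulated against a reference genome.

## The compound Poisson disruption model

Per arm `j` of length `L_j`, the number of conserved blocks is modelled as
`N(L_j) ~ Poisson(lambda_j * L_j)` and each block's arm-scaled length
`b / L_j` as i.i.d. `Exponential(rate = gamma_j)` — the unique length law
consistent with the mean total conserved length
`E[R_j] = N(L_j) * L_j / gamma_j`. With `Gamma(a0, b0)` priors the
posteriors are conjugate:

    lambda_j | data ~ Gamma(a0 + N, b0 + L_j)
    gamma_j  | data ~ Gamma(a0 + N, b0 + sum(b / L_j))

Defaults `a0 = b0 = 0.001` are near-flat, so posterior means approach the
maximum-likelihood values `N / L` and `N / sum(b / L)`; zero blocks leave
a proper, prior-dominated posterior that is flagged low-information.

The process is fitted twice per arm — to fully conserved blocks (`c`) and
to conserved-plus-disrupted blocks (`c+d`) — and paired posterior draws
give the differences `lambda^(c) - lambda^(c+d)` and
`1/gamma^(c) - 1/gamma^(c+d)` that characterise the disrupted blocks,
with the combined summary `z = lambda_diff * gamma_diff / L` (*blocks per
region length per total length*). Strong overlap of a difference with
zero means a negligible disruption rate; the *direction probability* (the
posterior mass on the dominant sign) is 0.5 in that case. The `c` and
`c+d` posteriors are differenced as if independent although `c` is a
subset of `c+d`; this is an approximation inherited from the analysis
design. Across arms, `rank_disruption()` reports both the probability
that an arm's `|z|` is the largest and the probability that its
`lambda_diff` is the most negative, since either can be meant by "the
highest rate of disrupted-block accumulation".

## What the synthetic generator does and does not emulate

`gen_shared_markers()` places `N` homolog pairs by atomising each arm at
inversion breakpoints and drawing a region pair from a categorical with
weight `len_a * len_b * gamma*(a, b)`, then positioning uniformly inside
the chosen atoms. A planted intensity on an inversion applies to all its
atoms; where overlapping inversions disagree the maximum applies. With
all `gamma* = 1` the marginal law is exactly uniform per arm — the
verified distribution of the real markers. Note one consequence of
conditioning on `N`: planting a hotspot re-normalises the placement law,
so the realised intensity of a planted `gamma* = 6` pair is
`6 / Z` with `Z` slightly above 1, and recovered intensities of other
pairs sit slightly below 1. The recovery checks in the test suite average
over replicate datasets for this reason.

`study_sharing_scenario()` freezes the study conditions used throughout
the tests and the acceptance script: a 61.5-Mb arm with five inversions of
4–12.5 Mb (two overlapping) against a 55-Mb arm with four, and
`N = 230` homologs (the 87–230 range covers what a physically plus
in-silico mapped species pair shares). `gen_rearranged_orders()` evolves
three lineages from an 87-gene ancestral arm (0.7-Mb spacing, ~61 Mb) by
independent segment reversals, 12 per lineage by default — pairwise
unsigned rearrangement distances between these species are ~30–35 and
concentrate on the fast-evolving arm emulated here. Reversal segments are
uniform over contiguous segments of length at least 2 (a one-gene
unsigned reversal is a no-op); a truncated-geometric length law is
available.

The generator does not emulate: non-uniform marker ascertainment,
translocations or pericentric inversions (none were observed between
these genomes), marker loss between species (every generated homolog is
present in both), or cytological-to-physical coordinate distortion. A
pass on synthetic data therefore validates the inferential machinery
under the stated placement laws, not the upstream mapping.

## Numerical choices and problem sizes

* Ties in the Monte-Carlo p-value count as exceedances; the p-value is a
  plain proportion (no +1 correction), matching its definition as the
  fraction of null draws at or above the observed statistic.
* Region pairs with zero fractional length are excluded from both the
  statistic and the model with a warning (they would divide by zero).
* The repositioning simulation is vectorised in blocks of ~2000 draws to
  bound memory at large `N`.
* The test suite runs the calibration study at 500 datasets x 1000 draws
  (`N = 200`, 4x4 inversions), the power study at 100 replicates, the
  hotspot recovery at 5 replicate fits of 50k/50k x 4 chains, the
  block-finder/oracle comparison at 1000 random instances of up to 10
  markers, and the coverage study at 200 simulated arms — sizes chosen so
  the whole suite completes in a few minutes on one core while keeping
  Monte-Carlo error well inside the asserted bands.

## Known limitations

* The intensity model conditions on the published inversion coordinates;
  uncertainty in inversion breakpoints is not propagated.
* The connectivity ratio treats the outside region as one aggregate;
  spatial structure outside inversions is invisible to it.
* Differencing the `c` and `c+d` fits ignores their overlap (see above).
* The block finder's tolerance is a single global constant; real maps may
  warrant per-arm or length-dependent tolerances.
* With very small region fractions the binomial-proportion Jeffreys term
  shrinks intensities slightly toward zero; at the study's marker counts
  the effect is a few percent.
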