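---
title: "Methods: quartet signal-and-noise analysis with unequal branch lengths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quartet signal-and-noise analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsn)
```

## The model

A quartet is parameterized by five (duration, rate) pairs: the internode
(`t0`, `lam0`) and four subtending branches (`T1..T4`, `lam1..lam4`).
Durations are in arbitrary time units; rates are average substitution
rates per unit time, so only the products `lam * t` (expected numbers of
substitutions) affect any probability. Character evolution on each branch
is a stationary, reversible continuous-time Markov chain over k states
with rate matrix **Q** built from symmetric exchangeabilities r_ij and
equilibrium frequencies pi: q_ij = s·r_ij·pi_j, with the global scale s
fixed so that the average rate at equilibrium, sum_i sum_{j≠i} pi_i q_ij,
equals the requested `lam`. The root state (the ancestral state M at one
end of the internode) is drawn from the model's own equilibrium
frequencies; non-stationary or non-reversible processes are out of scope.

Pattern probabilities are the literal sums of
pi_M p_MN p_MC1 p_MC2 p_NC3 p_NC4 over the state tuples defining each
AABB pattern. The production path contracts these sums over the ancestral
states using per-branch transition matrices (a handful of k×k matrix
products, O(k³) rather than O(k⁶)); `enumerate_oracle()` retains the naive
six-nested-loop sum, and the equivalence of the two on random instances is
asserted by the test suite at 1e-12.

The probability of *true* synapomorphy multiplies the internode signal
probability, 1 − sum_M pi_M p_MM(lam0, t0), by the no-change probability
e^{−(lam1·T1 + … + lam4·T4)}. The exponential uses the *average* rate on
each branch. Under JC (and any equal-frequency symmetric model) the exit
rate from every state equals the average rate, so this is exact. Under
HKY/GTR the state-specific exit rates −q_ii differ from `lam`, so the
expression is the standard rate-averaged approximation; empirically
Pi ≤ y holds throughout the parameter ranges exercised here (the suite
checks it on random quartets drawn from the JC/K2P/HKY/GTR model set), but
we do not claim it as a theorem for arbitrary reversible models.

## Numerical choices

* **Matrix exponential.** For reversible **Q** the similarity transform
  S = D·Q·D⁻¹ with D = diag(√pi) is symmetric, so `eigen(symmetric = TRUE)`
  gives an exact real spectral decomposition and
  P(t) = D⁻¹·V·e^{Λt}·V′·D. This is preferred over scaling-and-squaring
  because reversibility guarantees the transform's validity, and it makes
  P(t) cheap for many t. At `t = 0` or `lam = 0` the identity is returned
  exactly rather than through the eigenbasis, so degenerate branches give
  exactly zero pattern probabilities instead of 1e-16-level noise.
  Entries in (−1e-12, 0) arising from round-off are clamped to 0.
* **Tolerances.** Construction-level identities (frequencies summing to 1,
  oracle equivalence) are held to 1e-12; single matrix identities (row
  sums, stationarity, detailed balance) to 1e-10; products of matrices
  (Chapman–Kolmogorov) to 1e-9. These follow from double precision with
  k ≤ 20 states.
* **Ratio sentinels.** Branch-length-space scans touch axes where both
  homoplasy probabilities vanish. Ratios follow IEEE conventions — `Inf`
  for positive/0, `NaN` for 0/0 — and the CSV writer emits `inf`/`nan`
  tokens, so downstream contouring can mask them without silent failures.
* **Optimum and threshold of a rate curve.** The curve is evaluated on an
  ascending grid (default: 200 log-spaced rates on [1e-3, 50], which
  contains the optima and thresholds of all built-in families); the grid
  argmax is refined by golden-section search in its bracketing interval,
  and the threshold rate is the first sign change above the optimum,
  refined by bisection to 1e-8 relative tolerance. Smoothness justifies
  both: every curve value is a composition of exponentials. If the refined
  maximum falls below the best grid value (possible at flat maxima), the
  grid value is kept.
* **p-lengths.** The JC conversion p = 3/4 − 3/4·e^{−4λt/3} saturates to
  exactly 0.75 in double precision once λt ≳ 30; the inverse rejects
  p ≥ 0.75 with a domain error naming the admissible range [0, 0.75).

## The built-in parameterizations

* **Zone trees.** `"huelsenbeck_hillis"` ties the internode and subtending
  branches 1 and 3 (opposite sides of the internode) to the three-branch
  p-length `pa`, and branches 2 and 4 to the two-branch length `pb`;
  `"siddall"` ties the internode and branches 1 and 2 (same side) to `pa`,
  branches 3 and 4 to `pb`. Rates are fixed at 1 and the durations carry
  the lengths — under JC only the products matter, so nothing is lost.
  Default scan bounds [0.01, 0.74] avoid the p = 0 ratio singularities and
  the p = 0.75 pole; grid resolution defaults to 50×50 and is recorded in
  the output sidecar, since no canonical resolution exists for these maps.
* **Rate families.** `example_family("example2", scale = l)` is the
  asymmetric clock-like quartet: t0 = 0.1, T1 = T3 = 0.4,
  T2 = T4 = 0.4·l, all five rates bound to the free λ. `"example3"` is the
  symmetric tree with rate variation: t0 = 0.1, T1..T4 = 0.1·l, branches
  1 and 3 fixed at rate 1, the internode and branches 2 and 4 free. The
  sources describing this family disagree on which binding generated the
  published curves (the alternative — internode plus branches 1 and 3
  free, 2 and 4 fixed — appears in the accompanying text); we expose the
  first as `"example3"` and the second as `"example3_alt"` rather than
  guessing silently. `"example4"` fixes `"example3"` at scale 2.5 and is
  the family used for model comparison, with the ACT1 presets
  (`model_preset("act1-jc")` … `"act1-gtr"`) supplying the estimated
  exchangeabilities and frequencies. A single `scale` argument plays the
  role written variously as *l* or *m* in the sources.

## The simulator, and what passing tests show

`simulate_characters()` draws, per character, M from pi, N from row M of
the internode transition matrix, C1/C2 from rows M and C3/C4 from rows N
of the subtending matrices, then classifies the tip tuple into
synapomorphic / homoplasious x1 / homoplasious x2 / other. Draws are
inverse-CDF lookups on row cumulative sums fed by `runif`, so a seed fixes
the output across platforms; the caller's RNG state is restored on exit.

The simulator emulates exactly the generative model of the analytical
theory — i.i.d. characters, one shared model, constant per-branch rates,
no rate variation across sites, no indels, no alignment error, and
classification into the three AABB categories only. Agreement between
simulated frequencies and the analytic y, x1, x2 (the suite requires
|z| < 3.9 binomial standard errors at n = 100,000 for three
configurations) therefore validates the internal consistency of the
implementation, not the adequacy of these assumptions for real
alignments: real data add among-site rate heterogeneity, model
misspecification and non-independence that the theory deliberately
abstracts away.

## Problem sizes

The default test and validation runs use: 100 random quartets for oracle
equivalence (each checked against the full 4⁶-term sum), 50×50 nodes per
branch-space map, 120–200 rate points per curve with four asymmetry
levels, and 100,000 simulated characters per stochastic configuration.
These sizes give sub-minute runs per component while leaving Monte Carlo
standard errors far below the effect sizes being checked.

## Known limitations

* Non-reversible and non-stationary models, among-site rate variation
  (Gamma/invariant sites), codon models and shipped empirical amino-acid
  matrices are out of scope; the generic `MK_K`/`CUSTOM` interface covers
  k-state symmetric and user-supplied reversible models instead.
* The AABB patterns are treated as the entire parsimony-informative set;
  partially informative non-AABB patterns (which likelihood methods can
  exploit) are counted only in the simulator's `other` category.
* Utility here predicts *consistency* (sign) and relative informativeness,
  not finite-sample power; no sequence-length calculation is provided.
* Zone maps emit field values on a grid; contour rendering is left to
  downstream plotting.
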