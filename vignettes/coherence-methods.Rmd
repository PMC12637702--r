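---
title: "Attractor and basin coherence in Boolean networks: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attractor and basin coherence in Boolean networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bncoherence)
```

## The model

A Boolean network is a finite dynamical system on $N$ binary nodes,
$F : \{0,1\}^N \to \{0,1\}^N$, $x \mapsto (f_1(x), \dots, f_N(x))$, where
each update rule $f_i$ reads only its regulators (the wiring diagram) and all
nodes update synchronously. The deterministic dynamics partition the $2^N$
states into basins of attraction: every trajectory ends in an attractor — a
fixed point or limit cycle — which in a gene-regulatory reading represents a
phenotype or cell type.

`bncoherence` quantifies how robust this phenotype assignment is to
single-gene perturbations:

* **state coherence** $\psi_x$: the fraction of the $N$ single-bit-flip
  neighbours of $x$ whose trajectories return to the same attractor as $x$;
* **basin coherence** $\psi_B$: the unweighted mean of $\psi_x$ over all
  states of a basin;
* **attractor coherence** $\psi_A$: the mean of $\psi_x$ over the cycle
  states only;
* **network coherence** $\psi_F$: the mean over all $2^N$ states, equal to
  the basin-size-weighted mean of the basin coherences.

The substantive question is the *within-basin stability gradient*: whether
the attractor states themselves are as safe as the transient states that
feed them. The two 3-node worked examples shipped as `fixtureF()` and
`fixtureG()` isolate this: both have fixed-point basins of sizes 5 and 3,
basin coherences 2/3 and 4/9 and network coherence 14/24, yet the attractor
coherences are (1/3, 1/3) in one network and (1, 2/3) in the other. Basin
structure alone does not determine attractor stability.

```{r fixtures}
F <- network(fixtureF())
attractorRecords(F, networkId = "F")
```

## Coherence curves and the coherence gap

Because the expected coherence of a basin depends strongly on its relative
size $s$, ensembles are compared on the *conditional* curves
$E[\psi_B \mid s]$ and $E[\psi_A \mid s]$, integrated over a uniform size
axis. `coherenceCurves()` bins pooled per-attractor records (one record per
attractor; the attractor is the unit of analysis) into 1000 equal
subintervals of $(0, 1]$, averages within bins, and reports

* `AUC:BC` and `AUC:AC`, the areas under the two binned curves,
* `deltaAUC = AUC:BC - AUC:AC`, the *coherence gap*, and
* the excess over 0.5, the analytic baseline for completely random basin
  structure (in which a state's expected coherence equals its basin's
  relative size).

**Empty-bin policy.** At desk scale many of the 1000 bins receive no record.
The default fills empty bins by linear interpolation between the nearest
occupied bins, clamped at both ends; the alternative
`policy = "renormalize"` averages occupied bins only. Interpolation is the
default because it keeps the integral a proper area under a curve defined on
all of $(0, 1]$; both are exposed because neither convention is canonical.
Whenever the longest empty run reaches 0.02 of the size axis the curves are
flagged `excluded` and the gap accessors refuse, since the conditional means
are then unreliable over a non-negligible range; the raw `deltaAUC` slot
remains available for screening analyses.

**Perturbation semantics.** A perturbed state is classified by following the
deterministic dynamics all the way to its attractor, never by a one-step
comparison; this matters for transient states, whose one-step image may lie
far from the eventual attractor.

## Canalization, bias and sensitivity

A variable is *canalizing* when one of its values alone fixes the rule's
output. Iteratively peeling all canalizing variables and substituting their
non-canalizing values yields the *canalizing layer structure*
$(k_1, \dots, k_r)$; the depth $k = \sum k_i$ counts the variables that
eventually canalize, and rules with $k$ equal to the arity are *nested
canalizing functions* (NCFs). `layerStructure()` implements the peeling
directly and doubles as the oracle against which all random-rule generators
are verified in the test suite. Two summary statistics drive the analysis:

* bias $p$ (fraction of ones), reported as absolute bias $|2p - 1|$ and
  standardized bias $p(1 - p)$, linked by $4p(1-p) = 1 - |2p-1|^2$;
* average sensitivity $S(f)$, the expected number of output-changing
  single-input flips, whose per-network mean locates the dynamical regime
  (ordered below 1, critical near 1, chaotic above).

All NCFs sharing a layer structure share their absolute bias and average
sensitivity, so `canonicalNCF()` (the alternating or/and representative,
e.g. `A | B | C | (D & E)` for structure (3, 2)) fully describes each
stratum; `enumerateLayerStructures(n)` lists the $2^{n-2}$ strata.

## Random generators

All generators draw from R's global RNG; `runEnsemble()` seeds it from its
spec, making every ensemble a pure function of the spec.

* `randomNondegenerateFunction()` rejection-samples uniform truth tables
  until every declared input is essential — a rule such as `x | y` declared
  on three inputs is excluded.
* `randomFunctionWithDepth()` and `randomNCF()` use the standard monomial
  form: the canalized outputs of the $k$ canalizing variables are iid coin
  flips (for an NCF the last two are tied so the final layer has size at
  least 2), runs of equal outputs form the layers, and variables, canalizing
  inputs and polarity are uniform. Under this parameterisation every layer
  structure of a given depth is equally likely. Exact depth $k <$ arity is
  completed by a rejection-sampled non-canalizing, non-degenerate core;
  depth = arity − 1 is rejected as infeasible (a single leftover variable
  always canalizes).
* `randomWiring()` draws distinct regulators per node uniformly and
  resamples until the wiring digraph is strongly connected.

**Self-inputs.** Whether a node may regulate itself is a genuinely open
choice for random ensembles. The package default excludes self-inputs: in
the 12-node, degree-3, depth-0 reference condition the no-self-input
ensembles reproduce the expected basin *and* attractor excesses over the
0.5 baseline simultaneously, while allowing self-inputs noticeably inflates
the attractor side. The flag `allowSelfInputs` reverses the
choice per call.

**Rule classes for ensembles.** The "no canalization" reference condition is
canalizing depth exactly 0 (non-canalizing, non-degenerate rules), not the
uniform non-degenerate class: ensembles are stratified by depth, and the
uniform class mixes many canalizing rules into what should be the
zero-canalization stratum, raising its AUC:BC excess well above the
depth-0 value at degree 3. Both classes are exposed (`ruleClass = "depth", depth = 0` versus
`ruleClass = "random"`).

## Ensemble scale and what the defaults mean

`ensembleSpec()` defaults to the reference study conditions: 10,000
networks of 12 nodes per ensemble, fixed in-degree, strongly connected
wiring, non-degenerate rules. The package's own reproduction analyses (the
acceptance script and the heavier tests) run scaled-down ensembles chosen
once as a desk-scale compromise between Monte-Carlo error and runtime:
1,000 networks for the degree-3 depth-0 and NCF comparisons, and 250
networks for each of the 14 layer-structure-stratified ensembles of degrees
3–5. At 1,000 networks the percent-above-baseline statistics are stable
across seeds; the relative drop $100\,\Delta AUC / (AUC{:}BC - 0.5)$ is
the noisiest summary because it divides one small difference by another.

## Monte-Carlo analysis of large models

For networks beyond the exhaustive limit (default 22 nodes),
`sampleDecomposition()` draws $q$ initial states uniformly with replacement
(default 1000), iterates each trajectory with visited-set cycle detection,
and deduplicates attractors by their canonical (lexicographically smallest)
state. Hits/$q$ is an unbiased estimator of relative basin size; an
attractor of relative size $b$ is discovered with probability
$1 - (1-b)^q$ (`detectionProbability()`), so 1%-basins are found with
probability 99.996% at $q = 1000$ while tiny basins are systematically
missed — a property of the design, not a bug. Basin coherence is estimated
from the sampled states of each basin with every neighbour resolved by full
trajectory iteration (memoised within the network); attractor coherence is
computed *exactly* for every discovered attractor, whatever $q$. A step cap
(default $10^6$) guards against pathological transients; it is a safety
valve, not a parameter of the method.

## Biological models, source nodes and null models

Curated models often contain *source nodes* — self-copy rules
$x_i = x_i$ or zero-input constants — which fragment the state transition
graph into $2^M$ independent subgraphs and artificially inflate attractor
counts. `fixSources()` substitutes a fixed source configuration, drops
inputs that became inessential, and returns the reduced network over the
$N - M$ remaining nodes; coherence there perturbs only non-source
coordinates (denominator $N - M$; perturbing sources would count
by-construction-impossible transitions). Models with $2^M \le 16$ are
analysed under every configuration, larger ones under 16 sampled without
replacement, and statistics are averaged. Rules that reduce to constants
are kept as ordinary arity-0 nodes: they still take one step to settle, so
re-fixing them would change the reduced dynamics.

`nullModels()` preserves the wiring diagram exactly and redraws every rule
of arity at least 1 as a uniform non-degenerate function (arity-0 constants
have no non-degenerate counterpart and are kept).
`pairedStabilityComparison()` then tests whether the biological logic is
more stabilising than its topology alone: Shapiro–Wilk on the paired
coherence differences, a one-sided paired t-test (biological > null), and
an exact sign test on per-attractor $\psi_B - \psi_A$ pairs. These three
tests are deliberately the textbook procedures called through
`stats::shapiro.test`, `stats::t.test` and `stats::binom.test`.

## What the synthetic cohorts do and do not show

`syntheticCohort()` generates strongly connected random models (optionally
with self-copy source nodes wired into the core, and with a
`plantedEffect` that mixes nested canalizing rules into otherwise uniform
non-degenerate logic) so the entire pipeline is testable without any
external download. These cohorts emulate the *mechanisms* — canalization
raising coherence above topology-matched nulls, source-node fragmentation —
but not the size distribution, the in-degree heterogeneity, or the curated
regulatory logic of published models. Passing tests therefore demonstrate
correctness of the estimators and the direction and detectability of
planted effects, not the numeric cohort statistics of any real model
collection; those require the external model files, which
`analyzeModelDirectory()` consumes as a directory of BoolNet-style rule
files.

## Numerical and degenerate-input conventions

* Truth tables and state codes are MSB-first (node 1 is the high bit), so a
  rule's Hamming weight is the popcount of its table and each network state
  has one canonical integer code.
* Attractor identity is the lexicographically smallest cycle state, making
  limit cycles phase-invariant.
* Exhaustive decomposition composes the successor map with itself $N$ times
  (iterated squaring reaches $F^{2^N}$, past any transient), entirely in
  vectorised integer arithmetic; no recursion, no per-state loops.
* `layerStructure()` rejects degenerate and constant rules rather than
  inventing a convention; generators guarantee non-degeneracy upstream.
* Exact ties in the sign test (zero differences) are dropped, the standard
  convention for exact sign tests.

## Limitations

Only synchronous, deterministic Boolean dynamics are modelled;
asynchronous, probabilistic and multi-valued schemes are out of scope, as
are symbolic (SAT/BDD) attractor methods — exhaustive and Monte-Carlo modes
only. Coherence considers single-bit perturbations; multi-bit and
targeted perturbations are not implemented. The binned-AUC estimator is
unreliable when the basin-size support has wide gaps (hence the 0.02
exclusion rule), which at desk scale affects the most biased
layer-structure ensembles first.
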