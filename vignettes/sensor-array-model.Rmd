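---
title: "Modelling indicator-displacement sensor arrays: equilibria, fingerprints and discriminant analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling indicator-displacement sensor arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensarray)
```

## The model

A sensor unit is a solution holding one reporter dye and one or more host
site populations (a calixarene–cyclodextrin coassembly is represented as
two independent site populations), under one environmental condition.
Every host–guest pair forms at most a 1:1 complex characterized by an
association constant $K_a$ (M$^{-1}$); guests are dyes and analytes, and a
missing pair in the affinity table means $K_a = 0$. The equilibrium state
satisfies, for each host $j$ and guest $i$,

$$H_{j,t} = H_{j,f}\Bigl(1 + \sum_i K_{ij} G_{i,f}\Bigr), \qquad
  G_{i,t} = G_{i,f}\Bigl(1 + \sum_j K_{ij} H_{j,f}\Bigr), \qquad
  [H_jG_i] = K_{ij} H_{j,f} G_{i,f}.$$

Fluorescence is assumed linear in concentration (dye kept in the linear
range), so the observable is
$I = \varphi_{\mathrm{free}}[D]_f + \varphi_{\mathrm{bound}}\sum_j[H_jD]$,
and a unit's response to an analyte dose is the ratio $I/I_0$ of intensity
after versus before the addition. For a quench-type dye
($\varphi_{\mathrm{bound}} < \varphi_{\mathrm{free}}$) displacement
recovers fluorescence and $I/I_0 > 1$; for an enhancement-type dye the
displacement signal lies below 1.

Key assumptions, all explicit in the implementation:

* strict 1:1 stoichiometry, no ternary complexes or cooperativity between
  the coassembly's site populations (independent-site model);
* activity coefficients, ionic strength, kinetics, inner-filter and
  spectral-overlap effects are outside the model;
* concentrations are molar throughout; mass-per-volume dosing is converted
  upstream via `ug_per_ml_to_molar()` with a molecular weight.

Direct dye–analyte association, occasionally relevant experimentally, is
available as an optional first-order term
$\varphi_{DA} K_{DA} [D]_f [A]_f$ added to the intensity
(`intensity(..., dye_analyte = TRUE)`, with the dye in the host column of
the affinity table). It perturbs the signal without entering the host–guest
mass balance; it is off by default, and should be kept small relative to
the dye total where used.

## Solver numerics

`solve_equilibrium()` iterates on the free-host vector: guest frees are
eliminated analytically from the guest balances at the current host frees,
hosts are re-estimated from the host balances, and the update is damped
geometrically with exponent 0.5 (equivalently, half-steps in log space),
which keeps all iterates strictly positive and is contractive for 1:1
systems. Once the relative residual falls below $10^{-3}$ a Newton step on
the host balances (with analytic Jacobian, step-halving safeguard) takes
over, so the default tolerance of $10^{-10}$ — and the $10^{-13}$ used in
the oracle comparisons — is reached in a handful of extra iterations even
in tight-binding regimes ($K_a c \sim 10^3$). Failure to converge raises a
condition of class `sensarray_convergence_error` carrying the last
residual. Species dosed at zero are kept in the state with a free
concentration of exactly zero so that array layouts stay rectangular.

Two independent oracles guard the solver in the tests: the
cancellation-safe closed form for a single pair
(`closed_form_pair()`, $x = 2K_aH_tG_t/(b+\sqrt{b^2-4K_a^2H_tG_t})$ with
$b = K_a(H_t+G_t)+1$), and plain bisection on the one-dimensional host
balance for one host with up to six guests. `speciation_residual()` audits
any state against its composition; the denominator floor protecting
zero-total species is $10^{-15}$ M, far below every concentration the
package doses.

## Which way does the signal move?

At the concentration level the mechanism is monotone, and the tests assert
it: raising the host–analyte constant frees more dye, raising the host–dye
constant frees less, with everything else fixed. The intuitive
design rule "a weaker dye binder plus a stronger analyte binder gives a
larger $I/I_0$" must however be read with care at the ratio level: because
$I_0$ itself falls as the host–dye constant rises, the *ratio* $I/I_0$ in
the exact competitive model is typically an increasing function of the
host–dye constant at fixed micromolar totals — the baseline shrinks faster
than the displaced intensity. (In the dye-excess regime the rule's
direction is recovered.) The acceptance suite states both directions and
records the violation count for the dye direction rather than hiding it;
the analyte direction holds everywhere. Designers should therefore reason
about baselines and displaced fractions separately rather than about the
ratio alone.

## Array-construction strategies

The five builders mirror how practitioners actually vary units:

* `build_reporter_pair_array()` — different (host set, dye) pairs; default
  totals 1.0 µM per component.
* `build_dye_replacement_array()` — fixed coassembly, one unit per dye.
* `build_coassembly_ratio_array()` — fixed second macrocycle, first dosed
  at ratio × its total; the dye dosing rule is an explicit choice between
  `"dye-tracks-varied"` (dye equals the varied component, the usual pairing
  of the dye with the calixarene sites) and `"dye-fixed"`, because both
  conventions are in experimental use.
* `build_pair_ratio_array()` — fixed dye total, hosts at ratio × dye; all
  units share one affinity table, so downstream discrimination is
  attributable purely to the curvature of the binding isotherm.
* `build_condition_array()` — one reporter pair replicated across
  condition labels (e.g. pH values) that index different affinity entries.

Units deduplicate on the chemistry key (sorted host totals, dye and total,
condition) with totals compared at $10^{-12}$ relative tolerance;
`enumerate_units()` counts the coassembly-ratio × dye × reporter-ratio
cross product (2 receptors, 2 dyes, 5 and 5 ratios give 10 intermediate
and 50 total units), and `materialize_unit_library()` generates it
concretely. A degenerate all-equal-ratio array is built with a warning
rather than refused, since it is occasionally useful as a control.

## Synthetic data: what it emulates, and what it does not

`sample_affinity_panel()` draws association constants log-uniformly, by
default over $10^4$–$10^9$ M$^{-1}$ — a typical span for calixarene- and
cyclodextrin-based host–guest chemistry; condition-indexed copies are
independent draws. `simulate_responses()` computes noiseless fingerprints
through the full speciation model and then perturbs each replicate
multiplicatively, $x = (I/I_0)(1 + \mathrm{cv}\,z)$ with
$z \sim N(0,1)$, clipped positive — values scattered around the calculated
response, as replicate experiments are. Defaults: 6 replicates per analyte
(the usual experimental design) and cv = 2 %, a plate-reader-like
dispersion; the cv is recorded in every output and should be treated as a
scenario parameter, not a constant of nature. Every generated artifact
carries its seed, and regeneration is byte-identical.

Two scenario constructors reproduce structural challenges of IDA sensing.
`make_ambiguity_scenario()` tunes, by 1-D root finding, the dose of a
low-affinity analyte until its response on the first unit exactly matches
a low dose of a high-affinity analyte — a single unit then cannot beat
chance, while the remaining units separate the pair, which is the
motivation for arrays. `make_mixture_scenario()` builds two-component
blend panels (e.g. 0–100 % in steps) whose endpoints are the pure
components, emulating adulteration studies.

The generator reproduces the thermodynamic and statistical structure of
such experiments, not their chemistry: real protein surfaces bind
multivalently and condition-dependently in ways no log-uniform panel
captures, real noise has plate and batch structure, and real coassemblies
are not strictly independent site populations. Green tests on synthetic
panels therefore validate the machinery and its discrimination principles,
not any particular laboratory system.

## Discriminant analysis conventions

`fit_lda()` is a from-scratch canonical discriminant analysis: between- and
pooled within-class scatter matrices, a ridge of
$10^{-8}\,\mathrm{tr}(S_W)/p$ on $S_W$ (four-unit arrays with six
replicates per class can be near-singular), Cholesky whitening, and a
symmetric eigendecomposition. Directions are scaled to unit within-class
variance and sign-fixed so each factor's largest-magnitude loading is
positive; variance fractions are eigenvalue shares in percent over the
retained $\min(K-1, p)$ factors. Classification is nearest-centroid in the
full score space — Mahalanobis-equivalent under this scaling — with ties
broken by label order, and uses all retained factors even though plots
show the first two. Priors are equal, matching balanced replicate designs.
Scores are not re-standardized afterwards. The test suite checks the fit
against a brute-force eigendecomposition built by an independent route and
against `MASS::lda()` (per-factor score correlations of 1 up to sign).

`jackknife()` refits on every leave-one-out fold and needs at least three
samples per class so each fold keeps two. `confidence_ellipse()` uses the
$\chi^2_2$ quantile: semi-axes $\sqrt{\lambda_i\,q_{0.95}}$ from the score
covariance eigenstructure, degenerate (collinear) clouds flagged.
`overlap_check()` implements a geometric intersection test — centre
containment or boundary proximity, minimized over a 720-point grid with
local refinement — and counts tangency within $10^{-9}$ as overlap;
whether visual cluster separation in published score plots corresponds to
this exact test is unknowable, so the package reports the geometric answer
as such.

## Subset selection and array combination

No standard procedure exists for choosing which analytes a
partially-confused array "discriminates". `max_discriminable_subset()`
makes the package's choice explicit and auditable: greedily remove the
class with the most leave-one-out misclassification involvements (as true
or predicted class of an error; ties by label order) until the jackknifed
accuracy of the remainder is 100 %, and keep the elimination trace. On
small instances an exhaustive search in the tests bounds the greedy
optimality gap. `screen_combinations()` evaluates every unordered pair of
arrays by concatenating response columns over a shared sample panel and
flags pairs whose subset strictly exceeds both constituents'.

Concatenating features cannot destroy information: the combined responses
always separate the stronger constituent's retained subset at 100 %
resubstitution, and the tests assert exactly that. The *leave-one-out*
subset size, being an estimate, can occasionally dip when noisy extra
columns enter the fit (about 1 in 20 simulated scenarios at cv = 2 %);
the test suite reports such dips instead of asserting them away.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run, as the package's chosen
study sizes: 1,000 random solver instances against the oracles; 500
random panels for each monotonicity direction; an 11-analyte × 6-replicate
classification (66 score points); a ten-array inventory (45 pairwise
combinations); a $10^4$-point Monte-Carlo ellipse coverage; and a
12-seed × 4-level noise sweep (cv 0.5, 2, 5, 10 %) with common replicate
draws across levels so the comparison is paired. All randomness flows from
a single integer seed; `scripts/acceptance.R --seed N --out file.json`
reruns everything from scratch.

## Known limitations

Beyond the scope notes above: the solver handles only bipartite host–guest
binding (the optional dye–analyte term is perturbative); no
quadratic/regularized-nonlinear classifiers are provided, by design; the
ellipse overlap test is numerical, exact only to the stated tolerance; and
the greedy subset rule, while bounded by the exhaustive oracle at test
scale, is not guaranteed optimal on large panels.
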