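---
title: "Uniform design plus SVR: how udsvr optimizes multi-factor experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uniform design plus SVR: how udsvr optimizes multi-factor experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Fermentation media and process conditions are high-dimensional: a
typical optimization of a microbial product (the package's worked
example is pyrroloquinoline quinone, PQQ, produced by *Acinetobacter
calcoaceticus*) involves five to ten factors — carbon and nitrogen
sources in g/L, temperature, inoculum volume, pH — each tested at a
handful of discrete levels. Full factorials are astronomically large
(the example's first round spans 312,500 level combinations), while
one-factor-at-a-time misses interactions. `udsvr` implements a
sequential strategy that couples two classical ideas:

1. a **mixed-level uniform design** spreads a small number of runs
   (e.g. 40) as evenly as possible over the level lattice, so one
   round of experiments carries information about the whole space;
2. an **epsilon support-vector-regression surrogate**, tuned by
   cross-validated grid search, interpolates the measured response
   over every untested combination.

Between the two sit a **backward feature-screening** step that prunes
factors whose removal improves cross-validated error, and a
**frequency-statistical optimization** that turns the surrogate's
full-grid predictions into concrete next-round decisions: fix a
factor, keep a range, or extrapolate beyond a boundary. A complete
round is one call to `run_round()`; the human performs the wet-lab
step between rounds.

## Uniform designs and the centered L2-discrepancy

A U-type design assigns each factor's levels to runs so every level
appears (near-)equally often. Quality is scored by the squared
centered L2-discrepancy (CD2^2): level index l of a q-level column is
mapped to u = (l - 0.5)/q in (0, 1) and the closed-form double sum is
evaluated over runs. CD2^2 is invariant under row permutation and
per-column reflection, which the suite checks against a brute-force
triple-loop oracle.

Construction (`generate_uniform_design()`) follows the standard
good-lattice-point recipe: a base design on n levels built from
multipliers coprime with n, collapsed to each factor's q levels
(pseudo-level collapsing, occupancy within one run of n/q and exact
when q divides n), then improved by a seeded threshold-accepting
search over within-column swaps. The search keeps the best candidate
seen, so the result is never worse than the initial lattice design;
the default budget is 10,000 iterations and the whole construction is
deterministic in (grid, n, budget, seed). The package does not try to
reproduce any particular proprietary design table bit-for-bit —
published run tables are importable data, not construction targets.

## The SVR surrogate

`svr_grid_search()` scans kernels (linear, polynomial, RBF, sigmoid)
and powers of two for the penalty C in [2^-5, 2^15] and the kernel
coefficient gamma in [2^-15, 2^3], exponent step 2 by default, and
scores each cell by 5-fold cross-validated MSE (out-of-fold
predictions only). Choices the underlying literature leaves open were
fixed as follows:

* **Scaling.** Each input column and the response are standardized on
  the training folds only; predictions are back-transformed. Kernels
  over raw g/L-vs-degrees scales would be meaningless otherwise, and
  fold-wise scaling keeps the CV honest. The scaler state is stored
  in the fit for audit.
* **Tube width and degree.** epsilon = 0.1 on the standardized
  response; polynomial degree 3. Both configurable.
* **Folds.** Seeded shuffle then contiguous k-way split, sizes within
  one of each other. The fold seed is recorded in every report; with
  n = 40 the chosen partition measurably moves the MSE, which is why
  published cross-validated error values can only be matched
  qualitatively, never to the printed decimal.
* **Ties.** Lowest CV MSE, then smaller C, then smaller gamma, then
  kernel order linear < polynomial < rbf < sigmoid — prefer the
  flatter model, deterministically. For the linear kernel gamma is
  inert, so only the smallest grid gamma is evaluated.

## Backward nonlinear feature screening

`backward_screen()` is a greedy wrapper: compute the baseline CV MSE
of the current factor set, then the CV MSE with each single factor
removed; drop the factor whose removal helps most, or stop when none
helps. Baselines therefore decrease strictly, and the trace prints as
the familiar screening table (rows = rounds, columns = factors).
Hyperparameters are re-optimized by a full grid search for every
candidate subset — the conservative reading of the procedure, making
every comparison a best-vs-best comparison; a `reoptimize = FALSE`
flag freezes the initial (kernel, C, gamma) instead for speed. Ties
remove the earliest column. A `min_features` floor (default 1)
guarantees a non-empty model.

## Frequency-statistical optimization

`predict_grid()` evaluates the refit surrogate over every level
combination of the retained factors, in chunks so memory stays
bounded for millions of combinations. `frequency_statistics()` counts,
per factor, how often each level occurs among combinations predicted
above a threshold (strict inequality). The threshold is in response
units and study-specific — 50 mg/L in the PQQ example; when none is
supplied the 85th percentile of the predictions is used, which keeps
the selected set a comparable top slice regardless of scale.

`recommend()` turns the counts into a next-round plan:

* factors dropped by screening are fixed at the **lower median** of
  their tested levels (for even level counts the lower of the two
  middle values — an explicit convention, since "the median level" is
  ambiguous there);
* a factor whose modal level is interior and **dominant** — modal
  count at least 1.25 times the runner-up — is fixed at that level.
  The 1.25 quantification is the package's own: it reproduces the
  behaviour of keeping both top levels when two adjacent levels are
  nearly tied, while a conspicuous single peak freezes the factor;
* otherwise the factor stays active next round with at most 3 levels:
  the mode, the runner-up when the mode is not dominant, the level
  carried by the single best-predicted combination (kept always, so a
  lone optimum is never voted away by frequencies), and — when the
  mode sits on a boundary of the tested range — one inter-level step
  beyond that boundary, flagged `extend_up`/`extend_down`.

Convergence is declared when no factor stays active. All decisions are
pure functions of the report, hence idempotent and reproducible.

## The synthetic landscape generator

Real treatment tables are expensive, so `landscape_spec()` +
`make_landscape()` + `simulate_round()` provide an in-silico stand-in
with the statistical structure the method assumes: a concave
quadratic surface with optional pairwise interactions on physical
units, inert factors contributing exactly zero, and additive Gaussian
noise (simulated yields are truncated at zero — a fermentation cannot
produce a negative titer). Concavity is enforced at construction (the
Hessian must be negative definite), so the stated optimum really is
the global maximum, and optima may deliberately lie outside the
tested range to exercise the extrapolation rule.

`default_pqq_landscape()` encodes the conditions the package is
tested under, mirroring the case study's situation: eight candidate
factors on the first-round grid, six active (yeast powder, ammonium
sulfate, glutamic acid, tyrosine, temperature, pH) and two inert
(calcium chloride, inoculum volume); tyrosine and temperature optimal
above their tested ranges, yeast powder below, pH interior at 6.5;
noise 3 mg/L. Effect sizes were calibrated once, while designing the
generator, against the generator's own stated requirement — that
backward screening on a 40-run design recover the active/inert split
in at least 80% of seeds — because a surface too rough for 40 runs to
model leaves cross-validation noise masking the inert dimensions and
tests nothing. That calibration is why the default surface is
additive: pilot simulations during generator design showed that even
mild pairwise interactions (not identifiable from 40 runs in 8
dimensions) inflate surrogate bias enough to hide the inert factors
behind the screening baseline's winner's-curse optimism, dropping
recovery from ~90% to ~50% of seeds. The frozen curvatures give each
active factor an 8-16 mg/L swing over its range and grid responses
spanning roughly 10-60 mg/L, comparable to the study's observed
10-66 mg/L span. Interacting surfaces remain first-class citizens of
the landscape family and are exercised by their own tests.

What the generator does **not** emulate: replicate-level assay error,
non-Gaussian or heteroscedastic noise, non-quadratic response shapes
(plateaus, thresholds), and factor effects that change sign across
the range. Passing the recovery and boundary-detection properties
therefore shows the pipeline is correct and well-calibrated for
smooth unimodal surfaces, not that screening will succeed on every
real fermentation dataset.

## Numerical and reproducibility choices

* 1-based level indices internally, displayed as L1, L2, ... in
  reports and files.
* Physical values, not indices, are what the surrogate consumes;
  indices exist for design bookkeeping, and duplicate-run checks
  compare index tuples.
* The CD2^2 swap search uses O(n) incremental updates with an exact
  recomputation of the touched pair-matrix cells; the stored
  discrepancy of a returned design is always a fresh full evaluation,
  reproducible from the design alone to 1e-12.
* Every stochastic step (design search, simulated noise, CV shuffle)
  takes an explicit integer seed, and every seed is serialized into
  the JSON round report; reports contain nothing time-dependent, so
  identical inputs give byte-identical files.
* Simulation-based tests and the acceptance script use an RBF-only
  grid (exponent step 2 for screening studies, step 4 for quick
  fits). The RBF kernel is what grid search selects on these
  landscapes anyway, and the linear kernel at C near 2^15 can hit
  libsvm's iteration cap on weakly structured data; pinning the
  harness to RBF keeps the simulation studies' cost predictable
  without changing their outcome. Simulation sizes (20-seed screening
  study, 10-seed acceptance rates, 8-seed two-round campaigns) are
  the package's chosen balance between statistical resolution and
  runtime.

## Known limitations

* The screening outcome depends on the CV fold partition at small n;
  different fold seeds can defer the removal of a weakly inert
  factor by one round. This is a property of the method, not the
  implementation — the published screening tables it mirrors carry
  the same caveat.
* One reference inconsistency worth documenting: the case study's
  printed record anchors the screened-out inoculum volume at "its
  median" 0.4%, but the tested levels {0.1, 0.3, 0.5, 0.7, 0.9} have
  median 0.5% (which the same record's conclusion quotes). `udsvr`
  uses the true median. Similarly, the printed count of full-grid
  combinations for the six retained first-round factors (125,000)
  does not equal the product of the printed level counts
  (5·5·5·5·4·5 = 12,500); `enumeration_size()` returns the exact
  product.
* Published model-dependent quantities (cross-validated MSE values,
  full-grid prediction means, per-level frequency counts) are
  fold-partition- and grid-step-dependent and are treated as
  qualitative references throughout.
* The optimizer is greedy across rounds: it never revisits a fixed
  factor. That matches the sequential experimental practice it
  automates, but means a wrongly fixed factor costs a full round to
  recover.
* A quantitative consequence of the stop rule worth knowing: because
  each screening round's baseline is the *minimum* of the previous
  round's cross-validated estimates, it is optimistically biased, and
  at 40 runs with 3 mg/L noise the package's own 20-seed simulation
  study finds the second of two inert factors is left in the model in
  roughly a quarter of seeds (the first is essentially always found,
  and active factors are essentially never lost). Screening errs on
  the side of keeping factors — the cheap direction experimentally,
  since a kept inert factor is simply fixed at its median next round.
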