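---
title: "Tri-linear PLS regression and nested resampling: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tri-linear PLS regression and nested resampling: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nplsnest)
```

## The problem

In vivo studies of tissue remodeling or inflammation are usually fully
crossed by condition and time, with every time point a terminal endpoint:
each animal contributes one condition x time cell, and all of its
measurements — across variables and across the independent and dependent
blocks — move together. Partial least squares regression (PLSR) of such
data is conventionally run on *global averages* of the replicates, which
discards the animal-to-animal variance entirely. When that variance is
large (as it typically is in vivo, several-fold larger than for cultured
cells), latent variables (LVs) that look statistically meaningful in the
global-average model may merely encode the particular set of animals used.

`nplsnest` implements the tri-linear PLSR decomposition together with three
complementary model-vetting tools that all refit the model many times:

* **randomization null models** — shuffle the data within each condition,
  refit, and flag weights of the real model that exceed one null SD;
* **jackknife resampling** — omit one whole animal per condition x time
  cell, re-average, refit (a weak test: a relationship that disappears is
  severely underpowered);
* **subsample resampling** — keep exactly one animal per cell ("n-of-one"
  data), refit (a conservative test: an LV that survives reflects a large,
  reproducible effect).

The package's central discipline is that resampling **never breaks
nesting**: a replicate identifier groups every observation one animal
contributed to a cell, and draws remove or retain those observations as a
group, optionally coupled across the two blocks by an animal pairing
identifier.

## The decomposition

Data enter as a pair of dense arrays, `X` (conditions x times x variables,
the independent block) and `Y` (likewise, the dependent block), sharing
only the condition mode. Each LV is extracted from the mode-1 unfolded
residuals (columns enumerate time x variable pairs, variable index
fastest) by alternating projections

\[
  w = X^\top u,\quad t = X w,\quad q = Y^\top t,\quad u = Y q,
\]

with \(w\) and \(q\) rescaled to unit norm after each back-projection,
starting from \(u\) set to the first principal component of the `Y`
residual. Iteration stops when the change in \(\lVert t\rVert\) falls to
`tol` (default `1e-10`), with a hard `max_iterations` guard (default
10000) because the alternation alone carries no bound. After convergence
the inner coefficient \(b = (t^\top t)^{-1} t^\top u\) links the blocks,
and both are deflated: `X` by \(t\,w^\top\), `Y` by the predicted
contribution \(b\,t\,q^\top\).

Three choices here were genuinely open and are worth recording:

* **Prediction uses the per-LV inner coefficients** (a diagonal inner
  relation, \(\hat Y = \sum_n b_n t_n q_n^\top\)). The full least-squares
  matrix \(B = (T^\top T)^{-1} T^\top U\) is also computed and reported,
  but its off-diagonal entries are inconsistent with per-LV deflation: only
  the diagonal form makes "predict the training data with all LVs" equal
  "Y minus the final residual" exactly, which is the identity the test
  suite pins down. This is also standard bilinear PLS2 practice.
* **Weight normalization** to unit length is not part of the printed
  algorithm lineage but is required for cross-model comparability of
  weights in ensembles, and to keep the inner regression conditioned.
* **Factored weights.** The algorithm produces combined weights over
  (time, variable) pairs; the separate time and variable weights that one
  interprets are obtained by a rank-1 factorization (leading singular
  vectors of the `j x k` reshape) *after* convergence, with the
  factorization residual reported rather than hidden. A true tri-linear
  inner loop would refit the factors each iteration; the difference is
  surfaced, not assumed away.

Sign indeterminacy — negating one LV's scores and weights together changes
nothing — is handled at two levels when ensembles are summarized: each
member LV is flipped toward the reference model when the inner product of
its concatenated \((w, q)\) with the reference's is negative (the
operational form of "fold the symmetric bimodal distribution to its
dominant mode"), and the internal (time, variable) factorization split,
which carries its own sign ambiguity, is flipped *as a pair* toward the
reference. The second flip matters: a fixed per-model convention such as
"largest entry positive" silently folds the distribution of
noise-dominated weights and makes fragile LVs look stable. Both flips
leave every member's predictions bit-unchanged, which is asserted in the
tests.

## Standardization

Two study archetypes are built in. For differential-change designs
(`spec_baseline_mode3()`), the baseline-time entry is subtracted per
condition and variable — so all conditions start at zero and baseline
differences are not modeled — and each measured variable is then scaled by
its slab SD. For already-commensurate designs (`spec_modes23()`), scaling
runs across modes 3 then 2 sequentially, with both factor sets persisted.
Order matters and is fixed: subtraction first, then scaling (it is the
differential changes that get scaled); the baseline-time-equals-zero test
asserts the order.

The scaling "SD" is the uncentered root-mean-square when centering is off
(the differential-change archetype is uncentered by design) and the
mean-centered SD when centering is on. Whether the original MATLAB
pipelines centered before scaling for the modes-2&3 studies is not
documented; both estimators are supported and the uncentered default is
recorded here.

Standardization returns a state object holding every factor and baseline
actually applied. Held-out conditions are standardized with the frozen
training factors; their baseline is their *own* baseline-time entry
(baseline subtraction is within-condition by definition, so this leaks
nothing). Zero-variance slabs error under the strict default but receive a
factor of 1 (with a warning) under the lenient mode used inside resampling
loops, where an n-of-one draw can legitimately make a slab constant —
a resampling run must not abort because one draw is degenerate.

## Cross-validation and component selection

Model order is chosen by leave-one-condition-out cross-validation: for
each held-out condition the standardization state and the model are
recomputed from the remaining conditions only (the leakage-free default; a
standardize-once switch exists for reproducing pipelines that did
otherwise), the held-out slab is predicted with 1..`max_lvs` LVs, and the
pooled RMSE curve is minimized, ties going to fewer LVs. RMSE is reported
on the standardized (dimensionless) scale, matching how such curves are
used for selection; raw-scale RMSE is exported alongside. When a training
fold's variance is numerically exhausted before `max_lvs` (noiseless
low-rank data), the fit truncates and predictions plateau — an LV that
explains nothing changes nothing — rather than failing.

## Null models and robustness classification

The randomization null shuffles all (time x variable) entries within each
condition slab of each block independently, on the raw averaged tensors,
then re-standardizes and refits with the global LV count, 500 times by
default. A weight is *significant* when it lies strictly more than one
null SD from the null mean. A whole-row-permuting variant is available
behind a flag for the stricter reading of "shuffle within mode 1".

Resampling ensembles refit the model on each draw with the LV count fixed
to the global optimum (members must be comparable to the global model),
sign-align, and summarize each weight coordinate as mean ± SD. A
coordinate is *robust* when that interval strictly excludes zero — an
error bar touching zero is fragile (conservative boundary rule). When a
significance mask is supplied, the *retained fraction* — among
null-significant coordinates, the share whose resampled error bars exclude
zero — composes the two criteria; because the literature is not explicit
about the denominator, the overall robust fraction is reported alongside.

Jackknife draws are random (one omitted animal per cell per iteration)
rather than exhaustive, since the exhaustive cross-product over cells is
combinatorial; draws are independent across cells and, in unpaired mode,
across blocks. Paired mode couples the blocks only — never cells across
time, because terminal endpoints make animals time-specific. Member
failures are logged and excluded; more than 20% failures aborts the
ensemble, which signals a degenerate scheme or dataset rather than
something to average over.

## The synthetic world

`planted_model()` states the world the tests run in: cell means are sums
of rank-1 LV contributions with orthonormal per-mode loadings and
decreasing strengths; each replicate is the cell mean plus an animal-level
normal offset drawn once per replicate per cell and *shared across all of
that animal's variables*, plus i.i.d. measurement noise. The shared offset
is what makes nesting statistically real: leaving one animal out moves all
its variables coherently, which is precisely the structure nested
resampling exists to respect. Noise defaults encode the field's variance
regimes — replicate coefficients of variation near 11% for cultured-cell
data, 3-5x higher in vivo — as SDs of roughly 0.1 vs 0.3-0.5 on the unit
signal scale.

One emergent property of this world is worth knowing when reading test
output: because the animal offset is constant across variables, the
"noise LV" that high replicate variance induces has a *coherent variable
direction* (the all-ones vector) even though its time and condition
structure is arbitrary per draw. Degradation of trailing LVs under noise
is therefore assessed on the combined (time x variable) weights, where the
instability actually lives — the factored variable axis alone can remain
deceptively stable. Real data whose replicate deviations are not a shared
offset will not show this particular coherence.

What a green test does establish: oracle-level correctness of the
decomposition (eigendecomposition and bilinear-PLS equivalences),
parameter recovery at zero noise, exact degeneracy identities, null
calibration near the nominal 68% one-SD coverage on structureless data,
and the qualitative robustness contrast between low- and high-variance
regimes. What it does not establish: agreement with any particular
published study's numbers (the original source data are not
redistributable here), behavior under heavy-tailed or correlated
measurement noise, or designs that are not fully crossed.

Dimensions for the null-calibration test are chosen with `j*k` around 100:
sign alignment biases the null mean toward the reference by an
`O(1/sqrt(jk))` term, and the test's dimensionality keeps that bias well
inside the binomial tolerance rather than pretending it does not exist.

## Numerical details worth knowing

* Matricization order (variable fastest) is fixed package-wide; every
  weight reshape uses it. A silent order mismatch is the classic multiway
  bug, and the unfolding has its own enumeration-oracle test.
* Convergence is measured as the absolute change of \(\lVert t\rVert\);
  the `t` vector is randomly initialized from the model seed, but the
  iteration path after the first pass is deterministic given the data, so
  fits are reproducible and seed-insensitive at convergence.
* All stochastic steps (simulation, shuffles, draws, member fits) derive
  per-use seeds from one master seed with a fixed integer recurrence kept
  below 2^31; reruns are bit-identical.
* Baseline animals for differential-change designs may be shared or
  distinct across conditions; the data model allows either (reuse a
  replicate id per condition or not) and resampling treats cells
  independently either way.

## Limitations

Only 3-way arrays; no Tucker/PARAFAC, no nonlinear PLS variants, no
bootstrap-with-replacement or BCa intervals, no k-fold CV, and no
built-in ANOVA comparison of paired vs unpaired weight distributions
(ensemble tables are exported for external tools). Summary-table
simulation assumes normality and independence across variables within an
animal, because published mean/SD tables carry no covariance information.
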