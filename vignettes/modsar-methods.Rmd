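---
title: "Methods: modular network QSAR with optimal piecewise linear regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modular network QSAR with optimal piecewise linear regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its model, its numerical
choices, and the limits of what its tests demonstrate.

## The two-level model

`modsar()` assumes that a structure-activity landscape is locally much
simpler than it is globally: within a group of structurally related
molecules, activity is well approximated by a small number of linear
equations in the descriptors, with the group boundaries and the equation
boundaries both learned from data.

**Level 1 - chemical space network.** Molecules are 1024-bit circular
fingerprints (Morgan-style neighbourhood hashing, radius 2 - the ECFP4
configuration; see below). Similarity is the Tanimoto coefficient on those
bitsets, and the network links pairs with `Tc >= t*`. The threshold is not a
free parameter: scanning t over {0, 0.01, ..., 0.99} traces the average
clustering coefficient (ACC), which starts at 1 on the complete graph,
declines as between-scaffold edges thin out, and recovers to a peak when the
surviving edges concentrate inside coherent groups. `optimal_threshold()`
selects that first post-decline peak. Louvain modularity optimisation on the
resulting (unweighted) graph yields the modules; molecules with no
above-threshold neighbour become singletons, kept in the model with their
own activity as a constant equation rather than discarded as outliers.

**Level 2 - optimal piecewise linear regression (OPLRAreg).** Within a
module, one descriptor is selected as the partition feature, its axis is cut
by ordered breakpoints into R regions, and each region r gets a linear
equation fitted by least absolute deviations with an L1 coefficient
penalty:

$$\min \sum_s \left| y_s - (w_{r(s)} \cdot x_s + b_{r(s)}) \right|
      \;+\; \lambda \sum_{r,j} |w_{rj}|$$

The canonical statement of this problem is a mixed-integer program: binary
variables assign samples to regions, continuous breakpoints are ordered, and
big-M constraints tie assignments to the partition feature's value. This
package solves that program *exactly* by exploiting its structure instead of
calling a branch-and-bound solver: because assignments must respect the
ordering of the partition feature, every feasible assignment is a contiguous
segmentation of the samples sorted by that feature (ties at a breakpoint may
split). The optimum over segmentations is found by dynamic programming over
split positions, and each segment's LAD + L1 subproblem is itself a linear
program, solved exactly by the Barrodale-Roberts simplex
(`quantreg::rq.fit.br`) with the penalty encoded as zero-response
pseudo-observations `lambda * e_j` that do not touch the intercept. The
composition is equivalent to the mixed-integer optimum - it is the same
feasible set and the same objective - with deterministic results and no
solver tolerance beyond LP exactness.

Candidate partition features are evaluated by running the segmentation for
each feature and keeping the best objective; `oplra_control(top_k = )` can
shortlist features by a cheap univariate split-improvement score when
modules are large. Region count grows from R = 1 and an additional region is
accepted while the training MAE improves by more than a relative tolerance
(`epsilon`, default 0.03), up to `r_max` (default 6).

**Prediction.** A query molecule's similarity to every training molecule
decides its module: (i) the module holding the strict maximum number of
above-threshold neighbours; (ii) on a count tie, the tied module with the
largest average similarity over its above-threshold neighbours (then the
smaller module id - a deterministic tie-break); (iii) with no neighbour
above `t*`, the module of the single most similar molecule, and the
prediction is flagged `in_ad = FALSE`. The wording of cases (i) and (ii)
("many connections" vs "connected to multiple modules") overlaps; reading
(ii) strictly as the tie-break of (i) is the one disambiguation that makes
the three cases exhaustive and mutually exclusive, and is what
`assign_module()` implements. Singleton modules return their stored
activity - a deliberate feature: a close analogue of a lone reference
compound should be predicted at that compound's measured potency.

## Tunable parameters

| parameter | default | units / scale | rationale |
|---|---|---|---|
| fingerprint radius, bits | 2, 1024 | - | ECFP4 convention for chemical space networks |
| scan grid | 0 to 0.99 step 0.01 | Tc | 100 networks; finest grid that is still instant |
| `lambda` | 0.005 | pIC50 per unit of scaled descriptor | the reference sensitivity set is {0.005, 0.05, 0.10}; raise it for small modules (see limitations) |
| `min_region_size` | 5 samples | - | a region needs a handful of points for its equation to mean anything |
| `small_module` | 10 samples | - | below this, no breakpoint search: a single-region model |
| `epsilon` | 0.03 | relative MAE | region growth stops when the gain falls under 3% |
| `r_max` | 6 | regions | reference outputs show up to 5 regions |
| `delta` | 1e-4 | scaled descriptor | minimum breakpoint separation |
| `corr_cutoff` | 0.90 | abs Pearson r | descriptor pair filter |
| Louvain `seed` | 20191018 | - | fixes the node visiting order |

Descriptors are min-max scaled to [0, 1] on the training set; test-time
values outside the training range are clipped to [0, 1] so region rules stay
defined. pIC50 is -log10 of molar IC50; nanomolar inputs are converted by
1e-9 first. Replicate activities with a sample standard deviation above 1
log unit are treated as irreconcilable and dropped; concordant replicates
collapse to their median.

## Numerical choices and degenerate inputs

- **Peak detection.** The ACC curve is smoothed with a centred moving
  average of window 3 (partial windows at the ends); the selected index is
  the first i with `s[i-1] < s[i] >= s[i+1]` whose preceding running minimum
  is strictly below both the peak and the curve's start. The `>=` on the
  right shoulder assigns a plateau to its smallest threshold. If no peak
  exists (e.g. monotone decline), the ACC-maximising grid point in (0, 0.5]
  is used, falling back to 0.30, with a warning.
- **Edges are inclusive** (`Tc >= t`), so identical fingerprints remain
  linked even at t = 1, and ACC counts isolated and degree-1 nodes as 0,
  which makes ACC(0) = 1 exact and penalises over-thresholding.
- **LAD degeneracy.** When `lambda = 0` and a segment has fewer samples than
  coefficients the LP basis is singular; a penalty floor of 1e-9 keeps the
  solve stable, and the reported objective is recomputed from the returned
  coefficients with the true lambda. Coefficients below 1e-8 in magnitude
  are stored as exact zeros.
- **Breakpoints** are placed midway between the boundary samples; prediction
  uses half-open intervals (a value exactly at a breakpoint belongs to the
  upper region). Displayed rules round to 2 decimals, prediction never
  rounds.
- **Single samples** yield constant models; modules below `small_module`
  skip the breakpoint search; `fit_fixed(R = 1)` does not apply the
  per-region size floor since there is no breakpoint to support.
- **Serialisation** writes every numeric at 17 significant digits, so a
  reloaded model predicts bit-identically.

## The synthetic benchmark: what it does and does not emulate

`generate_benchmark()` plants M modules of molecules sharing a module core
of b = 100 set bits (of 1024). Each molecule keeps a random b - f subset of
its core and replaces the rest from a disjoint pool, and all cores share g
common bits. f and g are solved analytically from the target intra- and
inter-module similarities (defaults 0.6 / 0.1): the expected intersection of
two same-module molecules is (b-f)^2 / b and of two cross-module molecules
g((b-f)/b)^2, and Tc = I / (2b - I) when all molecules carry exactly b bits.
This yields an actual similarity gap (measured min-intra > max-inter in
nearly every draw) into which the ACC peak falls.

Activities are piecewise-linear in one designated descriptor per module
(slopes of magnitude 2-4 with alternating signs, breakpoints at equal
spacing, a discontinuity of 1-2 log units at each breakpoint - region
equations in this model family are independent lines, so discontinuous
pieces are the faithful shape) plus Gaussian noise (default sd 0.1).
Descriptors are independent uniforms, deliberately unrelated to the
fingerprints so module recovery and regression recovery are separable
claims.

What this does **not** emulate about real QSAR data: correlated descriptor
blocks, skewed descriptor and activity distributions, activity cliffs inside
a module, fingerprint-descriptor dependence, and assay noise that varies
with potency. Passing tests on this benchmark therefore demonstrate the
*mechanics* - threshold selection, module recovery, exact optimisation,
assignment rules - not predictive performance on real chemistry.

Default test scales are 3 x 20 molecules (60) for structural checks,
3 x 60 for noisy breakpoint recovery, and 4 x 50 (200) for the full
10 x 10 validation protocol; these sizes keep the entire suite to a few
minutes while leaving every property statistically meaningful.

## Design choices made where the design was open

- Case (i)/(ii) disambiguation at prediction, as above.
- Modularity is computed on the unweighted thresholded graph: once the
  threshold asserts "these pairs are significantly similar", the edge is a
  statement of membership, not of degree.
- The correlation filter drops, from each pair above the cutoff, the column
  with the larger mean absolute correlation to everything else, and the
  near-zero-variance rule uses frequency ratio 19 with a 10% distinct-value
  cut - the defaults of the preprocessing tooling this workflow
  traditionally uses.
- The replicate filter uses the sample (n - 1) standard deviation.
- The activity-cliff score is the similarity-weighted mean absolute activity
  difference over network neighbours. The high/intermediate/low cutoffs
  default to tertiles of the defined scores, with fixed cutoffs available;
  the score function is pluggable (`score_fn`) because discontinuity can
  reasonably be measured in several ways (e.g. a max-pairwise SALI-style
  score).
- The model file is a single versioned JSON document rather than an archive
  of partial files: one artefact, human-inspectable, exact round trip.
  GraphML and CSV exports remain available separately.

## Known limitations

- **Interpolation at small module sizes.** A region with barely more
  samples than descriptors lets the LAD equations interpolate (training MAE
  0 even under noise), which makes the *number* of regions unidentifiable -
  the relative-improvement rule will grow R to its cap - and inflates
  external error. Breakpoint *placement* at the planted region count remains
  well posed (the recovery tests run at 60 samples per module for exactly
  this reason). With modules of tens of samples and many descriptors, raise
  `lambda` well above 0.005, lower `r_max`, or shortlist features with
  `top_k`.
- **Hull clipping.** Test-time descriptor values outside the training range
  are clipped, so predictions are exact only inside the training hull; the
  most extreme external molecules carry a small boundary error even on
  noiseless data.
- **Threshold granularity.** `t*` is resolved to the scan grid (0.01); data
  whose similarity gap is narrower than the grid step needs a finer grid.
- The fingerprinting path requires ChemmineR/ChemmineOB (OpenBabel); the
  rest of the package operates on any precomputed bitsets and descriptor
  tables.
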