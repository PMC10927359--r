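---
title: "Time-resolved kinase regression and network assembly: methods and design"
author: "treking package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved kinase regression and network assembly: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treking)
```

# The problem

Kinase inhibitors are polypharmacological: each compound partially inhibits
many kinases at once. A screen that treats an endothelial monolayer with a
panel of inhibitors and records barrier integrity in real time (an
impedance-derived "cell index") therefore does not directly report which
kinase does what. Kinase regression (KiR) deconvolves such screens by
exploiting the overlap structure: the phenotype of inhibitor $i$ is modeled
as a linear combination of the residual activities $a_{ik}$ of the kinases
it touches, and kinases with nonzero regression coefficients are the ones
informative for the phenotype.

This package implements the time-resolved extension (tKiR) and its
downstream network assembly. Barrier kinetics are reduced to per-window
areas under the curve (AUC), a separate elastic-net regression is fitted in
every sliding window, kinase temporal-functionality profiles are clustered
on a self-organizing map (SOM), and per-cluster phosphosignaling networks
are reconstructed as unions of shortest paths over a kinase-substrate
background graph.

# Kinetics preprocessing

**Baseline normalization.** The cell index of every well is anchored to 0 at
the last sampled timepoint strictly before thrombin addition. Two
conventions yield that anchor: subtracting the reference value
(`mode = "delta"`) or dividing by it and subtracting one
(`mode = "ratio_minus_one"`). The package defaults to `delta` because it
preserves the cell-index scale, which keeps AUC differences interpretable in
index units; the ratio convention of impedance instruments is selectable.
The upstream instrument convention for the published screens is not
re-asserted here — both forms are supported.

**Sliding windows.** Windows are 5 min wide. Starts advance in 1-min steps
for the first 2 h after inhibitor addition and 5-min steps for the remaining
4 h, producing 164 windows over a 360-min course, with midpoints 2.5 to
357.5 min. Spans not divisible by the step truncate the final start
downward. Windows are closed intervals; AUC is the exact trapezoidal
integral of the piecewise-linear interpolant, with boundary values
interpolated linearly when a window edge falls between samples.

**The 0/100 transform.** In each window, every inhibitor's AUC is reduced by
the vehicle-control (DMSO) AUC; the most negative difference is mapped to 0
and the control to 100. When no difference is negative the affine map is
undefined and the column falls back to `100 + delta`, preserving the control
anchor, with a warning. The transform is invariant to constant shifts of a
window's AUCs.

# Per-window elastic net

For window response $y$ (normalized AUC per inhibitor, control excluded)
and design matrix $X$ (residual activity rescaled to fraction activity in
$[0,1]$, columns not standardized so slope signs stay interpretable), the
fit minimizes

$$\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i^\top\beta)^2 +
\lambda\left(\alpha\|\beta\|_1 + \frac{1-\alpha}{2}\|\beta\|_2^2\right)$$

with an unpenalized intercept. Tunable parameters:

* `alpha` (default 0.9): near-lasso mixing keeps per-window kinase sets
  sparse while tolerating correlated panel columns.
* `lambda`: selected at the minimum leave-one-out CV error over a 50-point
  log grid unless fixed. Leave-one-out is preferred because the screen has
  only ~28 observations per window; fold order is deterministic
  (`foldid = 1:n`), so fits are exactly reproducible.
* `tol` (default 1e-8): coefficients beyond this magnitude count as
  selected.

A positive coefficient means inhibiting the kinase lowers the barrier
response, i.e. the kinase is barrier-strengthening (+1); negative means
barrier-weakening (−1); zero means not predicted. A kinase called with both
signs in different windows is a *switch kinase*.

## The minimum-resolvable-effect gate

Two artifacts of the per-window pipeline inflate the raw nonzero-coefficient
rule. First, in windows where inhibitors genuinely differ from control, the
penalized fit shrinks the leading coefficients and correlated panel columns
absorb the residue, yielding many small nonzero coefficients. Second, in
windows with no real inhibitor effect the 0/100 transform divides by the
most negative difference — which is then mere noise — and stretches that
noise across the full 0–100 range, so coefficient magnitudes there carry no
physical meaning.

Both artifacts share a remedy with zero free data-dependent constants: a
coefficient is only turned into a call when the effect it claims is
physically resolvable. The coefficient is de-scaled from the per-window
normalized units back to raw AUC units (cell-index × minutes) by inverting
the 0/100 transform, and compared against the noise floor of a
control-subtracted AUC estimated from replicate spread (pooled
within-inhibitor standard deviation of replicate-well AUCs, propagated
through the replicate mean and the control subtraction). The default
threshold is 3 noise standard deviations — the conventional detection
limit — configurable via `min_effect_sigma`, with 0 restoring the bare
nonzero rule. When a plate carries no replicates the gate is inactive.

# SOM clustering

Profiles are the kinase rows of the functionality matrix, in
$\{-1, 0, +1\}$ per window, used raw (no rescaling — the encoding already
places both signs symmetrically around 0). The map is a 6×6 grid by
default. Because no training schedule is canonical for maps this small, the
package uses standard small-map defaults, all configurable and all recorded
in the run manifest:

* Gaussian neighborhood, initial width `sigma = 1.0` grid units;
* initial learning rate 0.5;
* inverse-time decay $1/(1 + t/(T/2))$ of both;
* $T$ = 500 × number of profiles random-sampling update steps;
* codebook initialized uniformly within the per-feature data range,
  seeded.

Best-matching units are chosen by Euclidean distance with exact ties broken
toward the lowest (i, j) coordinate in row-major order. The per-neuron mean
trace is the arithmetic mean of member calls per window: +1 exactly when
every member is barrier-strengthening, −0.5 when half are weakening, and so
on. The distance map (U-matrix) is each neuron's summed Euclidean distance
to its 8-connected neighbors, normalized by the maximum such sum.
Quantization error is reported before and after training and must not
increase; topographic error is reported as a diagnostic only, since
topology preservation on a 6×6 map of ternary profiles is an expectation,
not a guarantee.

Published neuron occupancies from real screens are not reproduction
targets: they depend on unpublished training seeds and on the exact kinase
sets predicted upstream.

# Network assembly

The background graph is built from a kinase-substrate flat file
(PhosphoSitePlus `Kinase_Substrate_Dataset` dialect): rows are kept when
kinase and substrate organisms both match the requested organism and the
substrate is itself a kinase (membership in a bundled, editable list of
human protein-kinase gene symbols; any user list can be substituted).
Multiple phosphosites collapse to one directed edge; autophosphorylation
rows become self-loops. A synonym table can remap gene symbols before
filtering; unmapped neuron members are logged in provenance, never silently
dropped.

For a neuron's member set, *every* shortest directed path is enumerated for
*every ordered pair* of members and their union forms the local network.
All-shortest-paths (rather than one arbitrary path per pair) is the default
because single-path unions are nondeterministic under tie-breaking; ordered
pairs are used because the graph is directed. Non-member kinases on the
paths are labeled `inferred`. A singleton member forms a network only
through an autophosphorylation self-loop; a member set with no connecting
paths yields no network — mirroring neurons excluded from analysis in
practice. Path length is reported in node counts (a direct edge scores 2, a
lone self-loop node scores 1).

The composite network pools members across several neurons and runs the
same search; the pipeline's network stage also writes the composite of all
occupied neurons as a global summary artifact. The overlay annotates the
full background graph with per-phase node classes (weakening /
strengthening / both) from the functionality matrices and edge classes from
the signs of the neuron networks each edge appears in.

# The synthetic-screen generator

The generator emulates the study conditions so the whole pipeline is
testable without licensed or unreleased inputs:

* 28 inhibitors in triplicate, 60 candidate kinases by default;
* sampling every minute for 2 h after inhibitor addition, then every 5 min
  to 6 h, with pre-thrombin baseline samples (thrombin 6 min before
  inhibitors);
* a control disruption/recovery curve
  $c(t) = -D\,(t/t_{\min})\,e^{1-t/t_{\min}}$ with $D = 0.4$ index units
  and $t_{\min} = 25$ min, an acute dip bottoming out 20–30 min after
  thrombin as observed for thrombin-treated brain endothelial monolayers;
* six planted kinases with signed, time-windowed, additive effects scaled
  linearly by per-inhibitor inhibition $(1 - a_{ik}/100)$ — the exact
  linearity KiR assumes — including one switch kinase (weakening 5–30 min,
  strengthening 100–140 min) and magnitudes 0.2–0.3 index units;
* Gaussian measurement noise, default sd 5% of the smallest planted
  magnitude, independent per replicate well;
* a panel guarantee that every kinase is inhibited below 50% residual
  activity by at least two inhibitors (identifiability);
* an Erdős–Rényi background digraph with planted chains guaranteed present.

What the generator deliberately does **not** model: inhibitor
pharmacokinetics (effects switch on and off instantaneously), saturation or
epistasis between kinases (effects are purely additive), drift or
well-position artifacts, and panel measurement error. Passing recovery
tests on this generator therefore demonstrates that the pipeline inverts
its own forward model at realistic noise — not that real screens are free
of model mismatch.

Recovery is scored at kinase level with window slack: a predicted kinase
counts as detected when planted and when its called windows overlap the
true active windows dilated by ±2 windows; precision is 1 by convention
when nothing is predicted; the per-kinase window-overlap Jaccard is
$|P \cap \mathrm{dilate}(T)| / |P \cup T|$.

# Numerical choices and degenerate inputs

* AUC integration is exact for piecewise-linear signals; windows outside
  the sampled range are errors, not extrapolations.
* A constant window response gives an all-zero fit (valid, not an error);
  `NA` responses are errors.
* Fixed-lambda fits terminate a descending warm-start path at the requested
  lambda, so `lambda = 0` reproduces least squares on over-determined
  panels to high precision (tighten `thresh` for oracle-grade agreement).
* Zero-variance windows make Pearson correlation undefined; they are
  returned as `NA` with a warning rather than silently dropped.
* The 0/100 transform's fallback (no negative delta) warns and keeps the
  column unscaled about the control anchor.
* SOM training on an empty profile set, distance maps on 1×1 grids, empty
  neurons, and phase ranges outside the window grid are all errors by
  contract.

# Problem sizes used in the checks

The package's own verification runs the default screen (28 inhibitors ×
60 kinases × 3 replicates, 164 windows) once end to end and reuses it
across checks; graph contracts run on 100 random digraphs of at most 12
nodes against a brute-force breadth-first oracle; SOM contracts use dozens
of ternary profiles. These sizes exercise every code path at full method
fidelity while keeping a complete verification run in minutes on a single
core.

# Known limitations

* Kinases absent from the activity panel cannot be predicted, whatever
  their real role; the panel defines the candidate universe.
* The noise-floor gate requires replicate wells; single-replicate plates
  fall back to the bare nonzero-coefficient rule and will over-call.
* Network reconstruction inherits the biases of the background database:
  missing true edges shorten nothing (paths simply do not exist), and
  promiscuous hub kinases attract inferred-node status.
* The SOM gives no uncertainty on cluster assignments; profiles near
  codebook boundaries can move between neurons under reseeding.
* p-value calibration of kinase selections and stability selection are out
  of scope.
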