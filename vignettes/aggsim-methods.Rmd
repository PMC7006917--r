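---
title: "Modelling molecular aggregation at the membrane with density-coupled agents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling molecular aggregation at the membrane with density-coupled agents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Membrane proteins form nanoscale clusters, and many competing cellular
processes (lipid domains, protein affinity, the cortical actin picket fence,
size exclusion) have been proposed as drivers. `aggsim` implements a highly
abstracted alternative: each molecule is an agent whose Brownian mobility
depends only on its current local density, a single "desire for clustering"
rule. If that one rule reproduces cell-like cluster statistics, the detailed
biophysics can be summarised by it.

Agents live on a flat 2D membrane patch with toroidally wrapped boundaries
(default 3 × 3 µm²), so molecule number is conserved and no edge corrections
are needed. The local density of agent $i$ is quantified by the localized
linearised Ripley's L statistic

$$L_{R,i} = \sqrt{\frac{A\,k_i}{\pi\,(n-1)}},$$

where $k_i$ is the number of other molecules within radius $R$ of $i$
("encircled molecules"), $A$ the patch area and $n$ the total count. The
normalisation makes the CSR (complete spatial randomness) expectation of
$L_R$ equal to $R$: with $n = 2000$ in $9\times10^6$ nm², $k = 7$ gives
$L_{100} \approx 100$ nm. $R$ defaults to 100 nm because membrane
nanoclusters are typically sub-diffraction (< 200 nm). Targets can be stated
either as an $L$ value or as a neighbour count via `l_from_count()` /
`count_from_l()`, which are exact inverses.

Each 10 ms frame, every agent's displacement rate is read off a
displacement-versus-$L$ profile and a step of length `rate × dt` is taken in
a uniformly random direction (or, in `gaussian` mode, with normal coordinate
increments whose RMS matches that step). The *Standard Condition* profile
decreases linearly from $D_\max = 3.5$ nm/ms at $L = 0$ to zero at the
target: any agent at or above its target density is fully immobile. Variant
families implement a positive mobility floor (`linear_floor`), a tent shape
immobile only at exact equality (`tent_nonconverging`), and a squared ramp
(`quadratic`).

A run starts from a CSR pattern and iterates density → rate → step →
boundary for 30,000 frames (5 simulated minutes). The per-frame mean
$\langle L^{100}\rangle$ is the headline output; replicate ensembles average
it frame-wise.

```{r, eval = FALSE}
library(aggsim)
cfg <- standard_condition(target_count = 45, seed = 1)
tr <- run_simulation(cfg)
plot(tr)
analyse_clusters(tr$final_frame)
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_agents` | 2000 | molecules in the patch |
| box | 3000 × 3000 nm | toroidal ROI |
| `dt` | 10 ms | frame interval |
| `duration` | 300 s | simulated time (30,000 frames) |
| `r` | 100 nm | density radius $R$ (variants 50, 200) |
| `d_max` | 3.5 nm/ms | mobility far from the target (35 nm per frame) |
| `d_min` | 0 | mobility at the target (`linear_floor` only) |
| `l_anchor` | 0 | $L$ at which the rate equals `d_max` |
| mesh spacing | none | pitch of the reflective actin grid (250/500/1000 nm) |

Two unit conventions deserve comment, both genuinely open in the source
material. First, rates are displacements per millisecond, so the Standard
step is exactly 35 nm per 10 ms frame; the equivalent diffusion coefficient
$({\rm step})^2/(4\,\Delta t) \approx 0.03$ µm²/s is treated as a
descriptive label, not a constraint. Second, the profile's anchor (the $L$
at which mobility is maximal) is not uniquely determined by a straight-line
profile sketch; we anchor at $L = 0$ by default and expose `l_anchor` so the
alternative (anchor at the CSR level) can be explored. "Fast" and "slow"
diffusion variants scale the step length by $\sqrt{10}$ and $1/\sqrt{10}$,
mapping tenfold diffusion-coefficient changes onto step lengths.

## Numerical choices

* **Neighbour counting** uses a cell list with cells at least $R$ wide, so a
  wrapped 3 × 3 neighbourhood is sufficient; it is exact, and tests pin it
  against an all-pairs oracle. Distance ties at exactly $R$ count as
  neighbours. Between frames the counts are maintained either by a full
  recount or by an exact incremental update that detaches and re-attaches
  only the agents that moved — the two are verified to be bit-identical, and
  the cheaper one is chosen per frame (moving agents become rare once most
  of the pattern is frozen).
* **Synchronous update**: all rates are computed from the pre-move snapshot,
  making the update order-independent and reproducible. An asynchronous
  mode (random agent order against the evolving pattern) is available as a
  pure-R sensitivity check for small patterns.
* **RNG discipline**: each replicate derives an initialisation stream and a
  motion stream from its seed, so changing the step mode never changes the
  initial pattern; direction deviates are drawn for every agent whether or
  not it moves, so the stream does not depend on the rates. Identical
  (config, seed) gives bit-identical trajectories.
* **Actin barriers** are reflective lines on a square grid whose pitch must
  divide the box. Reflection folds each coordinate back into the agent's
  mesh cell (exact specular reflection for axis-aligned lines when the step
  is shorter than the pitch, which is enforced). Barriers obstruct motion
  only; they are transparent to density counting, since they sit beneath
  the membrane and do not change in-plane distances.
* **Degenerate inputs**: patterns with fewer than 2 molecules have no
  defined density; empty patterns and zero-size clusters are legal
  everywhere in the analysis stack and reported as absent values.

## Convergence, regimes and the cut-off

The ensemble-mean $\langle L^{100}\rangle(t)$ series falls into three
regimes: *converged* (a horizontal asymptote above the CSR level within the
run), *converging* (elevated and still rising), and *csr* (indistinguishable
from the null). The asymptote criterion had to be operationalised:
`convergence_time()` returns the earliest time after which the series stays
within 2% of its end value, requires the end value to exceed the CSR level
by 5 nm, and — crucially — requires that plateau to be held for at least
60 s. Without the holding requirement any continuous rising series would
trivially end inside the ±2% band of its own final value, and a monotone
ramp would be misclassified as converged. The CSR call additionally requires
the end-window (60 s) trend slope to be below 0.02 nm/s. All thresholds are
arguments with the defaults above.

`detect_cutoff()` finds the digitization threshold of a target sweep: the
smallest tested target that is CSR with every larger tested target also CSR,
guarding against single-target noise in the marginal zone. The trivial
target at the CSR density itself is excluded. The exclusion matters: under
the freeze-at-target rule a target *at* the CSR level is not neutral — frozen
molecules act as sticky sinks and the mean $L$ ratchets slowly upward (about
15 nm over the first simulated minute), so the trivial target is neither
flatly CSR nor a genuine aggregation regime. This is an intrinsic property
of "immobile at $L \ge$ target" with a zero mobility floor.

Classification runs on the ensemble-mean series (per-replicate
classification remains available through `classify_regime()` on individual
runs for dispersion estimates).

## Cluster descriptors

Final frames are summarised by four per-ROI descriptors — cluster count, %
of molecules in clusters, molecules per cluster, cluster radius — averaged
across replicates. Clusters are called by a deterministic density-based
(DBSCAN-style) algorithm under toroidal distance with defaults
`linking_radius = 50` nm, `min_neighbors = 5`, `min_size = 5`. A Bayesian
engine with topographic-prominence thresholding, as used in parts of the
SMLM literature, is deliberately out of scope; the density-based caller is
transparent and deterministic, but it links any density-connected structure
into one cluster. On the large contiguous aggregates this model produces at
high targets, that yields systematically fewer, larger clusters (and
therefore larger radii) than a prominence-splitting engine would report —
cluster-count comparisons carry a wide tolerance for this reason, and the
radius statistic should be compared across conditions within this package
rather than against engines with different cluster definitions.

Cluster radius is defined as $\sqrt{2}\times$ the RMS toroidal distance of
members to their wrap-aware centroid (circular mean per axis, so
seam-straddling clusters are handled): the radius of the uniform disc with
the same RMS spread. Members uniform on a disc of radius $r$ give $r$; an
isotropic Gaussian blob of width $\sigma$ gives $2\sigma$.

## What the synthetic generators emulate

`generate_csr()` and `generate_blobs()` produce ground-truth patterns for
the analysis stack (uniform null; wrapped isotropic Gaussian blobs with
known membership), and `generate_l_curve()` produces flat/saturating/ramp
mean-$L$ series with closed-form convergence times for the regime
classifier. They emulate idealised point patterns only: no localization
error, no fluorophore blinking or multiple detections, no detection
inhomogeneity. Passing tests on these fixtures therefore validates the
statistics and the calling machinery, not robustness to SMLM imaging
artefacts.

## Problem sizes used in the test suite

The packaged checks run the full Standard geometry (2000 agents, 30,000
frames) but with 5–10 replicates per condition instead of 30, and probe the
cut-off on a bracketing grid of targets (e.g. 63–69 in steps of 2) rather
than the full 7–69 sweep. With ensembles this small the marginal targets
just below the cut-off are genuinely stochastic — individual conditions can
flip between "converging" and "csr" between seed sets — which is why the
cut-off detector demands CSR at *all* larger tested targets, and why
descriptor comparisons use ±30% bands.

## Known limitations

* The trivial CSR-level target drifts upward rather than staying flat (see
  above); regime analytics treat it as excluded-trivial rather than a null.
* The density-based cluster caller under-segments contiguous aggregates
  relative to prominence-based engines; radii at high targets are
  correspondingly larger.
* The asynchronous update mode is O(n²) per frame and intended for small
  sensitivity checks only.
* Static environment: no actin remodelling, no agent birth/death or binding
  kinetics, and no rigid-body diffusion of formed clusters.
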