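---
title: "Consensus-based spike sorting: model, parameters, and design notes"
author: "consensusSort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-based spike sorting: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the idea

Spike sorting assigns extracellularly recorded action-potential waveforms
to putative single neurons. Most sorters optimize a single clustering
solution under a distributional assumption on the waveforms (typically
Gaussianity) and leave cluster-merge decisions to visual inspection.
`consensusSort` takes a different route, built on *evidence
accumulation*: it runs the same simple clustering procedure many times
(`Nite`, default 100), lets the run-to-run variability probe the
ambiguity structure of the waveform ensemble, and derives both the final
partition and a per-unit error estimate from how consistently spikes
co-cluster.

Each iteration does three things:

1. K-means (`K` clusters, fresh random initialization) on a feature
   projection of the waveforms;
2. computes the mean spatiotemporal waveform (template) of every K-means
   cluster;
3. re-assigns every spike to the template that explains it best in the
   least-squares sense, allowing a bounded amplitude scale
   `a` in `[0.8, 1.2]`, and records the mean-squared residual
   (the spike's chi-square for that iteration).

From the resulting `n_spikes x Nite` label matrix the consensus stage
computes:

- `P0(i, j)`: the fraction of iterations in which spikes `i` and `j`
  share a label. Spikes with identical label vectors are interchangeable
  and are compressed to one *signature* before anything quadratic in the
  number of items is computed.
- *Core clusters*: a single-link tree over distance `1 - P0` is cut with
  an inconsistency-coefficient threshold (see *Numerical choices*); this
  yields groups of spikes that co-cluster more consistently than their
  surroundings. Cores smaller than `minCsize` spikes are re-assigned to
  the closest (highest mean `P0`) larger core, or excluded when even
  that co-assignment probability is at or below chance (`1/Nite`). The
  size threshold exists to stop small spike groups from acting as
  single-link chain links between distinct units.
- `Pmis(Ci, Cj)`: the expected fraction of misclassified spikes if the
  two clusters were kept separate. Per iteration and per K-means cluster
  `k`, whichever side of the pair has the strictly smaller (nonzero)
  intersection with `k` contributes its intersecting spikes; the counts
  are averaged over iterations and normalized by `N_Ci + N_Cj`. Ties
  contribute neither side.
- *Final clusters*: single-link over `1 - Pmis`, cut at `1 - P_th`
  (default `P_th = 0.15`), so clusters whose mutual misclassification
  probability exceeds `P_th` merge. `Pmis` is then recomputed once
  between the final clusters with their new sizes.

Spikes in the worst 5% of the mean chi-square distribution are withheld
from consensus clustering and assigned afterwards: by a plain template
fit when one final template explains them, otherwise by greedy matching
pursuit over (cluster, delay, amplitude) to resolve temporally
overlapping spikes (up to 3 components; delays within half the waveform
window; a component is emitted as its own spike-train event when its
delay is below the censored period, i.e. when the detector could not
have seen it separately).

Per-unit quality is estimated from the same ensemble: `PFP`/`PFN` count
how often a unit's spikes co-cluster with outsiders (normalized by unit
size and `Nite`), and a unit is validated when `PFP + PFN < 0.20`, its
template SNR exceeds 4, and its refractory violations (`ISI < 2 ms`)
stay below 1%.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `band` | 200--4000 Hz | zero-phase band-pass edges |
| `zTh` | 5 | detection threshold in robust noise SDs (`-zTh * median(|V|)/0.6745`) |
| `tauCMs` | 0.6 ms | censored period: closer events on nearby channels are one detection |
| `lumpRadiusUm` | 60 um | cross-channel lumping distance |
| `windowMs` | 6 ms | stored waveform window (trough-centred) |
| `tauWinMs` | 2.5 ms | feature/template window |
| `pLillie` | 0.01 | Lilliefors level for keeping non-Gaussian principal components |
| `K` | `"auto"` | K-means clusters per iteration (see below) |
| `Nite` | 100 | clustering iterations |
| `chi2Percentile` | 95 | chi-square gate: fraction of spikes entering consensus |
| `minCsizeRange` | 8 | core-size threshold (single value) or sweep range |
| `Pth` | 0.15 | misclassification probability above which clusters merge (0.05 for 2-D point demos) |
| `snrGate`, `misclassGate`, `isiGate` | 4, 0.20, 0.01 | unit validation criteria |

### Choosing K

`chooseK()` implements the fit-quality rule: the mean chi-square over
all spikes decreases with K towards a plateau, and the chosen value is
the smallest candidate (all below `sqrt(n_spikes)`) whose mean
chi-square lies within 15% of the best value attained — probing at full
Lloyd convergence, averaged over 5 passes, because the single-run
chi-square is a noisy local optimum.

The pipeline's `K = "auto"` adds one correction and one multiplier. The
plateau onset over-counts waveform *modes* when amplitude jitter splits
a unit into scaled copies of one template, so templates from a probe
run that are scaled copies of each other (relative residual under
unconstrained 1-D scaling below 0.25) are counted as one mode. The
working K is then 4x the mode count (capped below `sqrt(n)`): K must
exceed the number of modes comfortably, so that successive runs carve
the modes into different cells — that disagreement is the signal the
consensus stage feeds on — while a much larger K freezes each spike
into a stable micro-cell and manufactures spurious structure. On
synthetic recordings the sorting quality was flat across roughly 3-4
cells per unit and degraded on both sides.

### Why the K-means is deliberately un-optimized

Three related design choices all serve ensemble diversity, and all three
were measured to matter:

- initialization by a uniform random sample of K spikes (not a
  spread-out seeding such as k-means++): spread seeding makes successive
  runs converge to near-identical partitions;
- a single run per iteration, no restarts;
- Lloyd updates truncated at 10 rounds rather than run to convergence:
  fully converged runs reproducibly reach the same interior partition of
  each unit's spike cloud, so iterations stop disagreeing, and the
  consensus stage then sees artificially stable sub-clusters (observed
  as a unit split into two stable halves with `Pmis` just below the
  merge threshold).

When clustering *quality per iteration* rather than diversity is wanted
(as in the `chooseK` probes), full convergence is used.

### The core-size threshold

The sweep prescribed for chain-limited data (increase `minCsize`,
re-merge, keep the value maximizing the number of final clusters until
exclusions exceed 0.1%) is implemented (`minCsizeRange = c(4, 19)`, the
interior of the documented typical range) but is *not* the default. On
recordings without small-core chaining the final count decreases with
`minCsize`, and the max-count rule then systematically selects the most
fragmented partition. The default is therefore a fixed `minCsize = 8`,
the value of the basic point-cloud protocol. A structural point
motivates caring about this: `Pmis(A, B)` is bounded above by
`N_B / (N_A + N_B)`, so a satellite cluster below ~18% of its parent
unit can *never* reach `P_th = 0.15` no matter how perfectly it
co-mixes — reassignment under `minCsize` is the only mechanism that can
absorb small stable satellites.

### Flag-guided curation

Sub-clustering of one cell's spikes (amplitude variability, bursting) is
an expected behaviour at `P_th = 0.15`; such splits are detected by the
burst-merge flags (template correlation above 0.70 at the best time lag
*and* `Pmis > 0.05`). The sorter itself never merges automatically —
`sortSpikes()` only lists the flagged pairs — but
`curateFlaggedMerges()` applies exactly those merges deterministically
as an explicit post-processing step, which is how the package's
end-to-end evaluations are run. On the synthetic recordings this
resolves the roughly one-in-fifteen case where a unit's spike cloud is
cut into two stable halves.

## What the synthetic generator emulates — and what it does not

`makeRecording()` builds multichannel recordings from three parametric
template shapes (biphasic, triphasic, and a wide-repolarization
"bursty" shape) with Gaussian spatial amplitude decay over the
electrode geometry, Poisson spike trains with a 2-ms absolute refractory
period, per-spike amplitude scales from `Normal(1, jitterSd)` truncated
at zero (default +/-10%), and band-limited (200--4000 Hz) spatially
correlated Gaussian noise whose stationary spatial covariance matches
the requested matrix (the band-pass power loss is compensated
analytically). `replicateRecording()` reproduces the
replicated-channel-block protocol used to manufacture overlap-rich
ground truth; `injectSpikes()` the scaled-template injection protocol.

Real recordings additionally contain electrode drift, bursting with
systematic within-burst amplitude decay, non-Gaussian and non-stationary
noise, and genuinely overlapping background multi-unit activity. None of
these are emulated, so passing tests on this generator demonstrates the
machinery's correctness and its behaviour under controlled difficulty,
not performance on tissue. Two documented limitations visible even on
synthetic data: overlapping spikes closer than the censored period *on
shared channels* that still pass the chi-square gate are never routed to
the pursuit stage (measured recovery 85-96% in that regime, vs 100% when
the units occupy distinct channel blocks as in the replicated protocol);
and a merged pair of truly distinct units appears well isolated to the
stability estimates if no third cluster contests its spikes.

## Numerical choices

- *Filtering*: 4th-order Butterworth applied forward-backward; the
  effective magnitude response is squared, so a 1-kHz component sits ~5%
  below unity rather than within 1%.
- *Trough alignment*: waveforms are cut on a 4x-upsampled grid
  re-centred on the interpolated trough (after Gaussian matched
  smoothing, sigma 0.12 ms) and decimated to the band's Nyquist rate
  (2x the upper edge, 8 kHz by default). Without this, detection noise
  of +/-1 raw sample splits units into shifted-copy clusters.
- *Whitening*: spatial noise covariance from spike-free snippets (up to
  5000, threshold 4 robust SDs), symmetric (ZCA) inverse square root,
  ridge-regularized (`1e-6 * trace/channels`) when conditioning exceeds
  `1e8`; skipped (identity) when the recording carries no measurable
  noise.
- *Inconsistency cut*: MATLAB-convention coefficient at depth 2
  (`(height - mean)/sd` over the link and its direct children). The cut
  is made at the largest observed coefficient value — immediately above
  it the whole tree lumps into one cluster — treating values equal
  within `1e-6` as one band, because the depth-2 coefficient has hard
  algebraic ceilings (e.g. `2/sqrt(3)`) that many links attain up to
  float noise, and cutting only the float-max member of such a band
  produces an arbitrary coarse partition.
- *Tie-breaking*: template assignment ties (chi-square differences below
  `1e-9` of the spike's energy) go to the lowest cluster index; without
  the tolerance, exact fits on noiseless data break ties on
  floating-point dust that is stable across iterations and manufactures
  fragments.
- *Degenerate inputs*: the detection threshold is floored at 5% of the
  array-wide largest deflection so that (near-)noiseless recordings do
  not detect filter ringing; an all-zero channel yields threshold 0 and
  is skipped with a warning.
- *Merging cut*: `cutree` at height `1 - Pth - 1e-9`, so clusters merge
  only when `Pmis` strictly exceeds `Pth`.
- *Indexing*: all in-memory spike times are 1-based R sample indices;
  exported CSVs carry the same convention.

## Problem sizes used by the test-suite

The package's own checks run entirely on generated data, at sizes chosen
to exercise every stage with comfortable statistics: the five-cloud 2-D
demonstration uses 1000 points and 200 K-means runs; the end-to-end
recovery check sorts a 120-s, 8-channel, 3-unit recording at 5 Hz per
unit (~1800 spikes, `Nite = 100`); the estimator-validation check sorts
a 90-s, 16-channel recording with 10 units whose amplitudes are graded
from 40 to 130 uV; the overlap check plants 24 cross-unit spike pairs at
0.2-0.5 ms separation among ~900 isolated spikes on 16 channels. Module
tests use smaller fixtures and brute-force oracles (naive double loops,
set enumeration, exhaustive agglomeration) for every statistic the
package computes in vectorized or compiled form.

## Known limitations

- Waveform stationarity is assumed throughout; drift is out of scope.
- The chi-square gate percentile (95) bounds how many overlap events can
  be routed to the pursuit stage.
- `Pmis`-based merging cannot absorb clusters much smaller than ~18% of
  their counterpart (see above); the size threshold and the curation
  flags exist precisely for that regime.
- The co-assignment matrix is quadratic in the number of distinct label
  signatures; a guard (default 20000 signatures) suggests the
  best-iteration core mode (`coreMode = "best_iteration"`), which
  replaces the inconsistency-cut cores by the clusters of the
  lowest-chi-square iteration and bounds memory by `K`.
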