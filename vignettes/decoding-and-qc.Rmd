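---
title: "Spot-based barcode decoding and quality control: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spot-based barcode decoding and quality control: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotcall)
```

## The problem

Combinatorially barcoded FISH assays (seqFISH and relatives) identify
hundreds of mRNA species with a handful of fluorophores by imaging the
same tissue over `R` hybridization rounds. A transcript molecule emits
one fluorescent spot per round, and the sequence of channels across
rounds — its barcode — identifies the gene via a codebook. Decoding
means linking detected spots across rounds into barcodes. This is hard
because spots drift between rounds, some spots are never detected
(dropout), and spurious detections abound. Decoders that demand mutual
nearest neighbors between rounds lose many true transcripts under
drift; the exhaustive decoder implemented here instead considers *every*
combination of nearby spots that could form a barcode and selects the
best non-overlapping subset.

## The decoding algorithm

Given spots `(r, c, x, y, z, intensity)`, a codebook with no "off"
rounds, and a search radius, one decoding pass proceeds:

1. For each spot, find all neighbors in *other* rounds within the
   search radius (Euclidean distance in x, y, z).
2. For each spot ("seed"), enumerate the full cartesian product of
   one-spot-per-round combinations drawn from the seed's neighbors,
   with the seed occupying its own round.
3. Score each candidate:
   $$\mathrm{Score} = Q + S_v \cdot C,\quad
     Q = \log\big(1 + (R - \mathrm{QualSum})\big),\quad
     S_v = \log\Big(1 + \sum_{i \in \{x,y,z\}} \mathrm{var}(\mathrm{coords}_i)\Big)$$
   where `QualSum` is the summed normalized intensity of the member
   spots and `C = 2` by default. Lower is better; a perfect barcode
   (all intensities 1, spots co-located) scores 0.
4. *filter-first*: take each seed's minimum-score candidate, then drop
   it if its channel sequence matches no codebook entry.
   *decode-first*: restrict to codebook matches first, then take the
   minimum. Filter-first is more precise; decode-first recovers more.
5. Support filter: candidates with identical spot sets are the same
   barcode; keep a barcode only if at least `n` of its own member
   spots selected it as their best (`n` set by the mode).
6. Conflict resolution: build a graph whose nodes are surviving
   barcodes and whose edges join barcodes sharing a spot; eliminate
   nodes in order of highest degree — ties broken by removing the
   higher (worse) score — until no edges remain. Survivors are
   pairwise spot-disjoint.

Decoding runs in stages: for each radius in a schedule rising from 0 to
the search radius, a filter-first pass then (mode permitting) a
decode-first pass, each removing its consumed spots. Tight,
high-confidence barcodes are therefore called before looser ones.

### Mode presets

The precision/recall trade is packaged into three presets controlling
the support threshold and whether decode-first runs at all:

| mode   | filter-first support | decode-first support |
|--------|----------------------|----------------------|
| high   | R                    | (pass skipped)       |
| medium | R                    | R − 1                |
| low    | R − 1                | 1                    |

These exact values are this package's own defaults (chosen to realize
the documented precision ordering; they are overridable via
`decode_config(min_support = ...)`) — the original description leaves
them unpublished. The acceptance suite verifies the ordering
empirically: precision(high) ≥ precision(medium) ≥ precision(low) and
recall ordered oppositely on noisy synthetic data.

### Error correction

When every pair of codebook entries differs in ≥ 2 rounds, a barcode
remains uniquely identifiable with any single round missing. With
`error_rounds = 1`, after all exact passes the same staged structure
runs once more over `(R − 1)`-spot candidates; a partial channel
sequence is assigned only when it is consistent with exactly one
codebook entry. Such calls carry `rounds_used = R − 1` in the output so
downstream analyses can separate them; they are inherently more prone
to false positives. In the error passes, `R − 1` plays the role of `R`
in the support presets above. `RoundNum` in the score formula remains
the experiment's `R` (only relative scores within a pass matter).

### Determinism and tie-breaks

All orderings are fixed: score ties within a seed break toward the
larger `QualSum`, then the lexicographically smallest spot-id key;
elimination ties after degree and score break toward removing the
later-indexed node. Degrees are recomputed after each removal by
default (`recompute_degrees = FALSE` switches to initial degrees; the
verbal description of the elimination order is ambiguous between the
two). Note the elimination rule stops when no edges remain and never
re-inserts removed nodes, so the surviving independent set need not be
*maximal* — this is faithful to the description rather than an
optimization.

### Intensity normalization

The score requires `QualSum ≤ R`, i.e. intensities in [0, 1]. The
normalization convention — not fixed by the original description — is
division by the maximum observed intensity per (round, channel) group,
clamped to [0, 1]. This also equalizes channel-to-channel brightness
differences, which is what the intensity term is meant to reward
within, not across, channels.

## QC metrics

All metrics run per FOV and over combined FOVs (`run_pipeline`). When
the spot table carries segmentation assignments, spots without a
`cell_id` are excluded from the spot-tally metrics. Conventions not
fixed by the original description, all documented and switchable where
it matters:

- **Off-target threshold**: per-target call counts are tallied
  (including zero-count targets); the proposed on-target cutoff is the
  upper end of a two-tailed 95% normal CI on the off-target (blank)
  counts, `mean + 1.959964·sd`, computed for non-corrected calls and
  for corrected + non-corrected combined. `sd` is the *sample*
  standard deviation by default (`sd_type = "population"` available).
- **Per-cell FPR**: `off / (off + on)` over each cell's calls.
- **Tally moments**: standard deviation and *adjusted Fisher–Pearson*
  sample skewness of per-round/per-channel counts, for both raw spots
  and the source spots of decoded transcripts.
- **Transcripts per cell**: cells below `median − 1.5·(Q3 − Q1)` are
  flagged, with linear-interpolation (type 7) quantiles.
- **Ripley's K**: the raw estimator `K(r) = A·n_pairs(d ≤ r)/(n(n−1))`
  with no edge correction, evaluated at 10 radii spanning 0 to
  `sqrt(A)/2`. (The source text's radii range is garbled
  ("imagearea2"); we read it as `sqrt(area)/2` and expose it as a
  parameter.) The CSR envelope is the pointwise 2.5/97.5 percentile
  band over 100 (configurable) uniform resamples with the same `n` and
  window. Under CSR, ~95% of (pattern, radius) points fall inside,
  which the acceptance suite verifies by calibration.

## The synthetic-data generator

`simulate_spots()` emulates exactly the structure the decoder assumes:
ground-truth transcripts placed in the FOV (uniform or Gaussian
clusters), one spot per non-dropped round at the barcode's channel,
isotropic Gaussian positional drift per spot, clamped-Gaussian
intensities (default mean 0.8, sd 0.1 — bright spots with moderate
spread), iid per-(transcript, round) dropout, and Poisson background
spots with uniform positions, random channels, and (worst case) the
same intensity model. A `g × g` grid of square "cells" stands in for a
segmentation mask when per-cell metrics are exercised.

It deliberately does **not** emulate: optics (PSF overlap between
nearby spots, chromatic aberration), intensity correlation across
rounds of one molecule, spatially structured noise, registration
failure modes, or realistic cell shapes. A green test on this
generator therefore establishes algorithmic correctness of the
decoding and QC machinery under the stated noise model — not
performance on any real instrument's data.

The noisy benchmark world (used for the mode-ordering acceptance
criterion) is fixed as: 200 transcripts in a 100 × 100 FOV, drift
σ = 2 length units (≈ 0.6 × the ~3.3-unit mean nearest-neighbor
transcript spacing at this density, i.e. drift comparable to spacing),
10% dropout, 0.01 background spots per unit area per round (≈ 100 per
round, about 45% of the true spot count), search radius 5. These were
chosen from that verbal description once and then frozen.

The exposure-degradation model `output = input + n·input` with
`n ~ N(1.5, var = 3.0)` is provided for QC-sensitivity experiments;
negative outputs are clamped at 0 by default since the degraded
quantities are non-negative intensities (`clamp = FALSE` exposes the
raw model, which the moment tests use).

## smFISH threshold utilities

Spot detection over a threshold sweep yields a non-increasing
spot-count curve. The elbow (used as the final detection threshold) is
computed as the point of maximum perpendicular distance to the chord
joining the curve's endpoints after min–max normalization of both axes
— the standard knee heuristic; the original description names no
method, so correlation figures that depend on the exact elbow are not
reproduction targets. Ties break toward the smallest threshold. The
normalized AUC of the same curve (a mixing metric: high AUC = signal
and noise intensities poorly separated) min–max normalizes both axes
and integrates with composite Simpson's rule; uneven grids use the
quadratic-fit generalization per interval pair, with a trapezoid on a
trailing odd interval.

## Numerical and degenerate-input choices

- Logarithms are natural; variance in `S_v` is the population variance
  (candidates have ≤ R points; only score ordering matters).
- Radius 0 links only exactly co-located cross-round spots (distance
  comparisons use a 1e-12 absolute slack).
- Empty spot tables decode to an empty, correctly-typed table.
- A candidate-per-seed cap (`max_candidates_per_seed`, default 50000)
  guards against cartesian blow-up in pathologically dense data; seeds
  over the cap contribute nothing in that stage and the cap is a
  config knob, not a hidden constant.
- Precision is reported as 1.0 with a `zero_calls` flag when a decode
  returns nothing, so downstream comparisons never divide by zero.

## Known limitations

- Neighbor search materializes a dense distance matrix — fine for the
  10^3–10^4 spots per FOV this package targets, not for 10^6.
- FOVs are processed sequentially; there is no parallelism.
- The greedy independent set is an approximation; no optimality bound
  is claimed (tests bound it by the exact MIS on small instances).
- Pixel-based decoding, image preprocessing, and segmentation are out
  of scope; inputs are spot tables, not images.
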