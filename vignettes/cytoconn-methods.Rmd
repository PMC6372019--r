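---
title: "Methods: from laminar profiles to connectome statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from laminar profiles to connectome statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cytoconn)
```

`cytoconn` relates two descriptions of the same cortex: a *microscale* one —
laminar intensity profiles measured on cell-body-stained histology — and a
*macroscale* one — a streamline-tractography connectome. This vignette
documents the model behind each stage, the parameters that matter, the
numerical choices made where the procedure was genuinely open, and what the
synthetic-data tests do and do not establish.

## Laminar profile extraction

A *profile* is the mean stain intensity in 1,000 depth blocks between a
point on the pial surface and a paired point on the white-matter surface.
Two design choices deserve spelling out:

* **Block geometry.** The pair and its nearest-neighbour pair (nearest by
  Euclidean distance between segment *midpoints* — a definition symmetric in
  the pial and white-matter ends and robust to thickness differences) span a
  quadrilateral. We realize the 1,000 blocks as depth *strata* of the
  bilinear map of the unit square onto that quadrilateral: stratum *k*
  covers depth fractions [(k−1)/1000, k/1000), sampled on a lattice of 4
  points across by as many points in depth as needed to resolve the longer
  segment at pixel scale, with bilinear image interpolation. Full-width
  strata (rather than sub-columns) are an assumption; they are
  resolution-independent and oracle-checkable.
* **Region assignment** uses the segment midpoint's nearest labeled pixel —
  the least-biased single representative of the segment. Distance ties break
  to the lowest region id, then pixel order, so runs are deterministic.

Quality control applies two rules *in a fixed order*: first the distance
rule (drop profiles whose midpoint lies beyond Q3 + 1.5·IQR of the
nearest-labeled-pixel distance distribution; quartiles by linear
interpolation, i.e. `quantile(type = 7)`; the fence is one-sided because
only "too far" profiles are suspect), then the boundary rule (drop profiles
whose nearest-neighbour pair is assigned a different region). Regions
keep their regional mean profile only when at least `min_count = 20`
profiles survive; thresholds of 0 and 50 are exercised in the tests as
sensitivity settings.

## Similarity and the rank-matched transform

Interregional similarity is the Pearson correlation of regional mean
profiles. Because its distribution is generally non-normal, the off-diagonal
upper-triangle values are *rank-gaussianized*: values are replaced by
standard-normal quantiles at plotting positions (r − 0.5)/n (average ranks
for ties — the tie policy is our choice, as is the plotting position), then
affinely rescaled so the sample mean is exactly 1 and the sample SD exactly
0.2. The final rescale guarantees the printed moments for any n. The map is
monotone (rank-preserving) and idempotent. The same transform is applied to
streamline counts before edge-level correlations. A raw-similarity mode is
retained simply by not calling `gaussianize_similarity()`.

## Synthetic sections: what they emulate

`make_section()` draws the cortical ribbon as a circular annulus — pial
surface outside, white matter inside, regions as angular sectors — because
the closed form makes every oracle exact: perpendicular point pairs are
radii, and a pixel's cortical depth is an affine function of its radius.
`make_truth_profiles()` builds each region's ground-truth curve as six
Gaussian layer bumps whose amplitudes vary smoothly (low-order Fourier
modulation) along the ribbon, giving neighbouring regions similar curves and
a realistic spread of interregional correlations. Intensities live in
[0, 1]; only correlations matter, so the scale is arbitrary, and a
`polarity` flag flips the convention of whether darker stain records as
higher values, which is a digitization convention rather than a fact.

What the annulus does *not* emulate: cortical folding and curvature
gradients, thickness variation (every radius has the same length, so
thickness-agreement correlations on synthetic data are degenerate and are
reported as `NA`), staining artifacts, and 3-D section geometry. Passing the
recovery tests therefore shows the extraction machinery is correct, not that
it is robust to histological artifact.

One numerical caveat: within roughly one pixel of either boundary, bilinear
interpolation mixes ribbon and background intensities, so the outermost few
strata of a profile are biased toward the background. Tests of monotonicity
and recovery assess the ribbon interior; regional recovery correlations
still exceed 0.99 at the default 400-px section size.

## Cohort generator: the planted effect

`make_cohort()` plants a similarity–connectivity coupling in two levels,
mirroring how a group-consensus threshold behaves in real cohorts:

* a *group-level* edge indicator drawn once per pair with probability
  `plogis(qlogis(base_density) + coupling_beta * sim)`;
* per subject, a group edge is expressed with probability
  `p_subject = 0.8`, and expressed edges receive integer streamline counts
  `round(max(0, w0 + coupling_beta * sim + N(0, noise_sd)))` — rounding a
  truncated Gaussian because streamline counts are counts.

Defaults (`base_density = 0.15`, `w0 = 10`, `noise_sd = 3`,
`p_subject = 0.8`) were chosen on design grounds: with raw similarities
averaging ≈ 0.5, a coupling of 2 yields a realized edge density near 30%
(typical of consensus connectomes at this parcellation scale), subject-level
weight noise of about a third of the baseline count, and a per-edge
weight effect (≈ 0.4 counts per similarity SD) detectable across hundreds of
edges but invisible in any single one. Calibration is verified empirically:
with `coupling_beta = 0` the edge-level t test rejects at the nominal 5%
rate; with `coupling_beta = 2`, 60 regions and 30 subjects, the t statistic
is positive and FDR-significant in ≥ 95% of replicates.

## Tracking rules

`track_fact()` follows the classical deterministic fiber-assignment scheme:
seeds at the fixed 2×2×2 subvoxel grid (the seed count is prescribed; the
placement is our determinism-preserving choice), steps of 0.5 voxels along
the current voxel's axial direction with the sign aligned to the direction
of travel, re-reading the direction on voxel change, and termination when
the next voxel leaves the mask, has FA < 0.1, or turns by more than 45° —
strictly more: a 45.000° turn is traversed. The comparison uses a 1e-9
cosine guard so the boundary angle is not lost to floating-point round-off.
Streamline endpoints (not traversed voxels) define the region pair for
counting.

## Graph metrics

Path length is defined as the *lowest number of edges* traversed, so
betweenness and mean path length use binary hop counts on the consensus
topology even for the weighted network; nodal strength is the only
weight-using metric. A `weighted_paths` flag switches the path-based metrics
to 1/weight edge lengths for sensitivity analysis. Betweenness is
normalized by (N−1)(N−2) (ordered pairs), and its log transform uses the
offset ε = 1/((N−1)(N−2)) — the scale of the smallest attainable nonzero
value — so zero-betweenness nodes stay finite. Disconnected consensus
networks raise an error rather than returning partial path statistics.

## The 28-test family

The battery is declared in `default_test_family()` as data, not scattered
through code: the edge t test; NOS and density correlations; the
distance-category ANOVA (short/mid/long = shortest 25%, middle, longest 25%
of connected-pair centroid distances, ties resolved by stable order) with
three post hoc t tests and three per-bin correlations; the
distance/volume/area-residualized t test and correlation; three hemisphere
subsets of each edge-level analysis; node-level strength (two weight
kinds), degree, two profile-count-controlled partial correlations, a
distance-residualized node-level correlation, betweenness, clustering and
path-length correlations; and the strength coefficient of the joint
regression of regional similarity on the four nodal metrics. Only the
strength coefficient of that regression enters the corrected family; all
four coefficients are reported in `report$regression`. Benjamini–Hochberg
q-values are computed across the declared family only, with significance at
q < 0.05.

Pooled-variance (Student) t tests are used throughout rather than Welch,
consistent with integer degrees of freedom n1 + n2 − 2. The
distance-residualized *node-level* correlation regresses each region's mean
centroid distance to the other included regions out of both regional
similarity and nodal strength — the pairwise distance must be reduced to one
value per region, and the mean is the least structured reduction.

## Problem sizes and determinism

The default synthetic study uses 60 regions, 30 subjects, 40 point pairs
per region on a 400-px section, and 1,000 blocks per profile — enough for
every region to clear the 20-profile threshold at roughly the same
profile-to-threshold ratio as a full histological study, while a complete
run stays near twenty seconds. Replicate-level calibration
(`planted_recovery()`) skips image extraction and drives cohorts directly
from ground-truth profile similarity, which is what makes 100–500 replicate
studies affordable; the image-extraction path is exercised by its own
recovery tests. Every generator is a pure function of its arguments
including the seed, and a pipeline run writes byte-identical report JSON
when repeated with the same config.

## Known limitations

* The annulus ribbon has uniform thickness and no curvature, folding or
  artifact; thickness-related validations are degenerate on synthetic data.
* The tractography operates on voxelized axial direction fields without
  interpolation or crossing-fiber handling; it is a fixture for the
  termination rules, not a reconstruction method.
* Statistical tests treat region pairs as independent observations; no
  spatial-autocorrelation-preserving null models are provided.
* The headline effect sizes of a full-scale histology + in-vivo cohort are
  not reproducible at synthetic desk scale; what the tests establish is the
  directionality, calibration and procedural constants of the pipeline.
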