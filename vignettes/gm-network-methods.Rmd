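---
title: "Grey matter network small-worldness: methods and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grey matter network small-worldness: methods and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmnet)
```

## The method

Structural covariance ("grey matter") networks describe, within a single
subject, how similar the local grey matter structure is between pairs of
brain locations. `gmnet` implements the single-subject construction and its
group-level statistics end to end:

1. **Nodes.** A segmented GM partial-volume map, resliced to isotropic 2 mm
   voxels, is tiled by non-overlapping 3×3×3-voxel cubes anchored at the
   array origin. A cube becomes a node if at least
   `min_gm_voxels_per_cube` (default 1) of its 27 voxels exceed
   `gm_voxel_threshold` (default 0.1). Each node's feature vector is its 27
   raw intensities in a fixed x-fastest order. On real whole-brain 2 mm maps
   this tiling yields several thousand nodes; the synthetic volumes used
   throughout the tests yield 150–400.
2. **Edges.** The similarity of two nodes is the maximum Pearson correlation
   between one cube's intensities and all orthogonal rotations of the other.
   On a 3×3×3 grid exactly 24 proper rotations act without interpolation;
   `cube_rotations(include_reflections = TRUE)` extends the set to all 48
   orthogonal symmetries. A vector with zero variance has correlation 0 by
   convention. Rotation maximization makes the similarity invariant to the
   relative orientation of cortical structure inside the two cubes.
3. **Thresholding.** The similarity matrix is binarized at a per-subject
   threshold controlled at FDR 5%: `estimate_null()` permutes the 27
   intensities of randomly drawn node pairs (default 100,000 pairs) to build
   the null distribution of the rotation-maximized similarity; each
   upper-triangle entry gets the one-sided empirical p-value
   `(1 + #{null >= v}) / (n_perm + 1)`, and Benjamini–Hochberg is applied
   over the subject's full edge family. Only high similarity counts as
   evidence of an edge (one-sided), and the null is re-estimated per subject
   (and, at the local scale, per region) rather than pooled.
4. **Small-worldness.** For the binarized graph, `small_worldness()` computes
   the mean Watts–Strogatz clustering coefficient (vertices of degree < 2
   contribute 0) and the characteristic path length (mean breadth-first
   distance over unordered pairs in the largest connected component, with
   `component_fraction` recorded so downstream analysis can filter
   fragmented networks). Twenty random reference networks with the same
   degree sequence are generated by Maslov–Sneppen double-edge swaps (10 ×
   |E| attempted swaps each); γ and λ are the clustering and path length
   normalized by the ensemble means, and σ = γ / λ. A reference ensemble
   with zero mean clustering or path length flags σ as undefined instead of
   dividing.
5. **Local scale.** Cube nodes are assigned to atlas regions by majority
   vote over their 27 voxel labels (background excluded; ties to the
   smallest region id — the rule is not dictated by the construction, so it
   is fixed and documented here). Networks are rebuilt with the identical
   procedure per intrinsic connectivity network (7 ICNs: DMN, CCN, SVN,
   DAN, LN, SMN, VN) and per individual region. Individual regions whose
   average node count across the whole cohort is below 30 are omitted from
   statistics (a region at exactly 30 is retained); the 7 ICN scopes are
   large by construction and are analysed unfiltered.
6. **Statistics.** Demographics use Welch's unequal-variance t (the
   fractional degrees of freedom printed in demographic tables identify this
   flavor) and a Yates-corrected chi-square for sex. The group comparison of
   σ is an ANCOVA controlling total GM volume; education is deliberately
   never entered as a covariate (covarying education against a trait
   difference invites spurious adjustment). σ–anhedonia coupling uses
   partial correlations controlling GM volume (controls) plus illness
   duration and antipsychotic dose (patients); the group difference of the
   coefficients is a z-test after Fisher's r-to-z, with the variance term
   `1/(n − 3 − k)` extended by the number of controlled covariates k (a
   documented choice; the classical formula has k = 0). Each test family —
   the 7 ICN ANCOVAs, the retained-region ANCOVAs, and the correlation
   comparisons per scale — is FDR-corrected separately. Results with
   corrected p in (0.05, 0.1] are tagged `"trend"` and never counted as
   significant.

All randomness is routed through per-stage seeds derived deterministically
from a master seed and the subject/region identifier, so a fixed
configuration reproduces every numeric output bit for bit.

## What the synthetic cohort emulates

No imaging data ship with the package; `generate_cohort()` produces a cohort
with the statistical structure the analysis needs:

* **Cohort structure.** Defaults mirror a schizophrenia case–control study:
  121 patients and 160 controls; physical anhedonia scale (PAS, 0–61) means
  21.5 ± 9.6 vs 12.4 ± 7.5; social anhedonia scale (SAS, 0–40) means
  16.4 ± 6.9 vs 8.9 ± 4.4 with SAS observed in only 77 patients and 104
  controls; age, education, sex ratios, illness duration and
  chlorpromazine-equivalent dose drawn to match the same table. All of it is
  configurable.
* **Volumes.** Each subject's GM map is a ball-shaped compartment of 3×3×3
  cubes on the 2 mm grid. Cube intensities are latent-factor fields: every
  cube sums a window of shared Gaussian factors along a ring ordered by
  atlas region, plus 10% voxel noise, and the intensities are affinely
  mapped into [0, 1] so the realized total GM volume matches the subject's
  drawn target within 5%. The default desk-scale grid is 30³ voxels (≈ 360
  nodes, ≥ 30 average nodes per ICN); most tests use 24³ (≈ 160 nodes).
  Absolute GM volumes at this scale cannot equal real-brain values, so the
  default volume targets preserve the published group ratio
  (585.8 / 600.0) and coefficients of variation instead.
* **Regularity → σ.** The subject-level `regularity` parameter sets the
  latent window width: narrow overlapping windows give a banded, lattice-like
  similarity topology (high clustering, long paths — high σ), windows
  spanning the whole ring make all cubes share one factor set (a near
  complete graph — σ = 1). The mapping is smooth and monotone; an earlier
  design in which regularity rewired a fixed-width neighborhood graph turned
  out to be threshold-cliffy and produced fragmenting, erratically high-σ
  networks, and was replaced. Expected σ grows approximately log-linearly
  with regularity over the stable operating range; draws are clipped to
  [0.05, 0.88] because the band graph fragments above ≈ 0.9 and σ becomes
  erratic. Group σ differences are planted as regularity differences
  (defaults 0.62 patients vs 0.72 controls, SD 0.15).
* **σ–SAS coupling.** SAS is generated as a linear function of
  `exp(2.4 × regularity)` — the generator's own log-linear link for expected
  σ — plus noise, never of realized σ. The induced Pearson correlation
  between constructed σ and SAS therefore approaches the configured target
  as the cohort grows (measured attenuation ≈ 0.92 at 24³, dominated by the
  irreducible network-construction noise), without any circular use of the
  network outcome. Coupling to raw regularity instead of its σ link was
  tried first and attenuated the realized correlation to ≈ 0.65 of target,
  because σ is convex in regularity.
* **What is not emulated.** No anatomy, no tissue-segmentation errors, no
  bias fields or motion, no spatial registration: the atlas is generated
  directly on the subject grid (multi-source breadth-first growth of
  contiguous regions, each mapped cyclically to one of the 7 ICNs).
  Passing tests therefore validate the pipeline's statistical behavior —
  null control, effect recovery, calibration of σ on reference graphs — not
  its robustness to real MRI artifacts.

## Numerical choices and degenerate inputs

* Empirical p-values use add-one smoothing, so the smallest attainable
  p is `1/(n_perm + 1)`; an FDR level below that empties the network rather
  than erroring.
* Zero-variance intensity vectors (flat cubes) have similarity 0 to
  everything, and a permutation null built from constant nodes is exactly 0.
* Disconnected graphs: path length is computed on the largest connected
  component — the standard convention for FDR-thresholded graphs — and
  `component_fraction` is reported alongside.
* Regions with fewer than 2 nodes, or whose thresholded network is edgeless,
  yield missing-value rows with an explicit status, never silent zeros.
* Graphs admitting no valid double-edge swap (e.g. a triangle) are their own
  degree-matched reference; a complete graph therefore has γ = λ = σ = 1
  exactly.
* The ANCOVA F is computed as the squared t of the group coefficient from
  the OLS fit (an algebraic identity), and the error df is recomputed from
  the actual model rather than copied from any published table.

## Problem sizes used by the tests

The acceptance-style checks run at desk scale, chosen so the whole suite
completes on one CPU: 24³-voxel volumes (≈ 160 nodes), permutation nulls of
1,200–20,000 pairs (the package default is 100,000), cohorts of 6 + 6 for
the 100-replicate type-I check and 77 + 104 (the SAS-complete sizes) for
the 20-replicate power check of the Fisher z comparison. The replicated
cohort experiments build their reference ensembles with a 5 × |E| swap
budget (≈ 3–4 successful swaps per edge, applied identically to every
subject; the σ-calibration checks keep the full 10 × |E| default). At the power
check's stated conditions (target r = 0.4 in controls only, two-sided
α = 0.05) the ideal power is 0.78, so observed empirical power near 0.7 is
the expected behavior, not a defect of the construction.

## Known limitations

* The rotation set is exact only for the 24 (or 48) orthogonal cube
  symmetries; fractional-angle rotations would require interpolation and are
  deliberately out of scope.
* σ from 20 references carries ensemble noise of a few percent for sparse
  graphs; increase `n_random` when comparing σ values within a subject.
* The synthetic σ range (≈ 1.5–5 at the defaults) is wider than what
  whole-brain GM networks typically show (≈ 1.2–1.4); the generator aims for
  controllable, well-separated effects, not for matching the absolute σ
  scale of real cohorts.
* Only binary undirected networks and the σ small-world index are
  implemented; weighted variants and ω-style indices are not.
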