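# gmnet — single-subject grey matter networks and their small-worldness

`gmnet` is an R package plus a staged analysis workflow for studying the
topology of **single-subject grey matter (GM) structural covariance
networks** and how it differs between a patient and a control group — the
kind of question asked in schizophrenia imaging, where anhedonia severity is
related to GM network properties at whole-brain and regional scales.

The pipeline consumes segmented GM partial-volume maps (NIfTI, isotropic
2 mm) and an atlas on the same grid:

* **Nodes** are non-overlapping 3×3×3-voxel cubes with sufficient grey
  matter; each carries its 27 raw intensities.
* **Edges** come from the similarity matrix `S[i, j] = max_R cor(x_i, R x_j)`,
  the Pearson correlation maximized over the 24 orthogonal rotations `R` of
  the cube, binarized at a per-subject permutation-null threshold controlled
  at **FDR 5%** (Benjamini–Hochberg over the subject's edge family).
* **Small-worldness** is `σ = γ / λ`, with `γ = CC / ⟨CC_rand⟩` and
  `λ = L / ⟨L_rand⟩` normalized by the mean over 20 degree-matched random
  reference networks (Maslov–Sneppen rewiring). `CC` is the mean
  Watts–Strogatz clustering coefficient and `L` the characteristic path
  length on the largest connected component.
* **Local scale**: the identical construction per intrinsic connectivity
  network (7 ICNs) and per atlas region, with regions under 30 average nodes
  across the cohort omitted.
* **Statistics**: Welch t and Yates χ² demographics; ANCOVA on σ controlling
  total GM volume; partial correlations of σ with the Chapman physical and
  social anhedonia scales (PAS 0–61, SAS 0–40) per group; Fisher r-to-z
  comparison of the group coefficients; FDR correction per test family.

Because clinical MRI data cannot ship with the package, a first-class
**synthetic cohort generator** emulates the study inputs: two groups with
configurable latent "regularity" (which monotonically controls the expected
network σ), covariate tables matching the published demographics structure
(121/160 subjects, SAS observed in 77/104), and anhedonia scores coupled to
the latent trait so that a target σ–SAS correlation is induced — never
imposed — in a designated group. Every stage is a pure function of its
inputs and a seed.

## Worked example

```r
library(gmnet)

# a small two-group cohort on a 24^3-voxel grid (~160 cube nodes/subject)
cfg <- simulation_config(n_patients = 4, n_controls = 4,
                         volume_shape = c(24, 24, 24), seed = 1)
cohort <- generate_cohort(cfg)

# one subject's network and small-worldness
net <- construct_gm_network(cohort$volumes[[1]], n_perm = 5000, seed = 1)
net$metrics
#> <network_metrics> n=160, |E|=4459, CC=0.740, L=1.834, gamma=2.066, lambda=1.112, sigma=1.858 (ok)
```

A subject at the patient-group default regularity gives σ ≈ 1.9 here: the
network is twice as clustered as its degree-matched references
(γ ≈ 2.1) at only a modestly longer path length (λ ≈ 1.1) — a small-world
topology. Increasing the subject's regularity raises σ; at regularity 0 the
construction collapses to a near-complete graph and σ ≈ 1.

The staged workflow does this for a whole cohort and runs the statistics:

```sh
Rscript analysis/01_simulate_cohort.R     # cohort, atlas, volumes -> results/cohort/
Rscript analysis/02_construct_networks.R  # edge lists + global/local sigma tables
Rscript analysis/03_group_statistics.R    # demographics, ANCOVA, Fisher r-to-z tables
```

Stage 3 prints the demographics table (Welch t per covariate, Yates χ² for
sex), the per-scope ANCOVA of σ controlling GM volume with uncorrected and
FDR-corrected p, and the per-scale Fisher z comparison of the two groups'
σ–anhedonia partial correlations. `run_pipeline()` wraps the same steps in
one call with a manifest of checksums for reproducibility.

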