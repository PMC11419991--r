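---
title: "Discovering connectivity archetypes and degenerate brain-behavior coding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering connectivity archetypes and degenerate brain-behavior coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somarch)
```

## The problem

Resting-state functional connectivity (RSFC) predicts behavior unreliably:
the same trait is sometimes associated with one connectivity pattern,
sometimes with another, and often with none. One explanation is *degeneracy*
in the brain-behavior code — structurally different connectivity
configurations producing the same behavioral outcome. A linear model that
regresses a trait on edges or networks cannot see degeneracy by
construction: two groups with opposite connectivity but identical scores
cancel each other out.

`somarch` implements a clustering-first alternative. Per-run connectomes are
clustered into a small set of *archetypes* — characteristic connectivity
profiles arranged on a 2D self-organizing-map (SOM) grid — and behavior is
then analyzed as a function of the grid coordinates (X, Y, and their
interaction) rather than of individual edges. A behavior coded by the X:Y
interaction with indistinguishable means in two connectionally distant cells
is exactly the degenerate pattern a linear edgewise model misses.

## Pipeline overview

1. **Features** (`reduce_dataset()`): each symmetric connectome (Fisher-z
   units) is reduced to its strictly-lower-triangular vector, the stack of
   vectors goes through PCA (centered, not feature-scaled — edges already
   share the z scale), and the number of retained components is chosen by
   Horn's parallel analysis. Retained scores are z-scored per component so
   the SOM sees commensurate axes.
2. **SOM** (`som_fit()`): an online-trained rectangular grid of neurons,
   each holding a weight vector in feature space. Each presentation moves
   the best matching unit (BMU) and its grid neighbors toward the input
   with a Gaussian neighborhood over Euclidean grid distance.
3. **Stability tuning** (`tune_som()`): grid size is screened at a fixed
   epoch count, then epochs are swept for the surviving grids; every
   configuration is scored by the mean pairwise agreement (ARI and AMI) of
   repeated, independently seeded trainings. The selected configuration is
   the argmax with parsimony tie-breaks (fewer epochs, then smaller grid).
4. **Consensus** (`consensus_cluster()`): many SOMs are trained at the
   chosen configuration; the co-assignment frequency of each observation
   pair forms the consensus matrix; average-linkage hierarchical clustering
   on one-minus-consensus, cut to the grid size, gives the final partition.
   The *representative run* — the ensemble member agreeing best with the
   consensus — supplies the grid coordinates used downstream.
5. **Null model** (`consistency_test()`): the mean number of distinct
   archetypes per subject is compared with a Monte Carlo null in which every
   run receives an i.i.d. uniform label. With K clusters and R runs the
   null mean is analytic, `K(1 - (1 - 1/K)^R)`; for K = R = 4 that is
   2.7344.
6. **Association battery** (`associate_behaviors()`): behaviors are Box-Cox
   transformed and rescaled to [1, 100], then tested against the grid
   coordinates with a two-way ANOVA (Type-II sums of squares for unbalanced
   cells) *and* a linear mixed model with a subject random intercept — a
   deliberate multiverse pair: the ANOVA treats each run as an observation,
   the LME guards against the pseudo-replication this implies. Post-hoc
   Welch tests compare cells differing in exactly one coordinate, corrected
   by Benjamini-Hochberg and Bonferroni within each behavior's family;
   battery-wide corrections tier every term as uncorrected (p < 0.001),
   FDR-surviving, or Bonferroni-surviving.
7. **Degeneracy report** (`degeneracy_report()`): each behavior is
   classified by its most significant surviving term (X-coded, Y-coded,
   interaction-coded, uncoded). For interaction-coded behaviors the report
   lists *degenerate pairs*: archetype pairs whose score means do not
   differ (Welch p ≥ 0.05) yet whose mean connectomes are at least the
   median pairwise distance apart.

## The synthetic-data generator

Real multi-site resting-state datasets of the relevant size are
access-restricted, so validation runs on synthetic studies with planted
ground truth (`simulate_study()`). The generator emulates the *structure*
of such data:

- S subjects × R runs of N×N symmetric Fisher-z connectomes;
- K = Dx·Dy archetype templates on a 2D grid: a constant baseline plus
  `(x-1)·block_effect` on edges within an "anterior" node block and
  `(y-1)·block_effect` within a "posterior" block (first and second
  `ceiling(N/3)` nodes; the remainder is unstructured background);
- each subject draws a modal archetype uniformly; each run keeps it with
  probability ρ (`run_consistency`) and is otherwise redrawn uniformly over
  the *whole* grid, so the empirical run consistency converges to
  ρ + (1-ρ)/K;
- i.i.d. Gaussian edge noise of standard deviation `noise_sd`;
- one score per subject and behavior: `d·σ·g(x, y)` plus N(0, σ²) noise,
  where `g` indicates the last X level (X-coded), last Y level (Y-coded),
  or the XOR of the two (interaction-coded — the degenerate pattern in
  which the two off-diagonal cells share a high outcome); at σ = 0 the
  pattern is kept with amplitude `d` so noiseless fixtures remain
  informative.

Reference conditions (the package defaults) are 200 subjects × 4 runs, 90
nodes, a 2×2 grid, `block_effect` 0.5 z-units over `noise_sd` 0.3 — a
block-to-noise ratio of 1.67, i.e. a clearly resolvable but not trivial
group difference on the Fisher-z scale — ρ = 0.8, behavioral effect d = 0.8
at σ = 1. Under these conditions the consensus partition recovers the
planted archetypes with ARI ≈ 1 and the X-margin difference matrix
reproduces the planted 0.5 z-unit anterior effect.

What the generator deliberately does *not* emulate: spatial autocorrelation
of edge noise, heavy-tailed or motion-contaminated edges, unequal archetype
prevalences, site effects, or psychometric distributions of any particular
instrument. Passing tests therefore demonstrate correctness of the
*procedure* under clean planted structure, not robustness to every artifact
of real fMRI data.

## Numerical and design choices

- **SOM schedules.** Learning rate decays linearly 0.5 → 0.01 and the
  Gaussian neighborhood radius `max(Dx, Dy)/2 → 0.5` across epochs; one
  epoch is one seeded shuffled pass over all observations; updates are
  online; topology is rectangular with Euclidean grid distance. These are
  deliberately plain, fully specified choices: the consensus layer absorbs
  run-to-run variability by construction, so the procedure's claims do not
  depend on a particular toolbox's defaults. Training is single-threaded
  and bit-reproducible under a fixed seed.
- **Label alignment.** SOM grid axes are exchangeable between runs, so
  coordinates from different runs cannot be averaged. Consensus uses only
  label-free co-assignment; coordinates enter the association stage only
  through the single representative run. Consequently the planted "X" axis
  may surface as the recovered Y axis (or with flipped levels) —
  everything downstream is invariant to this, and validation checks
  effects on whichever margin aligns with the planted block.
- **ARI/AMI conventions.** ARI is computed in an integer-scaled form so
  rational results (like the textbook −0.5 case) are exact. AMI uses the
  permutation-model expected MI and arithmetic-mean entropy normalization.
  Two single-cluster partitions compare as 1; single- vs multi-cluster as
  0 (the 0/0 conventions).
- **Stability on unstructured data.** Repeated SOM runs cluster the *same*
  data realization, so even pure-noise data yields pairwise ARI well above
  zero (the chance correction zeroes only independent partitions);
  stability values are meaningful as a contrast between configurations,
  not as absolute chance-level scores.
- **Parallel analysis.** The null is standard-normal data of identical
  shape; each of `n_sim` Monte Carlo datasets contributes one
  correlation-matrix eigenvalue per rank, compared rank-by-rank at the
  95th percentile; retention stops at the first non-exceeding rank (a
  non-contiguous retained set is uninterpretable). Null quantiles depend
  only on the data shape and can be precomputed once
  (`pa_null_quantiles()`) and shared across same-shape datasets. With more
  features than observations, eigenvalues are computed from the n×n Gram
  matrix of the standardized data.
- **Hierarchical cut.** The consensus dendrogram is cut to exactly
  `Dx·Dy` clusters (not at a height); a cut yielding fewer distinct
  clusters warns.
- **Sums of squares.** Type II by default for unbalanced cells, Type III
  available via `ss_type = 3`. Degenerate inputs are handled explicitly:
  constant scores return F = 0, p = 1; single-level factors report their
  terms as missing.
- **Degenerate-pair definition.** The connectivity threshold (at least the
  median pairwise archetype distance) and the outcome side (`side =
  "high"`: both cell means above the behavior's grand mean) are package
  definitions. The high-side default singles out pairs sharing an
  *elevated* outcome — the canonical degeneracy readout; `side = "low"`
  and `"both"` cover the mirrored and unrestricted variants, which on an
  XOR-coded 2×2 grid would also report the low-scoring diagonal pair.
- **Behavior across runs.** Behavioral scores are per subject and
  replicated across the subject's runs when aligned to observations
  (`mode = "runs"`); `mode = "subjects"` instead uses one row per subject
  at the modal cell. Both are exposed because either alignment is
  defensible; the LME arm makes the replicated mode statistically safe.

## Problem sizes used in validation

The test suite and the acceptance script run deliberately scaled-down
study sizes chosen to exercise every claim at desk scale: stability
searches with 3–20 repeats rather than hundreds, consensus ensembles of
8–100 runs, parallel analysis with 100–1,000 Monte Carlo datasets, 10
recovery seeds at the reference 200×4×90 conditions, 1,000 null ANOVA
simulations, and 50–100 planted-degeneracy seeds. Full-fidelity settings
(200 stability repeats, 10,000 parallel-analysis simulations) remain
available through `pipeline_config()`.

## Known limitations

- A 2×2 grid yields coarse archetypes; larger grids are supported but less
  stable, and the stability search will usually reject them — that is the
  intended behavior, not a bug.
- The representative-run coordinates inherit one run's arbitrary axis
  orientation; cross-study comparisons of "the X axis" are meaningless
  without an alignment step.
- The degeneracy report is descriptive: it flags candidate pairs at fixed
  thresholds and performs no formal equivalence test.
- Empirical p-values from the consistency null are bounded below by
  1/n_sims and reported as such.
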