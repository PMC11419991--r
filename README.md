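# somarch

Functional-connectivity **archetypes** via stability-tuned self-organizing
maps, and detection of **degenerate brain-behavior coding**.

## What problem does this solve?

Resting-state functional connectivity (RSFC) is a popular but unreliable
predictor of behavior. One reason may be *degeneracy*: structurally
different connectivity configurations that produce the same behavioral
outcome. Linear edgewise models cannot detect degeneracy — two groups with
opposite connectivity but identical scores cancel out.

`somarch` takes a clustering-first route, for researchers analyzing
multi-run connectome studies (subjects × runs × N×N connectivity matrices
plus a behavioral score table):

1. Each run's connectome (Fisher-z, `z = atanh(r)`) is vectorized
   (strict lower triangle, length N(N−1)/2), reduced by PCA, and the
   retained dimensionality is chosen by Horn's **parallel analysis**: keep
   the leading components whose correlation-matrix eigenvalues exceed the
   95th percentile of eigenvalues from shape-matched standard-normal null
   data.
2. A **self-organizing map** (from-scratch, online training, Gaussian
   neighborhood on a rectangular grid) clusters the reduced profiles; grid
   size and epochs are tuned by *clustering stability* — mean pairwise
   adjusted Rand index (ARI) and adjusted mutual information (AMI) across
   repeated seeded trainings.
3. **Consensus clustering** aggregates 100 SOM runs: the co-assignment
   matrix `M[i,j] = P(i, j share a cluster)` is cut by average-linkage
   hierarchical clustering on `1 − M`; the ensemble run most similar to
   the consensus supplies each archetype's grid coordinate (X, Y).
4. Within-subject assignment consistency is tested against a Monte Carlo
   null with i.i.d. labels, whose analytic mean unique-clusters-per-subject
   is `K(1 − (1 − 1/K)^R)`.
5. Behaviors (Box-Cox transformed, rescaled to [1, 100]) are tested
   against the grid coordinates by two-way ANOVA (Type-II SS) **and** a
   subject-random-intercept mixed model, with restricted post-hoc
   comparisons and FDR/Bonferroni tiers. Interaction-coded behaviors whose
   scores are indistinguishable across two connectionally distant
   archetypes are flagged as **degenerate pairs**.

A synthetic-study generator with planted grid archetypes and known
behavioral coding (`simulate_study()`) provides ground truth for
validation end to end.

## Worked example

```r
library(somarch)

cfg   <- synth_config(n_subjects = 60, n_runs = 4, n_nodes = 40, seed = 3)
study <- simulate_study(cfg)   # connectomes + behaviors + planted truth
study$connectomes
#> <connectome_set> 240 observations, 40 x 40 nodes, 60 subjects

red <- reduce_dataset(study$connectomes, n_sim = 200, seed = 103)
red
#> <reduced_features> 240 observations, 2 retained component(s)

cons <- consensus_cluster(red, dims = c(2, 2), epochs = 200,
                          n_runs = 50, seed = 203)
adjusted_rand_index(cons$final_labels, study$truth$assignments$cell)
#> [1] 1

null <- random_assignment_null(60, 4, 4, n_sims = 10000, seed = 303)
consistency_test(cons$assignment, null)
#> <consistency_report> observed mean unique clusters 1.533 vs null 2.734
#> (sd 0.0844), p < 1/10000

assoc <- associate_behaviors(preprocess_behaviors(study$behavior)$scores,
                             cons$assignment)
degeneracy_report(assoc, summarize_archetypes(study$connectomes,
                                              cons$assignment))
#> <degeneracy_report> tier 'fdr', side 'high'
#> # A tibble: 4 x 4
#>   behavior coding            term    p.value
#> 1 beh_null uncoded           <NA>  NA
#> 2 beh_x    X-coded           X      5.75e- 7
#> 3 beh_xor  interaction-coded X:Y    2.26e- 5
#> 4 beh_y    Y-coded           Y      4.77e-13
#> degenerate pairs:
#>   behavior    x1    y1    x2    y2 p_equal distance median_distance
#> 1 beh_xor      1     2     2     1   0.177     9.90            7.22
```

Reading the output: the two retained components carry the planted 2×2 grid;
the consensus partition matches the planted archetypes exactly (ARI 1);
subjects' runs are far more consistent than the random-assignment null
(1.53 vs 2.73 mean unique clusters, empirical p below 1/10,000); each
planted behavior is classified by its true coding; and the XOR-coded
behavior yields one degenerate pair — archetypes (1,2) and (2,1) share the
same elevated score (equality p = 0.18) while their mean connectomes are
9.9 z-units apart, above the 7.2 median pairwise distance. That pair *is*
the degeneracy signature.

The full pipeline (preprocessing → reduction → tuning → consensus → null →
association → degeneracy, with a deterministic JSON run report) is
available as `run_pipeline()` / `run_pipeline_file()`; see the
`archetype-methods` vignette for the model, its assumptions, and every
numerical choice.

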