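# megnet

Simulation-backed effective-connectivity network analysis for MEG.

## What it does

Magnetoencephalography studies of clinical populations often summarize a
recording as a *directed brain network*: band-limited sensor data are
projected to source space, source pairs whose activity is correlated are
connected, Granger causality orients the connections, and graph-theoretic
summaries of the result are compared between groups and correlated with
clinical scores. `megnet` implements that full chain as a tested,
reusable R pipeline:

- **Preprocessing** — DC removal, 50 Hz notch, zero-phase Butterworth
  band-pass into the five canonical bands (delta 1–4 Hz … gamma
  30–90 Hz), epoching on the 90–180 ms post-stimulus window with
  amplitude-based artifact rejection.
- **Source reconstruction** — unit-gain LCMV beamformer
  `w = (C+λI)⁻¹g / gᵀ(C+λI)⁻¹g` on a volumetric grid, with sub-10 mm
  voxel merging.
- **Connectivity** — Pearson correlation `R(Xa,Xb) = C(Xa,Xb)/(S_Xa S_Xb)`
  thresholded via its t value `Tp = R·√((K−2)/(1−R²))` at p < 0.01,
  edge direction by multivariate Granger causality
  (`GC(a→b) = ln(σ²_reduced/σ²_full)`, F-tested), excitatory/inhibitory
  signs and driver/driven node roles.
- **Graph metrics** — degree D, strength S, characteristic path length L,
  clustering coefficient C.
- **Group statistics** — Fisher's exact test on directed-pattern
  prevalence, pooled t-tests with Bonferroni (0.05/5 = 0.01 and
  0.05/20 = 0.0025) and Benjamini–Hochberg FDR, Spearman correlations
  against clinical covariates (HAM-A, HAM-D, headache history…).
- **Synthetic cohorts** — stable MVAR source networks with a planted
  directed PFC→TL coupling whose prevalence differs between groups, a
  distance-kernel forward model, sensor noise at a requested SNR, and
  Gaussian-copula clinical covariates with a chosen Spearman correlation
  to network strength, so every stage of the pipeline can be validated
  against ground truth.

Audience: methods researchers who need a transparent, fully seeded
reference implementation of correlation-plus-Granger network analysis,
and anyone who wants to stress-test such a pipeline on data where the
right answer is known.

## Worked example

```r
library(megnet)

net <- example_network()                  # 8 sources, planted PFC -> TL edge
cohort <- example_cohort_spec(seed = 42,  # 24 patients + 24 controls
                              pattern_prevalence_patients = 19/24,
                              pattern_prevalence_controls = 8/24,
                              clinical_rho = -0.5)
recs <- generate_cohort(cohort, net)
out <- run_pipeline(recs, example_pipeline_config())

out$result
#> <cohort result>
#>   band gamma: Fisher p = 8.828e-05
#>   0/4 metric tests Bonferroni-significant (threshold 0.0025)

out$result$prevalence$gamma$table
#>         present absent
#> patient      21      3
#> control       7     17

subset(out$result$clinical_correlations,
       covariate == "ham_a" & parameter == "strength_S")
#>     band covariate  parameter        rho          p  n
#> 18 gamma     ham_a strength_S -0.4547826 0.02556158 24
```

The Fisher p-value tests the planted group difference in PFC→TL pattern
prevalence: here the pipeline detected the pattern in 21/24 patients vs
7/24 controls, a significant contrast (p ≈ 8.8e-5). No graph metric
differs between the groups — the generator planted a prevalence
contrast, not a metric contrast — and the recovered Spearman correlation
between HAM-A and network strength S in patients (−0.45) matches the
planted −0.5 in sign and closely in size.

Single-subject building blocks are exported too (`simulate_mvar`,
`lcmv_weights`, `scan_grid`, `merge_close_voxels`,
`pairwise_correlation`, `t_threshold`, `granger_direction`,
`graph_metrics`, `fisher_exact_2x2`, `fdr_bh`, `spearman_cor`, …), and
`inst/scripts/run-pipeline.R` is a thin command-line wrapper over a YAML
config.

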