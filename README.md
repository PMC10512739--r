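# shvote

Stable hierarchical voting (SHV) for identifying discriminative voxels in
multi-subject fMRI decoding studies.

## The problem

In small-sample fMRI experiments — e.g. aversive-conditioning paradigms
where a visual cue (CS+) predicts a noxious outcome and another (CS−)
does not — one wants the set of voxels whose activity discriminates the
two conditions, not just a classifier. With tens of thousands of
correlated, noisy voxels and a few dozen trials per subject, many
different weight maps predict equally well, so sparse decoders are
notoriously unstable: rerunning the fit on a perturbed sample selects
different voxels, and per-subject maps rarely agree.

`shvote` attacks this with three ingredients:

1. **Data-driven parcellation.** In-mask voxels are grouped into
   `N_C` clusters by normalized-cut spectral clustering of an affinity
   graph combining signal correlation with a spatial kernel,
   `A(v1,v2) = |corr(x_v1, x_v2)| * exp(-dist(v1,v2)^2 / sigma_d^2)`.
   Features are averaged within clusters, shrinking the problem from
   voxels to clusters.

2. **Groupwise mixed l1/l2 (group-lasso) logistic regression.** All
   subjects are fitted jointly; the weight matrix `W` (clusters x
   subjects) is penalized by `lambda * sum_j ||W(j,:)||_2`, so whole
   clusters are kept or discarded *consistently across subjects* while
   per-subject weights inside a kept cluster remain free:

   ```
   min_{W,b}  sum_i sum_t log(1 + exp(-y_i(t) (D_i(t,:) W(:,i) + b_i)))
              + lambda * sum_j ||W(j,:)||_2
   ```

   The solver is a monotone accelerated proximal-gradient (FISTA)
   method with backtracking, compiled via RcppArmadillo.

3. **Stability selection with quality-controlled hierarchical voting.**
   An outer loop draws `N_K` constrained 3x3x3-block subsamples of
   voxels; an inner loop fits the model on `N_L` stratified trial
   subsamples and scores held-out accuracy. Per subject, only the top
   `alpha_K` fraction of outer loops by verification accuracy vote.
   Votes aggregate hierarchically: per-cluster score vectors
   `s(j) = mean_l |W_l(j,i)|`, top-`N_sel` selectors, groupwise cluster
   vote rates `phi_C`, per-voxel sampling-conditional vote rates
   `phi~_V`, and finally the **effective vote ratio**
   `EVR(m) = phi~_V(m) * phi_C(cluster(m))` — the per-voxel output map.

Selection stability across subjects is quantified by the
chance-corrected pairwise overlap
`O(S1,S2) = | |S1 ∩ S2| - |S1||S2|/N_V | / max(|S1|,|S2|)`.

## Worked example

The package ships a planted-signal benchmark generator: atlas-like
contiguous regions on a 3D grid, three discriminative regions shared by
all subjects whose uniform base values combine linearly into the class
signal, per-subject interference regions, and unit Gaussian noise.

```r
library(shvote)

ds  <- generate_dataset(synthetic_spec("reduced", seed = 1))
ds
#> <synthetic_dataset> reduced scale: 9 subjects, grid 20x22x20
#> (8800 voxels, 40 regions), planted regions {11, 15, 21}

cfg <- benchmark_config(seed = 1)           # N_K=50, N_L=10, N_sel=4 ...
sel <- select_lambda(ds$subjects, ds$mask, ds$parcellation_truth, cfg)
sel$r_bar
#> # A tibble: 3 x 2
#>   lambda r_bar
#>    <dbl> <dbl>
#> 1   1.97 0.819
#> 2   7.88 0.847
#> 3  19.7  0.827

res <- sel$result
res
#> <shv_result> group method, lambda = 7.876: 9 subjects, 50 loops,
#> 8 clusters voted, mean qualified accuracy 0.847

dplyr::arrange(tidy(res), dplyr::desc(vote_rate))
#> # A tibble: 40 x 2
#>   cluster_id vote_rate
#>        <int>     <dbl>
#> 1         15     1
#> 2         21     1
#> 3         11     0.889
#> 4         28     0.333
#> 5         30     0.333
#> # i 35 more rows

mean_overlap(selected_voxels(res))
#> [1] 0.4802843
```

The penalty with the best qualified verification accuracy (0.847) is
kept; under it the three planted clusters (11, 15, 21) receive the
highest groupwise vote rates — every selector of every subject marks
15 and 21, and 8 of 9 subjects mark 11 — while interference clusters
trail well below. Their voxels carry the largest EVR values
(`res$mean_evr`, writable as a NIfTI map with `write_brain_map()`),
and the selections agree across subjects far above chance
(chance-corrected overlap 0.48). Fitting each subject separately
(`method = "single"`) on the same sampling plans drops the mean
overlap to about 0.32 across benchmark seeds — the stability gain of
the group penalty.

A thin command-line interface wraps the same functions:

```sh
Rscript exec/shv.R simulate --out sim/ --scale reduced --seed 1
Rscript exec/shv.R run --data sim/ --out run/ --lambda 8
Rscript exec/shv.R evaluate --run-dir run/ --out overlap.csv
```

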