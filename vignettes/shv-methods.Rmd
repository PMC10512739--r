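---
title: "Stable hierarchical voting: model, design choices, and what the benchmark shows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stable hierarchical voting: model, design choices, and what the benchmark shows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shvote)
```

## The model

`shvote` estimates, for every voxel of a multi-subject two-condition
fMRI study, how consistently that voxel participates in a sparse
decoding model. Three layers are stacked:

**Parcellation.** Voxels are clustered by normalized-cut spectral
clustering of the affinity
$A(v_1,v_2) = |\mathrm{corr}(x_{v_1}, x_{v_2})|\,
e^{-\mathrm{dist}(v_1,v_2)^2/\sigma_d^2}$, computed on a user-chosen
data matrix. Cluster-averaged features reduce the unknowns from
$N_V$ voxels to $N_C$ clusters, comparable to the trial count.

**Groupwise sparse logistic model.** With cluster features $D^i$
(trials $\times$ clusters) and labels $y^i \in \{\pm 1\}$ for subject
$i$, the weight matrix $W \in \mathbb{R}^{N_C \times N_S}$ and
intercepts $b_i$ minimize

$$\sum_{i=1}^{N_S}\sum_{t} \log\!\big(1 + e^{-y^i(t)\,(D^i(t,:)W(:,i) + b_i)}\big)
  \;+\; \lambda \sum_{j=1}^{N_C} \lVert W(j,:)\rVert_2 .$$

The row-wise $\ell_2$ norm couples the subjects: a cluster is either
active for everyone (with subject-specific weights) or zeroed for
everyone, which is the formal expression of the assumption that
discriminative regions overlap across subjects. With $N_S = 1$ the
penalty reduces to the lasso and the model to the per-subject
"alternative" baseline.

**Stability voting.** $N_K$ outer loops draw whole $3^3$-voxel blocks
until a fraction $\alpha_{col}$ of voxels is covered (blocks respect
the local correlation structure that independent voxel draws would
break); $N_L$ inner loops split trials $\alpha_{row}/1-\alpha_{row}$
with class stratification, fit the model, and score held-out accuracy.
Per subject only the top $\alpha_K N_K$ loops by accuracy vote
(uniform spatial sampling frequently yields uninformative voxel sets;
the accuracy filter discards them). Votes are aggregated as: score
vector $s_{i,k}(j) = \tfrac1{N_L}\sum_l |W_l(j,i)|$; top-$N_{sel}$
selector $\pi(\cdot, N_{sel})$ marking only strictly positive entries;
cluster vote rate
$\phi^C = \tfrac1{N_S}\sum_i \pi\big(\tfrac1{N_i}\sum_k \pi(s_{i,k}),\,N_{sel}\big)$;
per-voxel rate $\tilde\phi^V_i(m)$ = (loops where $m$ was sampled and
its cluster selected) / (loops where $m$ was sampled); and the
effective vote ratio $\phi^V_i(m) = \tilde\phi^V_i(m)\,\phi^C(j)$,
$m \in g_j$. The penalty $\lambda$ is chosen to maximize
$\bar R = \tfrac1{N_S}\sum_i \tfrac1{N_i}\sum_k R^{test}_{i,k}$.

Selection stability across subjects is summarized by the
chance-corrected mean pairwise overlap
$O(S_1,S_2) = \big|\,|S_1\cap S_2| - |S_1||S_2|/N_V\,\big| /
\max(|S_1|,|S_2|)$ of the nonzero-EVR voxel sets.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `sigma_d` | distance kernel radius (voxels) | 3 | neighbourhood of strong BOLD correlation |
| `support_radius` | affinity cutoff | `3*sigma_d` | kernel $< e^{-9}$ beyond it; keeps the graph sparse |
| `n_k`, `n_l` | outer/inner loops | 200 / 20 | real-data settings; benchmark preset 50 / 10 |
| `alpha_col` | voxel fraction per loop | 0.01 | real-data setting; 0.05 in the benchmark preset |
| `alpha_row` | training-trial fraction | 0.9 | leaves a small stratified verification set |
| `alpha_k` | qualified-loop fraction | 0.3 | the quality-control ratio used throughout |
| `n_sel` | clusters per selector | 15 | study-specific; 4 in the benchmark preset |
| `block_size` | voxel sampling blocks | 3×3×3 | matches local correlation scale |
| `lambda_grid` | penalty candidates | `{0.05, 0.2, 0.5}·λ_max` | spans sparse to nearly-unpenalized; λ_max computed from the full data |
| `tol`, `max_iter` | solver stopping | 1e-6, 2000 | relative objective change of the convex fit |

## Numerical and design choices

* **Solver.** The objective is convex but non-smooth; we use monotone
  FISTA with backtracking (compiled, RcppArmadillo) with intercepts
  excluded from the proximal step (they are never penalized). The
  iterate starts at $W=0$, $b_i = \log(n^+_i/n^-_i)$ — the exact
  optimum of the intercept-only model — which also makes the
  $\lambda \ge \lambda_{max}$ limit exact: the solver returns $W = 0$
  identically. The recorded objective trace is non-increasing by
  construction (rejected steps restart the momentum).
* **Feature scaling.** Cluster features are z-scored per subject on
  the training trials of each split; verification trials reuse the
  training moments. This keeps one $\lambda$ comparable across
  subsamples and subjects.
* **Affinity cues.** The correlation term is computed on whatever
  matrix the user supplies — raw time series, trial features, or
  their row-wise concatenation after per-source z-scoring
  (`combined_group_data()`), the default recommendation, so both cues
  enter through one correlation.
* **Ties and degenerate cases.** Top-$N$ selection breaks ties toward
  the lower cluster id; a selector never marks a zero score; clusters
  with no sampled voxel in a loop are dropped from that fit and score
  zero; a voxel never sampled in a qualified loop has vote rate 0
  (no evidence, conservative); qualified-loop ties break by loop
  order; penalty ties go to the larger (sparser) $\lambda$.
* **Sampling plans.** All randomness of a run is drawn up-front from
  the master seed into an explicit plan: per-loop voxel blocks shared
  by all subjects (the joint fit needs a common cluster support) and
  per-subject stratified trial splits. Penalty candidates and the
  group/single methods therefore see *identical* plans (common random
  numbers), which sharpens both the $\bar R$ comparison and the
  group-vs-single stability comparison.
* **Spectral clustering.** Symmetric normalized affinity, dense
  eigendecomposition up to 1500 voxels, Lanczos (ARPACK) beyond;
  Ng–Jordan–Weiss row normalization; k-means with 10 restarts under a
  fixed seed. Graphs with more connected components than requested
  clusters raise an error suggesting a larger support radius. Spatial
  contiguity is encouraged by the distance kernel but not enforced.
* **Indexing.** All voxel and cluster indices are 1-based, in the
  mask's column-major linear order; NIfTI affines are carried through
  I/O but never used for resampling (inputs are assumed co-registered).

## The synthetic benchmark

The generator plants a known answer in data whose difficulty mimics a
small-sample whole-brain study. A full 3D grid is partitioned into
contiguous atlas-like regions (balanced region growing from spread-out
seeds — a synthetic stand-in for an anatomical template). Three
regions, shared by all subjects, carry uniform base values
$M_j \sim U(0,1)$ per trial; their weighted sum
$y_1 = \sum_j W^{init}_j \alpha^i_j M_j$ (weights $\{1,1,-2\}$ scaled
per subject by $\alpha \sim U(0.5,1.5)$) determines the label: class
+1 trials are rejection-sampled into the top 40% of the unconditional
$y_1$ distribution, class −1 into the bottom 40% (thresholds from
$10^5$ pilot Monte-Carlo draws). Each subject additionally gets
consecutive interference regions (shifted per subject, so neighbours
overlap but differ) whose base value must fall in the top/bottom 80%
of $U(0,1)$ for class +1/−1 — exact uniform quantiles, so those draws
are taken from the truncated uniform directly, which is
distributionally identical to rejection and faster. Region voxels all
share the trial's base value; everything is then immersed in unit
Gaussian noise (non-region voxels are pure noise, drawn once).

Two properties matter. First, by construction the classes are
perfectly separable by a threshold on $y_1$, but *no single region*
separates them — the signal is genuinely distributed. Second, the
80% rule leaves each interference region with a moderate label
correlation (conditional means 0.6 vs 0.4 of $U(0,1)$), so
interference regions are honest decoys that a per-subject sparse fit
happily selects; only their inconsistency across subjects (different
regions per subject) lets the group penalty reject them.

At full scale the defaults mirror the motivating study (53×63×52 grid,
116 regions, regions {32, 44, 62} planted, 15 interference regions per
subject at ids $72{+}3i \ldots 86{+}3i$, 20 trials per class). The
`"reduced"` scale keeps the identical structure at desk size —
20×22×20 grid (8,800 voxels), 40 regions of ≈220 voxels, planted
regions {11, 15, 21} at the same relative positions, 5 interference
regions per subject at $24{+}i \ldots 28{+}i$, 9 subjects — so a
benchmark run with `benchmark_config()` (50 outer loops, 10 inner
loops, $\alpha_{col} = 0.05$, $N_{sel} = 4$, 3-point penalty grid)
completes in well under a minute per penalty candidate on one CPU.
These problem sizes are the package's chosen benchmark conditions; the
tests and the acceptance script run them as-is.

What the generator does **not** emulate: hemodynamic temporal
structure, spatially autocorrelated noise beyond the region blocks,
inter-subject registration error, or partial overlap of the
discriminative regions across subjects (they are shared exactly).
Passing the benchmark therefore shows that the voting hierarchy
recovers a distributed, subject-consistent signal among correlated
decoys at realistic noise — not that it handles misregistered or
temporally confounded real data.

One methodological note on the null control: the quality-control step
keeps the top $\alpha_K$ fraction of loops *by verification accuracy*,
so even under a label permutation the qualified mean sits above 0.5 by
roughly $1.16\,\sigma_{loop}$ (the mean of the upper-30% Gaussian order
statistics), where $\sigma_{loop}$ is the Monte-Carlo spread of a
loop's accuracy estimate. A meaningful null check therefore needs
verification sets large enough that this bias is small; the package's
null control uses $\alpha_{row} = 0.6$ (16 verification trials per
split) for that reason.

## Known limitations

* Binary decoding only; no multinomial extension.
* The group penalty assumes the discriminative clusters are common to
  all subjects; a cluster informative for a minority of subjects is
  penalized toward zero for everyone.
* Quality control by verification accuracy biases qualified accuracy
  upward (see above); $\bar R$ is a model-selection criterion, not an
  unbiased performance estimate.
* Loops are embarrassingly parallel but executed serially; no
  scheduler is built in.
* NCut on very large masks relies on Lanczos convergence of the
  normalized affinity; extremely disconnected or near-disconnected
  graphs may need a larger `support_radius`.
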