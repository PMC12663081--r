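---
title: "Dynamic centrality modes: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic centrality modes: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynhub)
```

## The question the pipeline answers

Resting-state fMRI gives, for each subject, one mean BOLD time series per
region of a network of interest — here a 20-node motor network sampled at
TR = 1.714 s for 260 volumes. Static functional connectivity summarises a
whole scan with one correlation matrix; the premise of this package is that
the *topological role* of a region fluctuates on the scale of tens of
seconds, and that the time a region spends as a network *hub* carries
clinical information. The pipeline quantifies that idea and tests, per
node, whether hub-time is associated with an ordinal impairment score — the
upper-limb score (ULS, 0 = no deficit to 4 = severe), item 5a of the NIH
Stroke Scale.

## The procedure

For each subject with time series $X \in \mathbb{R}^{T \times N}$:

1. **Sliding windows.** Half-open windows of `length_tr` volumes (default
   20 TRs ≈ 34 s), onset advanced by `step_tr` (default 1 TR), giving
   $W = \lfloor (T - L)/s \rfloor + 1$ windows; $T=260$ gives $W=241$.
2. **Windowed connectivity.** Pearson correlation between every node pair
   inside the window, Fisher-transformed: $z = \operatorname{atanh}(r)$.
3. **Proportional threshold.** Each windowed matrix is binarized by keeping
   the $k = \operatorname{round}(0.20 \cdot N(N-1)/2)$ largest *signed*
   weights ($k = 38$ for $N = 20$), an edge-density rather than
   absolute-value criterion, so every window's graph has the same density.
4. **Rank-based betweenness.** Raw betweenness centrality
   $BC(v) = \sum_{s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}$ on the binary
   graph, converted within each window to descending ranks
   (1 = most central, ties averaged).
5. **Centrality modes.** For each node, the cohort-concatenated sequence of
   windowed ranks is clustered by k-means under the cityblock metric, with
   the cluster count $k$ chosen by the mixed performance criterion
   $\mathrm{MPFC} = (CS \cdot AS \cdot DI) / DB$ (average cluster size,
   average silhouette, Dunn index, Davies–Bouldin index, all under
   cityblock distance). The mode with the smallest centroid rank is the
   *high-centrality mode* (HCM); a subject's HCM occupancy is the number of
   windows spent in it.
6. **Association.** Per node, Spearman's rho between HCM occupancy and ULS
   across subjects, with significance assessed against a permutation null
   (1000 permutations of the score; the same permutation set for every
   node). The significant node with the largest $|\rho|$ is the *dynamic
   central motor node* (DCMN). For every other node, the *DCMN-linked
   mode* counts windows in which that node shares an edge with the DCMN
   while the DCMN sits in its HCM; those counts are tested the same way.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `length_tr` | 20 | TRs | ≈34 s; a common compromise between estimator variance and temporal precision for sliding-window connectivity |
| `step_tr` | 1 | TRs | maximal temporal resolution of the trace |
| `density` | 0.20 | fraction | proportional threshold retaining the strongest fifth of weights |
| `k_grid` | 2–6 | — | candidate mode counts; observed optima on realistic data are 2–3, 6 bounds the search generously |
| `n_perm` | 1000 | — | permutation-null resolution; the q99 critical value is then estimated from 1000 draws |
| `q_level` | 0.99 | — | significance = observed \|rho\| exceeding the 99th percentile of the signed null (~0.02 two-sided) |
| `filter_band` | off | Hz | 0.029–0.15 Hz band-pass for raw data; off by default because preprocessed inputs arrive already filtered |

## Statistical choices

**Sidedness.** The null distribution is built from the signed permutation
correlations; the critical value is its 99th percentile and the observed
$|\rho|$ is compared against it. With a symmetric null this rejects in two
~1% tails, a nominal level near 0.02, and flags strong negative
associations (the clinically expected direction) as well as strong positive
ones. A one-sided negative variant (`alternative = "less"`) is provided.
No multiple-comparison correction is applied across the 20 nodes by
default; the permutation set is shared across nodes so their results are
comparable.

**Ties.** Spearman correlations use average ranks throughout (scores are
heavily tied by construction). Betweenness ties — frequent in sparse binary
graphs, where many nodes score exactly zero — get average ranks, which
keeps every window's rank sum at $N(N+1)/2$; the clustering step relies on
that invariance.

**Numerical edges.** Perfect windowed correlations are clipped to
$|r| = 1 - 10^{-7}$ before the Fisher transform so all weights stay finite
and totally ordered. Ties exactly at the proportional-threshold boundary
are resolved deterministically by node-index order (and warned about).
Zero-variance windows abort the subject with a precise error by default; a
`"drop"` option discards the affected windows with a warning instead.
k-means uses k-means++-style seeding with cityblock-distance weighting, 20
restarts, and median centroid updates (the cityblock centroid of 1-D data
is the median); for sorted 1-D data each iteration is $O(k \log n)$, since
nearest-centroid assignment partitions the sorted sample into contiguous
segments. Degenerate clusterings are excluded from the k-grid with a
logged note: an empty cluster or an all-singleton partition makes the
criterion undefined, and coincident centroids score $-\infty$.

## The synthetic cohort and what it does (not) show

No patient data ships with the package, so the generator
(`simulate_cohort()`) plants a known effect to give every stage a
ground-truth recovery test:

* Two $20 \times 20$ correlation matrices define a **hub state** and a
  **non-hub state**. In the hub state the hub node is strongly correlated
  (0.60–0.74) with ten satellite nodes split into two groups whose mutual
  correlation stays below the proportional cut — the hub is the groups'
  only bridge and provably holds betweenness rank 1 of the thresholded
  matrix. The non-hub state is the *same* network with the hub's row
  flattened to 0.05: sharing the periphery between states is what keeps
  every other node's centrality statistically state-independent. The two
  strongest satellites ("linked" nodes, hub correlations 0.74/0.73) hold
  their hub edge in essentially every hub-state window, grounding the
  linked-mode recovery test.
* Ten satellites at $r \ge 0.6$ force satellite inter-correlations of
  roughly 0.5–0.6 for positive definiteness — a genuinely star-like hub
  with weakly coupled satellites is not a valid correlation matrix at this
  size. Community weight tiers are graded in round-robin order so no node
  systematically owns the weakest, noise-flippable edges.
* A two-state Markov chain switches each subject between the states
  (default mean hub-state dwell 200 TRs), conditioned — within a bounded
  number of seeded draws — on realizing its target occupancy and on few
  state episodes, so per-subject occupancies stay spaced as specified
  rather than clumping under finite-length chain noise.
* ULS is assigned by deterministic block-permutation rank binning:
  subjects ordered by occupancy are cut into blocks matching a realistic
  impairment marginal (5% none, 55% mild/moderate, 40% severe at $n=20$),
  and the block-to-level permutation whose realized Spearman correlation
  is closest to `coupling_rho` (default −0.6) is kept. Because subjects
  within a block share a level, the planted coupling is insensitive to
  small perturbations of the estimated occupancy ordering.
* Within a state, volumes are white multivariate Gaussian draws plus white
  measurement noise (`noise_sd = 0.3`).

What passing recovery tests on this cohort shows: the pipeline's stages
compose correctly and can detect an occupancy–impairment coupling of the
planted size at $n = 20$. What it does not show: robustness to
hemodynamic autocorrelation, drift, motion or physiological noise, none of
which the generator emulates (temporal whiteness within state is an
explicit simplification for testability), nor anything about effect sizes
in real patients.

Recovery at cohort size 20 runs close to its statistical ceiling: with a
planted coupling of −0.6, the expected best spurious correlation among 19
null nodes is ≈0.5, so occasional replicates crown a spurious node or miss
significance even with a perfect pipeline. The replicate counts asserted by
the package's tests (≥80% hub recovery, ≥60% joint linked-node flagging
over 25 replicates) sit a few points below that ceiling.

## Design decisions that were genuinely open

* **HCM identity.** The high-centrality mode is the mode with the
  *smallest* centroid on the rank scale (rank 1 = most central). Mean HCM
  centroids on realistic data land around rank 2–6 on a 1–20 scale. This
  is fixed, not configurable: picking the largest centroid would select
  the *least* central epochs.
* **Signed vs absolute thresholding.** "Strongest" weights are the largest
  signed z-values by default — a graph of strong positive couplings — with
  an absolute-value mode (`threshold_mode = "absolute"`) for sensitivity
  analyses.
* **Betweenness implementation.** Brandes' algorithm in C++ (the pipeline
  evaluates ~4800 graphs per cohort and validation sweeps millions), with
  an independent exhaustive geodesic-enumeration reference
  (`betweenness_exhaustive()`) shipped alongside; the test suite compares
  the two across every labelled graph on up to 7 nodes and random
  cohort-scale graphs, and cross-checks igraph.
* **Unnormalized betweenness.** Raw values, converted to within-window
  ranks; ranks absorb any normalization and the tie convention.
* **Filter.** A 4th-order Butterworth applied forward–backward (zero
  phase) with odd-reflection padding; the band 0.029–0.15 Hz. Filtering is
  off by default in the pipeline because its intended inputs are
  denoised, already-filtered series.
* **Command-line interface.** `inst/cli/dynhub.R` wraps `simulate`, `run`
  and `report` subcommands over the exported functions for shell use; the
  R API is the primary interface.

## Problem sizes used by the shipped checks

Unit tests run on reduced cohorts (6–8 subjects, 8–10 nodes, 60–120
volumes); the end-to-end recovery checks use the full reference geometry
(20 × 20 × 260) with 25 seeded replicates, 1000 permutations per test, and
a 500-replicate calibration of the permutation rule. The exhaustive
betweenness sweep covers all $2^{21}$ labelled 7-node graphs.

## Known limitations

* Sliding-window correlation with a fixed 20-TR window fixes the temporal
  resolution; no tapering, DCC or phase-based alternatives are provided.
* One density (0.20) per run; sensitivity across densities is the user's
  loop.
* The permutation test conditions on the observed scores; with $n = 20$
  subjects its q99 critical value itself carries Monte-Carlo noise of a
  few hundredths.
* The generator's two-state model is a caricature: real dynamic hub
  behaviour is unlikely to be binary, and its state switches are shared
  network-wide rather than hub-specific.
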