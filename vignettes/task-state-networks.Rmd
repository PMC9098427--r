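---
title: "Task-state networks from phase transfer entropy: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-state networks from phase transfer entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptenet)
```

This vignette is the package's own account of its science: the
estimators and tests it implements, the generative model it validates
them against, the defaults it chooses where the analysis design leaves
choices open, and the limits of what its passing test suite shows.

## 1. The analysis model

The pipeline treats a trial-based recording as a set of *task-defined
network states*: for each experimental condition, a directed
functional network over the same node set (cortical parcels), and,
across conditions, a quantitative description of how those states
interact.

### 1.1 Phase extraction

Instantaneous phases come from a frequency-domain analytic signal:
`analytic_phase()` Fourier-transforms the epoch, zeroes every
negative-frequency and out-of-band coefficient, doubles the retained
positive-frequency coefficients, inverse-transforms, and takes the
argument. Band restriction and phase extraction are thereby fused into
one linear operation; no time-domain filter is applied anywhere in the
chain, so no extra temporal smearing of phase is introduced. The
default band is 2–60 Hz, wide enough to carry event-related deviance
responses; it is a `pte_config()` field because some preprocessing
conventions prefer 2–40 Hz.

### 1.2 Phase transfer entropy

For a source phase series $x_t$ and target $y_t$, with delay $\delta$
(default 10 samples) and a single-sample target history,

$$\mathrm{PTE}_{x \to y} = H(y_{t+\delta}, y_t) - H(y_t)
  - H(y_{t+\delta}, y_t, x_t) + H(y_t, x_t),$$

all entropies being natural-log plug-in estimates from histograms of
binned phases over $t = 1..T-\delta$. This is the conditional mutual
information between the target's future phase and the source's past,
given the target's past — nonnegative up to floating error, asymmetric
in $x, y$, and sensitive to linear and nonlinear phase coupling alike.

Bins partition $[-\pi, \pi]$ uniformly; their count follows the
normal-reference (Nason–Scott) width $h = 3.49\,\hat\sigma\,m^{-1/3}$,
giving $\lceil 2\pi/h \rceil$ bins with $\hat\sigma$ estimated from the
pooled phases of the whole trial and $m = T - \delta$ (13 bins at the
full epoch geometry of 1921 samples). One bin count serves every axis
of a trial so that entropies are comparable across pairs. A
`bins_override` exists for reproducibility studies.

Design choices worth stating: entropies are in nats (downstream use is
purely comparative); the delay is interpreted in samples; edge-of-epoch
samples are not trimmed beyond the $\delta$-shift; no detrending. The
per-pair reference estimator (`pte_pair()`, pure R) and the compiled
all-pairs kernel behind `pte_matrix()` are tested for exact agreement,
and both against a brute-force triple-loop entropy oracle.

`condition_mean_z()` averages the trial matrices entrywise and z-scores
the *mean matrix* over its off-diagonal entries. The normalization
could equally be taken within one matrix or across a cohort of
subjects; within-matrix was chosen because it
makes each subject × condition network self-normalized, and the flag is
carried in the object so the choice is visible downstream.

### 1.3 Permutation network contrasts

`paired_edge_stats()` (paired $t$ on deviant − standard, $F = t^2$) and
`interaction_edge_stats()` (two-sample $t$ on per-subject difference
matrices — the 2 × 2 group × condition interaction) feed
`permutation_pvalues()`: sign flips of each subject's difference for
paired/one-sample schemes, group-label reshuffles for two-sample
schemes, with the add-one estimator
$p = (1 + \#\{|t_{perm}| \ge |t_{obs}|\})/(1 + P)$, which never returns
zero. Permuted statistics tied with the observed one (the identity
flip, exact symmetries) are counted as exceedances with a relative
tolerance, which the exhaustive-enumeration test requires. Edge-level
FDR control is Benjamini–Hochberg (`fdr_bh()`, delegating to
`stats::p.adjust`); cluster-extent thresholding is deliberately not
implemented. `significant_network()` assembles the surviving edges with
node strength ($\sum |t|$ over incident significant edges), degree, and
density $|E|/(N(N-1))$.

Two arithmetic facts govern every permutation-FDR configuration and are
asserted in the tests rather than left implicit. First, the add-one
p-value cannot go below $1/(P+1)$, so BH at level $q$ over $m$ entries
can only ever reject if $1/(P+1) \le k\,q/m$ for the achievable
discovery count $k$ — permutation counts must be chosen accordingly
(10,000 permutations at full scale). Second, a sign-flip test on
$n$ subjects has granularity $2/2^{n}$; group sizes around 13–15 give
floors near $2.4 \times 10^{-4}$ to $6 \times 10^{-5}$.

### 1.4 Multilink matrices and the multilayer graph

For two conditions A and B, `edge_condition_correlation()` pairs trials
by chronological index (after truncation to the common count; a seeded
random pairing exists for sensitivity analysis) and computes, for every
directed edge, the Pearson correlation between its single-trial PTE
values in A and in B. Entries failing a two-sided per-edge test at
$\alpha$ (default 0.05, uncorrected — a per-subject descriptive
threshold, configurable) are set to zero; significant positive *and*
negative correlations are both retained, implementing a broad notion of
"related" edges. Raw $r$ (not Fisher-z) is stored, since the values
feed group t-tests directly.

`assemble_multilayer()` places the K z-scored condition networks on the
block diagonal and each pair's multilink matrix on both off-diagonal
blocks (mirrored, untransposed: the correlation is one number per
directed edge, symmetric in condition order). At full scale
(K = 4 states over a 360-parcel whole-cortex atlas) the graph is
1440 × 1440. Group inference reuses the
permutation machinery: `group_one_sample_graph_test()` (sign-flip,
entry vs 0), `group_difference_graph_test()` (label permutation, split
by sign into the two one-sided contrasts), and
`one_sample_network_test()` for a single block. Multilinks are read out
as connected components (`multilink_components()`, igraph), common
links across blocks (`common_links()`), and between-block node degrees.

### 1.5 Paradigm and behavior

`build_pattern_set()` constructs the four pattern categories of the
multifeatured statistical-learning stream: 11 base stimuli couple
shape↔color and pitch↔timbre, a seeded bijection couples pitch↔shape
(the audiovisual stream), and six standard triplets (distinct first
stimuli) generate each deviant category by replacing, in the third
stimulus only, the violated feature(s) with the value carried by the
first stimulus of a different standard pattern. The concrete symbol
assignments of the six standard patterns are free parameters of the
design; they are constructed pseudo-randomly under the coupling
constraints, seeded, because only the transitional-probability *structure* matters
downstream. "Equally and randomly interleaved" is implemented as a
seeded permutation of an exactly balanced multiset (115 per category
per 460-pattern run), which guarantees the stated balance rather than
approximating it. Timing (400 ms stimuli, 150 ms ISI) is carried as
metadata; no audio or image is rendered.

The behavioral module mirrors the standard 2AFC analysis: logit
accuracies (with a Laplace-style $(k+0.5)/(n+1)$ correction by default,
off by default-free choice where exact chance level 0 at 18/36 is
needed), chance-level one-sample t tests, the group × modality mixed
ANOVA via classical sums of squares with a subject error stratum
(partial $\eta^2$ per effect against its own error term), and the
pooled-variance two-sample t with Hedges' correction
$J = 1 - 3/(4\,df - 1)$. The equal-variance (not Welch) t is used, so
the test's degrees of freedom are $df = n_A + n_B - 2$.

## 2. The synthetic-data generator

The analysis chain itself presumes no generative model; the package
supplies one so every stage has a recoverable target, and its defaults
are fixed once, here.

Phases evolve as delayed-coupling Kuramoto-type oscillators under an
Euler step:

$$\theta_i[t+1] = \theta_i[t] + 2\pi f_i/f_s
 + \frac{1}{f_s}\sum_j \kappa^{(trial)}_{ij}
   \sin(\theta_j[t-d] - \theta_i[t]) + \eta_t,$$

observed as $x_i[t] = \sin\theta_i[t]$ plus measurement noise. Defaults:
natural frequencies uniform on 8–12 Hz (inside the analysis band);
coupling scale 60 rad/s (strong enough that a planted unidirectional
edge is recovered by PTE in ≥95% of single 1.6 s epochs, weak relative
to $f_s$ so the Euler step stays stable); process noise 0.15 rad/step
(the stochastic drive that makes directed information transfer
detectable); measurement noise 0.05; coupling delay 10 samples,
matching the estimator's default. Epoch geometry defaults to
1921 samples at 1200 Hz.

Per-trial strengths follow $\kappa^{(trial)} = \bar\kappa(1 + \gamma u)$
with $u \sim N(0,1)$ — drawn *shared* between trial $k$ of the two
paired conditions for multilink edges (gain $\gamma$, default 2) and
independently otherwise (same law, so only the sharing distinguishes a
multilink). Deviant conditions add a configurable `effect` to a
designated edge subset, giving condition contrasts a known target.

What the generator deliberately does not emulate: no forward/inverse
field modeling, no volume conduction or source leakage, no sensor
noise topography, no evoked (phase-locked) components, no amplitude
dynamics. Passing tests therefore demonstrate that the *estimators and
statistics* behave as claimed on signals with planted phase-coupled
structure — not that real MEG source series satisfy the oscillator
model.

### A measured limitation: co-modulation delocalizes in dense networks

Validating the generator exposed a genuine property of coupled
oscillator networks worth recording. When many strong couplings share
nodes (e.g., 60 edges over 20 nodes), the five shared strength draws of
the planted multilinks shift the *global* network state of both paired
conditions, so single-trial PTE values co-vary across conditions on
many edges, not just the planted ones — and no coupling scale fixes
this (weaker coupling destroys the planted signal before it localizes
the spillover). At sparse density (12 edges over 20 nodes) the planted
edges and their reversals cleanly attain the largest cross-condition
correlations, and the test suite demonstrates exactly that on the full
oscillator → PTE path. Consequently, the multilink-recovery validation
at the dense design plants the strength law at the trial-edge-value
level (the multilayer module's own input contract) and runs the
between-state one-sample chain on it; the oscillator route validates
locality where the physics permits it.

## 3. Problem sizes and numerical choices

The test suite and the acceptance script run at reduced but stated
sizes chosen as this package's own validation design: 100 two-node
simulations at full epoch geometry for direction recovery; null
calibration with 10-node networks, 13 + 12 subjects, 1000 permutations,
200 replicates; planted-effect power at N = 20, n = 13, effect 1.5 SD
of the paired difference; multilink recovery with 5 of 60 edges
co-modulated at $\gamma = 2$, 15 subjects × 60 paired trials, the
between-state test at $q = 0.05$ with 10,000 permutations (the relaxed
of the two conventional levels — the stricter $q = 0.001$ is
unreachable below the permutation floor at $m = 380$ entries). End-to-end oscillator demonstrations use 961–1441
samples at 600–900 Hz, preserving the samples-per-cycle of the full
geometry.

Degenerate inputs are handled explicitly: constant signals are rejected
at phase extraction; zero-spread phase samples are rejected by the bin
rule; zero-variance edges get statistic 0 (with a warning where that is
anomalous, silently inside multilayer stacks where thresholded zeros
are routine); constant edge series yield correlation 0 with a warning;
all-zero sums of squares yield F = 0. Seeded functions restore the
caller's RNG state (`withr::local_seed`), so Monte-Carlo loops over
seeded calls remain independent.

## 4. Known limitations

- The oscillator generator is a stand-in, not a claim about MEG data;
  see §2.
- Single-trial PTE at 1.6 s epochs is biased upward at small samples
  (the suite asserts the bias shrinks with T); all inference is
  comparative across conditions estimated at identical geometry, which
  is why the bias cancels to first order.
- Edge-level FDR is the only correction offered (by design); no
  cluster-extent or spatial-adjacency inference.
- The trial pairing across conditions required by the multilink
  correlation is chronological by index; no convention fixes it a
  priori, and the alternative seeded random pairing is provided to
  check sensitivity.
- A "multilink count" can refer to nonzero matrix entries or to
  connected components; both are computed (`sum(mask)`,
  `multilink_components()`) and reported side by side, since the two
  can differ substantially on clustered masks.
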