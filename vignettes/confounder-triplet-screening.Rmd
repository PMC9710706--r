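---
title: "Confounder triplet screening for paired omics data: model, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confounder triplet screening for paired omics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkcor)
```

## The model

`linkcor` integrates two numerical datasets measured on the same n samples:
a vertex matrix V (m features) whose pairwise relationships are the object
of study, and a linker matrix L (p features) screened for variables that
*control* those relationships. The unit of inference is the **triplet**
(a, b, l): an unordered vertex pair plus one linker.

For each triplet the screen contrasts the zero-order correlation
$r_{ab}$ with the first-order partial correlation

$$ r_{ab \cdot l} \;=\; \frac{r_{ab} - r_{al}\,r_{bl}}
   {\sqrt{(1-r_{al}^2)(1-r_{bl}^2)}}, $$

which equals the correlation of the least-squares residuals $a^*, b^*$ of
a and b on l. If conditioning on l changes the correlation significantly,
l is flagged as a putative confounder of the a–b relationship. No
normalization of the inputs is required: correlations are invariant to
per-feature affine rescaling, and the only preprocessing the package
performs is validation (finite values, non-zero variance) plus the
optional variance pre-filter discussed below.

### The test

Equality of $r_{ab}$ and $r_{ab \cdot l}$ is tested with a Steiger-type Z
for two dependent, non-overlapping correlations. Both coefficients are
Fisher-transformed (after clamping at $1 - 10^{-12}$ so degenerate toy
inputs cannot produce infinities); the covariance between them is
estimated by the Pearson–Filon expression in the six pairwise sample
correlations among $\{a, b, a^*, b^*\}$, evaluated at the pooled
coefficient as Steiger proposed, and $n-3$ effective degrees of freedom
are used for both terms:

$$ Z = (z_1 - z_2)\sqrt{\frac{n-3}{2 - 2c}} . $$

All six correlations have closed forms in $(r_{ab}, r_{al}, r_{bl})$
(e.g. $\mathrm{cor}(a, a^*) = \sqrt{1-r_{al}^2}$), so the whole screen is
evaluated vectorized from two correlation matrices; `steiger_test()`
exposes the same computation for a single triplet. We verified the
covariance formula by simulation: for two genuinely distinct variable
pairs with equal population correlation the test rejects at 5.3% at
$\alpha = 0.05$ (n = 100), and that check is part of the test suite.

**An important caveat, verified empirically and by a degeneracy argument:**
when l is (nearly) unrelated to a and b, $\hat r_{ab}$ and
$\hat r_{ab\cdot l}$ are estimated from the same sample and their
difference is second-order (a quadratic form in the $O(n^{-1/2})$
quantities $\hat r_{al}, \hat r_{bl}$), so the Z statistic is not
asymptotically standard normal under that null — it is strongly
*conservative*. We measure a realized type-I error of roughly $2 \times
10^{-4}$ at nominal $\alpha = 0.05$. No choice of degrees of freedom
repairs a wrong limiting shape, and every delta-method comparison of r
with r|l computed from one sample shares the defect. The package keeps
the classical test because (i) it is the field's standard for this
screen, (ii) conservativeness is the safe direction for a discovery tool,
and (iii) the power to detect *strong* confounders (the targets of the
method) remains high — the suite verifies >95% rejection for a planted
common cause at n = 100. The practical consequence: realized false-positive
rates sit far below nominal, and p-values near the threshold should be
read as a ranking, not as calibrated error statements.

### Multiplicity and sparsification

Vertex pairs are first restricted to those significantly correlated
(two-sided t test on n−2 df, Benjamini–Hochberg across all pairs, default
$\alpha_{pair} = 0.05$; switchable to raw p-values or off). This both
focuses the screen on interpretable relationships and tames the
$O(m^2/2) \cdot p$ triplet count. Across all tested triplets the Steiger
p-values are then BH-adjusted globally (default $\alpha = 0.05$); we
adjust globally rather than per pair so the flag set is a single
coherent discovery list. An optional second sparsification additionally
requires the partial correlation itself to be significant (off by
default). Triplets whose linker shares a feature ID with either vertex
are degenerate and are skipped and counted.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha_pair` | 0.05 | BH level for vertex-pair sparsification |
| `alpha_triplet` | 0.05 | BH level for the triplet screen |
| `method` | pearson | correlation type (spearman for monotone, outlier-prone data) |
| `fhvf` | off | keep only high-variance features before the run |
| `fhvf_quantile` | 0.75 | variance quantile kept by the pre-filter |
| `fhvf_target` | linker | which matrix the pre-filter applies to |
| `chunk_size` | 512 | vertex pairs per streamed chunk (memory knob only) |
| `workers` | 1 | forked workers (results independent of the setting) |

The variance pre-filter is defined as "keep features at or above the
`fhvf_quantile` quantile of feature variances", ties kept. It applies to
the linker matrix by default — in benchmark experience it is the linker
side whose bulk dominates runtime, and pre-filtering vertices changes the
object of study — but a switch covers vertex-side or both. Note the
filter is variance-based, hence scale-sensitive: on unstandardized data
it preferentially keeps high-magnitude features.

A minimum of n = 4 samples is enforced everywhere (the partial
correlation's significance has n − 3 degrees of freedom); matrices are
aligned on the intersection of their sample IDs before any computation.

## The simulation benchmark

`simulate_latent_datasets()` draws each view from its own sparse
latent-factor model: k standard-normal factors per view, each
feature-factor loading active with probability 0.5 and standard normal,
plus i.i.d. Gaussian noise. This emulates the correlated blocks real
omics data shows within a layer. **Factors are deliberately
view-specific**: with factors shared across views, every linker loading
on a factor that drives a correlated vertex pair would be a genuine
confounder of that pair, and an induced-triplet ground truth could not
label the (correct) detections — false-discovery rates would be
meaningless by construction. Keeping the views independent at baseline
makes the induced triplets the only cross-view signal and the benchmark
rates well defined.

`induce_true_triplets()` plants ground truth: for disjoint vertex pairs
and distinct linkers it adds the standardized linker profile as a common
cause, $a' = a + \beta \tilde l$, $b' = b + s\,\beta \tilde l$, choosing
the sign pattern $s = +1$ when pushing the pair correlation toward +1
leaves headroom ($1 - r_{ab} \ge t$) and $s = -1$ otherwise, so a target
is reachable for any baseline correlation with $t \le 1$. $\beta$ is
bisected until the achieved $|\Delta\mathrm{corr}|$ lands in
$[0.9\,t,\ t]$ — the parameter t bounds the allowed change from above,
and the band's lower edge turns t into an effective effect size rather
than a loose cap. Pairs where the band is unreachable in 100 bisection
steps are skipped with a warning.

Generator defaults (k = 3 factors, activation 0.5, noise sd 1, m = 30,
p = 20, 5 induced triplets) were fixed once as a realistic desk-scale
condition: unit noise against unit-scale factor signal gives within-view
correlations spanning weak to strong, and five planted triplets keep the
truth sparse relative to the ~2000-triplet universe. The default
benchmark grid crosses n ∈ {10, 100}, pre-filter on/off and
t ∈ {0.2, 0.4, 0.6}, 20 repetitions per cell in the shipped acceptance
runs (100 is just a parameter change); all seeds derive from one master
seed and rerun bit-identically.

### What the benchmark shows — and what it cannot

With n = 100 and no pre-filter, measured over 20 repetitions per
condition: specificity is essentially 1 (≥ 0.99), sensitivity rises
steeply in t (≈ 0.04 at t = 0.2 to ≈ 0.8 at t ≥ 0.4), n = 10 recovers
essentially nothing (pair sparsification at n = 10 requires |r| near 1),
and an aggressive linker pre-filter discards most true linkers before the
run and costs sensitivity accordingly. All of these are asserted by the
acceptance suite at exactly these scales.

False discovery proportions against the induced truth need careful
reading: injecting l into a and b also makes l a genuine confounder of
pairs joining a modified vertex to its correlated neighbors. These
*spillover* detections are real consequences of the injection, but the
exact-triplet truth set counts them as false positives, so the measured
"FDR" (≈ 0.3 at t = 0.4, higher at t = 0.6 where spillover is stronger)
is an upper bound that mixes labeling artifacts with genuine errors.
Specificity is the robust scale for error control here because true
negatives dominate the tested universe.

The generator emulates within-layer correlation structure and additive
confounding only. It does not model heavy tails, nonlinear regulation,
compositionality, batch structure, or missingness — passing benchmarks
here demonstrates correctness of the machinery under the stated model,
not robustness to those features of real data.

### Scoring

`evaluate_recovery()` counts an exact (vertex pair, linker) match as a
true positive; the universe for true negatives is the set of tested
triplets. A truth triplet that was never tested (its linker fell to the
pre-filter, or its pair to sparsification) errors by default; the
benchmark instead counts it as a false negative and extends the universe,
because losing testable truth to aggressive filtering *is* the
sensitivity cost being measured. `fdr` is defined 0 when nothing is
flagged.

## Numerical and design choices

- Correlations are clamped at $1 - 10^{-12}$ before Fisher transforms;
  the covariance scale factor c is clipped to $[-1, 1 - 10^{-12}]$.
- The screen streams over chunks of vertex pairs with per-triplet scalar
  algebra — mathematically identical to materializing partial-correlation
  matrices, with memory bounded by `chunk_size` × p. Chunking and worker
  count provably cannot affect results (pure per-triplet arithmetic), and
  the suite asserts record-for-record equality.
- Edge weights in the weighted view count distinct confounding linkers;
  mean |Δ| is stored as an alternative weight attribute, so an
  aggregate-correlation-change weighting is available downstream without
  refitting.
- Betweenness and edge betweenness use the unweighted topology: the
  confounder-count weights are affinities, and igraph would treat them as
  distances.
- HITS hub scores on an undirected graph coincide with the principal
  adjacency eigenvector; they are computed with the dense symmetric
  eigensolver (not an iterative method) so that graphs with degenerate
  top eigenvalues — e.g. two identical components — still yield
  deterministic output, and normalized to max 1.
- Spectral community detection is normalized-Laplacian embedding with k
  chosen by the largest eigengap (capped at `kmax`) and a seed-controlled
  k-means (20 restarts). Greedy-modularity and edge-betweenness
  clustering delegate to igraph.
- Community enrichment ("local controlling features") uses the triplet as
  its unit: a triplet is inside a community when both vertices are;
  cross-community triplets count toward the total N but toward no
  community's inside count, which keeps all margins consistent. The test
  is the one-sided hypergeometric (Fisher upper tail), BH-adjusted across
  all (linker, community) pairs with at least one inside triplet.
- Ranking linkers uses max |Δ| over significant triplets, then mean |Δ|,
  then feature ID — documented, total, deterministic.
- "Shared" triplets across conditions means exact (pair, linker) identity
  by default; `level = "edge"` relaxes to the vertex pair. The Jaccard
  index is reported on the chosen key.
- File outputs round-trip exactly (17-significant-digit formatting) and
  contain no timestamps, so reruns are byte-identical; the run manifest
  records config digest, input MD5s, package version and stage counts.

## Known limitations

- The Steiger screen's conservativeness under weak confounding (above)
  means nominal α overstates the realized false-positive rate by orders
  of magnitude; power for weak confounders (|Δ| ≲ 0.15 at n = 100) is
  correspondingly low.
- Only first-order partial correlations are screened: a pair controlled
  by two linkers jointly but neither individually will be missed, and
  correlated linkers produce partially redundant flags.
- Linear, Gaussian-flavored machinery throughout; Spearman correlations
  are offered but the Steiger covariance is still the Pearson–Filon
  asymptotic form.
- The benchmark's absolute recovery numbers depend on the generator; they
  are comparable across its own conditions, not across publications using
  other simulators.
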