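---
title: "Bimodal gene expression: model, estimation and validation"
author: "bimodr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bimodal gene expression: model, estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimodr)
```

## The model

`bimodr` assumes that for a *bimodal* gene the distribution of expression
signals across a cohort is a mixture of two roughly Gaussian components —
two modes corresponding to two physiological states of the samples — while
for most genes it is a single unimodal bump. The machinery makes only weak
use of this assumption: the estimator is a partition statistic, not a
likelihood, so it degrades gracefully when modes are skewed or unbalanced.
Compared with two-component mixture fits (EM + likelihood ratio or BIC) it
is orders of magnitude cheaper, has no convergence failures, and — unlike
kurtosis-based scores — still detects strongly unbalanced modes.

### The optimal two-way partition

For a gene's non-missing signals, sorted ascending, every split index
$k \in [1, n-1]$ defines a lower subset $L$ (the $k$ smallest values) and
upper subset $U$. The quality of a split is the within-subset sum of
squares $\gamma(k) = \mathrm{SS}(L) + \mathrm{SS}(U)$, and the optimal
partition minimizes it — the exact 1-D two-means solution, computed in one
pass with prefix sums. One-sided splits (an empty subset) are not
admissible: a single cluster is by definition not bimodal. Ties in
$\gamma$ are broken toward the smallest $k$; because mathematically equal
splits can differ by ~1e-15 after floating-point accumulation, the
tie-break uses a $10^{-9}$ relative tolerance, which makes results
independent of input order and platform.

The threshold separating the modes is the midpoint
$T = (\max L + \min U)/2$. Any value in $[\max L, \min U]$ would separate
the subsets; the midpoint is the unique symmetric choice, and it maps to
exactly 0 on the normalized scale below.

### The $\tau$ statistic

$$\tau = \frac{u - l}{\sqrt{\gamma / M}},$$

with $l = \langle L \rangle$, $u = \langle U \rangle$ and $M$ the number of
signals entering the fit. $\tau$ measures how far apart the two subset
means are in units of pooled within-subset spread; it is invariant under
positive affine transforms $x \mapsto ax + b$, since $u-l$ and
$\sqrt{\gamma/M}$ both scale by $a$. When $\gamma = 0$ with $u > l$ (two
perfectly constant separated levels) $\tau$ is reported as `Inf` and
serialized as the token `"inf"`.

For iid Gaussian signals the optimal split converges to the mean, the
subset means to the half-normal means $\mp\sigma\sqrt{2/\pi}$, and
$\gamma/M$ to the half-normal variance $\sigma^2(1 - 2/\pi)$, giving the
closed-form baseline

$$\tau_\infty = \frac{2\sqrt{2/\pi}}{\sqrt{1 - 2/\pi}} \approx 2.6472,$$

available as `tau_normal_baseline()`. The default call threshold 2.64 is
this baseline: a gene whose spread looks no wider than a single Gaussian's
should not be called bimodal.

**Finite-sample behaviour.** Because $\gamma$ is *minimized* over splits,
it is biased slightly downward at finite $M$, so the null expectation of
$\tau$ sits *above* the asymptote: simulation (see
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`) gives a mean
of ≈ 2.75 at $M = 100$, ≈ 2.68 at $M = 295$, approaching 2.647 only for
$M \gtrsim 10^4$. Two practical consequences: (i) the acceptance script's
null-cohort mean reproduces ≈ 2.68, not the asymptote; (ii) with the
threshold fixed at the asymptote, roughly half to two-thirds of *unimodal*
genes exceed it by chance at cohort sizes of a few hundred. The $\tau$
cutoff is therefore a *candidate filter*, deliberately liberal, not a
hypothesis test with controlled false-positive rate; downstream steps
(control-sample orientation, cross-dataset intersection, group discovery)
provide the real specificity. Users who need a conservative single-dataset
call should raise `tau_threshold` above the simulated null quantile for
their $M$.

### Outliers and the variance filter

A handful of extreme values would otherwise masquerade as a mode (e.g. 3
samples far above the other 97). If the optimal partition isolates a
subset smaller than `outlier_fraction` (default 5%) of the *original*
sample count, those values are flagged as outliers, removed, and the
remainder re-partitioned, iterating until both subsets are large enough.
Measuring against the original $n$ keeps repeated trimming from eroding a
genuine small mode; the procedure is idempotent once it reports no
removals, and fewer than 4 surviving values is an error (a flag, at the
batch level). Alternatives — dropping the gene outright, or winsorising —
were rejected because the remainder of a trimmed gene is often a clean
bimodal profile worth keeping.

Genes must also pass a variance screen: sample standard deviation (n−1
denominator) strictly greater than the 25th percentile
(linear-interpolation quantile, R type 7) of the per-gene sd distribution.
Both conventions are stated so results are bit-reproducible. With
`min_samples` (default 10) the per-gene fit is skipped for very sparse
rows; real cohorts of hundreds of samples never hit this guard.

## Bimodal normalization

Signals are rescaled per gene by the piecewise-linear map

$$x \mapsto \begin{cases} (x - T)/(T - l), & x \le T \\ (x - T)/(u - T), & x > T, \end{cases}$$

sending $l \to -1$, $T \to 0$, $u \to +1$ exactly (the anchor identities
hold bit-exactly in IEEE arithmetic, not just approximately). A single
linear map cannot satisfy all three anchors unless $T$ happens to be the
midpoint of the mode means, hence the two hinged segments. Values beyond
the mode means map beyond ±1 and are *not* clipped — clipping would hide
outliers and break strict monotonicity; consumers may clip for display.

Because the anchors are estimated from each gene's own distribution, the
normalized profile is exactly invariant under per-gene positive affine
distortions of the raw data — the formal content of cross-platform
comparability, verified to 1e-9 in the acceptance suite.

**Control orientation.** With control/normal samples present, the mode
holding the controls is given the +1 direction: per gene, if all controls
sit above $T$ the gene is kept as-is; if all sit below (control mean
$\nu < T$) the normalized values are negated; if controls straddle $T$ the
gene's direction is ambiguous and it is excluded (values set to missing).
A control exactly at $T$ counts as the upper side, consistent with the
barcode boundary convention below. Without controls the upper mode is +1.

## "Close neighbors" groups and barcoding

Co-regulated bimodal genes switch modes together, so their normalized
profiles are nearly parallel: the cosine distance
$\rho = 1 - \cos(x, y) \in [0, 2]$ from a query gene to its partners is
near 0 while unrelated bimodal genes sit near 1 (independent switching)
and anti-synchronized genes near 2. Group discovery histograms the
distances from the query over $[0, 1]$ (bin width 0.05) and looks for an
isolated near-zero cluster: the *gap* is the first empty bin below the
distance median that has at least one non-query gene below it, and the
group is everything below that gap. Leading empty bins immediately after
the query's own zero bin do not count as gaps — with realistic mode
agreement (~95%) genuine partners sit at distances around 0.2, so a
literal "first empty bin" rule would terminate at ~0.05 and never return a
group. A `fixed` strategy (plain distance cutoff, default 0.25) is
available as a fallback. No group (only the query below every gap, or no
gap below the median) is a valid `NULL` outcome, not an error.
Anti-correlated genes are not folded in with a sign flip: after control
orientation, true group members run in the same direction.

A group's expression in a sample is the mean of its members' normalized
values; members absent from a dataset (not assayed on that platform) are
skipped, so groups remain usable descriptors across platforms. Sample
**barcodes** read each group's mean as a digit — 1 below 0, 2 at or above
0 (the boundary convention is arbitrary but fixed) — and join them with
dashes in user-given group order, partitioning the cohort into at most
$2^G$ clusters.

## Meta-analysis

Cross-dataset comparison restricts each pair to the *shared universe* of
genes assayed on both platforms (absent genes are "not assayed", never
"not bimodal"), intersects the bimodal sets within it, and scores overlap
with the one-sided hypergeometric upper tail
$P(X \ge \text{overlap})$ — the Fisher exact test for over-representation,
computed via `phyper(log.p = TRUE)` so magnitudes like $10^{-112}$ are
exact; tests cross-check it against direct log-space summation of point
masses. Annotation enrichment takes a user-supplied universe constant
(genome-scale, e.g. 40,599) rather than the platform size, since the
annotation sets are genome-wide resources. "Commonly bimodal" genes are
those called in at least `min_datasets` (default 3) datasets.

## The synthetic cohort generator

`simulate_cohort()` draws cohorts with the exact structure the method
assumes, with ground truth for every stage:

* gene baselines $\mu_g \sim N(8, 2)$ and within-mode sd $\sigma = 0.5$ —
  a log2-intensity-like scale;
* bimodal genes (default 10%) split by a per-sample binary mode with mean
  gap $\delta\sigma$ ($\delta = 6$ by default, a clearly separated pair of
  peaks) and upper-mode probability `balance` (0.5);
* planted groups (default five of 4–6 genes) whose members copy a shared
  per-sample latent mode, flipped independently with probability
  $1 -$ `group_agreement` (0.05) — synchronized within, independent
  between groups;
* optional control samples whose latent modes are pinned to the upper
  mode (a homogeneous reference tissue, exempt from disagreement flips);
* optional per-cell outlier spikes placed far above the upper mode;
* per platform, a per-gene distortion $a_g x + b_g$ with
  $a_g = e^{N(0, \texttt{affine\_jitter})} > 0$ — the minimal model of
  cross-platform intensity differences.

Everything derives from one seed. The generator emulates mode structure,
synchrony and platform effects; it does **not** emulate probe-level array
physics (saturation, background), correlated unimodal covariation, or
heavy-tailed biological noise — so passing tests demonstrate correctness
of the machinery under the stated model, not performance guarantees on any
real cohort.

## Problem sizes and numerical choices

The validation suite uses cohorts chosen to make every property measurable
in seconds: the planted-recovery check runs the full pipeline on a 2,000 ×
200 cohort at the default conditions; the null-baseline check uses 1,000
genes × 295 samples; the partition oracle cross-checks 10,000 random
vectors of length 4–50 (mixed continuous and tie-heavy discrete
distributions) against an exhaustive scan. Degenerate inputs are
first-class: constant genes are flagged (`"degenerate"`), sparse genes
(`"insufficient"`), and batch calls never abort on a bad gene. At these
conditions the detector's sensitivity for $\delta = 6$ genes exceeds 0.95
while raw specificity sits near 0.5 — the liberal-filter behaviour
discussed above, quantified honestly rather than tuned away.

## Known limitations

* The $\tau$ threshold is not a p-value; its null exceedance depends on
  $M$ (see finite-sample note above).
* Cross-platform gene matching is by case-insensitive symbol only; no
  probe/identifier mapping service is included.
* Multi-modal ($>2$) structure is collapsed onto the best two-way split.
* Barcode clusters are descriptive; no survival or end-point association
  testing is provided.
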