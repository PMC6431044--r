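---
title: "Calling cells against the ambient profile: models and design choices"
author: "emptydrops package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling cells against the ambient profile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emptydrops)
```

This vignette documents the statistical model behind `empty_drops()`,
the parameters that matter, the synthetic data the package tests itself
on, and the places where the design was genuinely open and a choice had
to be made.

# The null model

An empty droplet contains no cell; its transcripts are a random
encapsulation of the cell-free ambient pool. Conditional on the total
UMI count $t_b$ of barcode $b$, we model its counts $y_{gb}$ as
Dirichlet-multinomial (DM) with mean proportions $\tilde p_g$ and scale
$\alpha$:

$$
L_b \;=\; \frac{t_b!\,\Gamma(\alpha)}{\Gamma(t_b+\alpha)}
\prod_{g=1}^{N}\frac{\Gamma(y_{gb}+\alpha_g)}{y_{gb}!\,\Gamma(\alpha_g)},
\qquad \alpha_g = \alpha\,\tilde p_g .
$$

The multinomial is the $\alpha\to\infty$ limit; finite $\alpha$ absorbs
overdispersion from amplification bias and correlated molecule
sampling. Everything is computed in log space through `lgamma()`;
zero-count genes contribute exactly zero and are skipped, so the cost of
one likelihood is proportional to the number of expressed genes in the
barcode.

Cell-containing droplets are expected to deviate from the ambient
proportions, so a small $L_b$ relative to its null distribution is
evidence for a cell. The test conditions on $t_b$, which is what makes
small cells recoverable: a barcode whose *profile* deviates is called
even if its *total* is unremarkable.

## Ambient profile estimation

Barcodes with $t_b \le T$ are presumed empty and pooled; `lower`
(= $T$, default 100) should sit below any plausible cell. The pooled
counts $A_g$ are converted to proportions with simple Good-Turing
smoothing (Gale–Sampson), via `edgeR::goodTuringProportions()`: the
unseen mass $P_0 = n_1/N$ is split equally among zero-count genes, and
observed counts get smoothed, renormalized estimates. Positivity of
every $\tilde p_g$ keeps $L_b$ defined for any barcode.

Two degenerate regimes are handled directly because the Good-Turing
frequency regression is then undefined: no singletons ($n_1 = 0$), or
fewer than two distinct positive frequencies. In both, every zero-count
gene receives the floor $1/(N + G)$ ($N$ total ambient molecules, $G$
genes) and observed genes share the remainder proportionally to their
counts. The floor is a pragmatic guarantee of positivity, not a claim
about the true unseen mass.

Two caveats worth knowing about genuine simple Good-Turing output: the
equal split of $P_0$ can give a zero-count gene *more* mass than a
singleton gene when few genes are unseen, and the switch from Turing to
smoothed estimates can mildly invert adjacent frequencies. Neither
affects the validity of the downstream test (only positivity and
sum-to-one are required), but the proportions should not be read as a
monotone transform of the counts.

## Fitting the scale

$\alpha$ is estimated once, by maximizing the summed DM log-likelihood
of the ambient barcodes with $\tilde p_g$ plugged in, and treated as
fixed downstream. The likelihood is smooth and unimodal in $\alpha$, so
a bounded Brent search over $\log_{10}\alpha \in [-2, 4]$ with
tolerance $10^{-5}$ suffices; six decades comfortably cover observed
droplet data. Hitting the upper bound simply means the ambient counts
look multinomial (this is expected, and warned about, when empties are
resampled without replacement in the simulation harness, which is
underdispersed by construction). For speed the objective collapses the
ambient submatrix to weighted unique (gene, count) pairs, so each
evaluation is a few thousand `lgamma` calls regardless of pool size.

# Monte Carlo p-values

Exact tail probabilities are intractable (the composition space is
astronomically large), so p-values are Monte Carlo:

$$P_b = \frac{R_b + 1}{R + 1},$$

with $R_b$ the number of iterations whose simulated log-likelihood is at
or below the observed one. This (Phipson–Smyth) estimator never returns
zero, which matters during the BH correction. The default
$R = 10\,000$ puts the attainable floor $1/(R+1) \approx 10^{-4}$ well
below the 0.1% FDR working point; barcodes at the floor are flagged
`limited`, and `power_limited` further marks flagged non-calls, which
users should read as "increase R", not "confidently empty".

## The grouped urn sampler

Simulating $R$ independent DM vectors per barcode would cost
$O(R \sum_b t_b)$. Instead, each iteration grows a *single* count
vector one molecule at a time by the Pólya-urn rule — gene $g$ is drawn
with probability proportional to $\alpha_g$ plus its current count —
and the running log-likelihood is recorded whenever the running total
equals some barcode's total. The urn path's marginal distribution at
total $t$ is exactly DM($t$, $\alpha_g$), so all barcodes sharing a
total share $R$ valid null draws (the null depends on $b$ only through
$t_b$), at cost $O(R \cdot \max_b t_b)$.

Implementation notes:

* One uniform deviate per molecule both chooses the base-measure versus
  reinforcement branch and indexes the gene (Walker alias table for the
  base measure, a uniformly chosen previous molecule for
  reinforcement).
* The likelihood's size term telescopes to
  $\log t! + \log\Gamma(\alpha) - \log\Gamma(t+\alpha)$ and is computed
  directly at the recorded totals with the same expression used for
  observed likelihoods; only the per-gene product is accumulated along
  the path, flushed into log space near the double range.
* Comparisons $L'_{bi} \le L_b$ use a tolerance of
  $10^{-6} + 10^{-9}|L_b|$: the simulated gene term is accumulated
  incrementally while the observed one is computed directly, so exact
  ties (identical compositions) agree only to rounding. The tolerance
  is orders of magnitude below the spacing of distinct compositions in
  any regime where ties carry probability mass, and the package's
  enumeration test (all compositions at small $t$) verifies that tied
  compositions are counted.
* A naive per-total sampler (Dirichlet draw, then multinomial, then the
  direct likelihood) is retained behind `sampler = "naive"` as a
  verification oracle; a two-sample test in the suite checks the two
  samplers agree in distribution.
* One seed drives the whole run; results are independent of barcode
  order because the simulation stream depends only on the sorted set of
  unique totals.

# The barcode-rank curve

Barcodes are ranked by decreasing total with average ranks for ties, so
each distinct total is one point $(\log \bar r, \log t)$ and the curve
is a function. Two landmarks are detected:

* **Inflection**: the most negative finite difference
  $\mathrm{d}\log t/\mathrm{d}\log r$, searched right of the first 1%
  of ranks and restricted to totals above `lower`, so that noisy
  differences between sparse large totals or among ambient barcodes
  cannot win; the right edge of the steepest segment is reported.
* **Knee**: a cubic smoothing spline $f$ is fitted to the window from
  the smallest rank through the inflection point, its first and second
  derivatives are evaluated analytically from the spline basis (no
  numerical differentiation of fitted values), and the knee is the grid
  point minimizing the signed curvature $f''/(1+f'^2)^{3/2}$ over 1,000
  evaluations, ties broken toward smaller rank (a larger, more
  conservative threshold). The smoothing parameter comes from
  generalized cross-validation with a small floor (`spar` at least 0.1)
  against interpolation.

The knee total is the retention threshold $U$: every barcode with
$t_b \ge U$ is called a cell regardless of its p-value, because a
distinct subset of large totals is not consistent with the unimodal,
decaying total-count distribution expected of empty droplets. The knee
(not the inflection) is used because it is the larger, more
conservative total. `knee_override` sets $U$ manually and
`ignore_knee` disables retention entirely (statistically cleaner, but
ambient-like large cells may then be lost).

Design notes, where the choices were open:

* "The interval containing the knee point" is interpreted as
  [smallest rank, inflection rank]. A fixed low-df spline (df = 20) was
  evaluated as an alternative to GCV and rejected: it rounds the
  plateau/cliff corner and drags the curvature minimum into the plateau.
* The signed-curvature knee is, by construction, the point where the
  curve *begins* to drop. On data whose "plateau" actually slopes over
  a decade (heterogeneous cell sizes), the knee lands inside the bulk
  of the cell totals and knee-based retention sheds the plateau's lower
  tail. This is a property of the definition, not of the fit; the
  significance test recovers those cells regardless.
* A knee is reported `low_confidence` when the minimum curvature is
  weaker than 0.5 in magnitude — near-linear curves produce only
  smoothing wiggles at that scale, while genuine plateau-to-cliff
  corners measure in the tens. If the spline window has fewer than four
  points the knee falls back to the inflection with a warning; the
  fallback can never silently pick a tiny $U$ below it.

# Multiple testing

BH correction runs over tested barcodes only ($t_b > T$): barcodes at
or below $T$ were used to *build* the null and are excluded outright,
which lightens the correction. Knee-retained barcodes
($t_b \ge U$) enter the correction with $p = 0$ — known positives that
further lighten the correction for everything else — while their raw
p-values are still reported for transparency. Cells are barcodes with
adjusted FDR at or below the threshold (default 0.1%) or total at or
above $U$. The reported FDR is therefore conditional on the knee
assumption: if $U$ were ever to land among genuinely empty totals, the
retention rule, not the test, would admit those empties.

# The simulation harness

Real datasets carry no ground truth, so performance is measured on
simulations built from a base dataset (any 10X matrix, or the synthetic
fixture below):

1. The base's inflection point splits barcodes; everything below it is
   the empty set $\mathcal G_0$ (the inflection is used, not the knee,
   to keep real cells out of the simulated ambient pool). Pooled
   $\mathcal G_0$ molecules are globally permuted and partitioned into
   totals matching the *exact multiset* of $\mathcal G_0$ totals —
   sampling without replacement that reproduces the observed number of
   empties and their totals while conserving every gene's pool count.
2. $G_1$ large cells are sampled with replacement from above-inflection
   barcodes.
3. $G_2$ small cells are sampled likewise, then downsampled to 10% of
   their totals by multivariate hypergeometric draws (exact totals,
   marginal expectation 10% per gene), mimicking low-RNA cells.
4. In all sampled cell profiles, 10% of genes (chosen once per
   simulation) have their counts permuted among themselves, a fresh
   permutation per barcode, breaking ambient resemblance while
   preserving totals. The scrambling operator and its once-per-
   simulation gene choice are an interpretation — the goal is only
   that true cells not be ambient-like — and scrambling is applied to
   the final (post-downsampling) small-cell profiles.

`evaluate_methods()` then runs the ambient test, the knee baseline and
the expected-cell-count quantile baseline (with the true cell count as
the expectation), reporting recall per group and the observed FDR (the
fraction of called barcodes that are labelled empty).
`benchmark_scenarios()` repeats this over a scenario grid with seeds
derived from one root.

## The synthetic base fixture

`make_base_fixture()` emulates an unfiltered droplet run with the
geometry the calling problem presumes; defaults were fixed once, on the
following reasoning:

* 2,000 genes, 2,000 cells, 50,000 empties: large enough for stable
  rank-curve landmarks and thousands of tested barcodes, small enough
  that a full benchmark grid runs in minutes on one CPU.
* Ambient proportions Zipf ($p_g \propto 1/g$): droplet ambient pools
  are heavily dominated by a few transcripts.
* Empty totals lognormal(log 50, 0.6): mode near tens of molecules,
  ~12% of empties above $T = 100$ (so observed-FDR denominators are
  meaningful), 99.9th percentile ≈ 320 — a realistic light upper tail
  that stays clearly below the cell plateau.
* Cell totals lognormal(log 5000, 0.15): a genuinely flat plateau
  (90% range ≈ 3,900–6,400). The fixture models the idealized
  two-plateau geometry; heterogeneous cell sizes are deliberately out
  of its scope (see limitations).
* Empties are DM draws at $\alpha = 100$ — visible overdispersion
  without swamping the signal; the worked example in the README shows
  the estimator recovering it.
* Three cell types, each a lognormal (sd 1 on the log scale) fold
  perturbation of the ambient proportions: distinct but correlated
  profiles, as in real tissue.

The package's own evaluation (the acceptance script and the end-to-end
test file) runs the scenario grid $G_1, G_2 \in \{500, 2000\}^2$ with
10 iterations per scenario at $R = 10\,000$ and nominal FDR 0.1%, and
checks that the observed FDR stays at or below nominal within Monte
Carlo error, that small-cell recall beats both baselines in at least
9 of 10 iterations per scenario, that the Monte Carlo p-values match
brute-force enumeration on a 3-gene problem, that null p-values are
conservative, that the $\alpha$ MLE recovers truths across
$\{1, 10, 100, 1000\}$, and that the detected knee lands inside the
generator's transition band in at least 95% of 40 seeds. Those problem
sizes are the package's chosen test conditions, not limits of the
method.

# What passing tests do and do not show

The fixture's empties are ideal DM draws from a single ambient profile,
its cells form one flat plateau, and every barcode is independent. Real
data violate all three: ambient pools drift within a run, cell
populations mix sizes across decades, and barcode-level artifacts
(index swapping, barcode collisions, doublets, damaged cells) produce
profiles that are neither ambient nor any single cell. Consequences to
expect on real data:

* Damaged or stripped cells deviate from the ambient profile and are
  *correctly* called non-empty; mitochondrial or ribosomal QC remains a
  separate, necessary step.
* Cells whose profile genuinely matches the ambient pool (homogeneous
  samples, or a subpopulation that dominates the pool) are only
  recoverable through the knee retention rule.
* On sloping plateaus the knee sits at the top of the bend; users
  wanting CellRanger-like behaviour there should set `knee_override`
  from the diagnostic rank-curve export rather than trust the curvature
  knee.
* The FDR guarantee is an expectation over the DM null with plugged-in
  $\tilde p_g$ and $\hat\alpha$; severe misestimation of the ambient
  profile (e.g., many true cells below $T$) biases it.

# Parameter summary

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `lower` ($T$) | ambient pool threshold (UMI) | 100 | inclusive: $t_b \le T$ is pooled, $t_b > T$ is tested |
| `n_iters` ($R$) | Monte Carlo iterations | 10,000 | p-value floor $1/(R+1)$; raise for FDR thresholds below 0.1% |
| `fdr_threshold` | calling working point | 0.001 | BH-adjusted |
| `alpha` | DM scale override | estimated | bounded MLE over $\log_{10}\alpha \in [-2,4]$ |
| `knee_override` | manual $U$ (UMI) | none | wins over the detected knee |
| `ignore_knee` | disable retention | `FALSE` | $U = \infty$; calls rest on p-values alone |
| `sampler` | null sampler | `"urn"` | `"naive"` is the verification oracle |
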