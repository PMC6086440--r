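---
title: "Methods: monophyly odds, topological ESS and MCC summaries from posterior tree sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: posterior tree-set analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PosteriorTrees)
```

# The statistical problem

A Bayesian phylogenetic analysis returns not one tree but a posterior
sample of thousands of trees. Questions about clades then become
questions about that sample: the posterior probability that a taxon set
is monophyletic is estimated by the fraction of sampled trees that
contain the clade, and is communicated as the posterior odds
$P(H\mid D)/(1-P(H\mid D))$. This vignette documents the model
assumptions, estimators, parameter choices and numerical conventions
the package uses, and what its synthetic-data tests do and do not
establish.

# Monophyly tests and the zero-frequency bound

`monophylyTest()` evaluates monophyly on **rooted** trees: a taxon set
is monophyletic iff some node's descendant leaf set equals it exactly.
Clock trees are rooted, and a rooted clade is the object a divergence
date attaches to; an unrooted bipartition option exists in the distance
layer (`unrooted = TRUE`) but is off by default.

When the clade frequency is strictly between 0 and 1, the probability
and odds are exact sample quantities. Two boundary cases need care:

* **Frequency 0.** The sample cannot distinguish "probability 0" from
  "probability below the sample's resolution". An autocorrelated chain
  of $N$ trees carries about $ESS$ independent draws, so absence from
  all of them supports only the bound $P(H \mid D) < 1/ESS_{topology}$.
  Both topological ESS bases ("P" pseudo, "A" approximate, below) are
  always reported side by side; no "best" basis is chosen, because the
  two estimators fail in different ways and a reader should see both.
* **Frequency 1.** The sampler is silent about this case; the root
  clade always triggers it. We report the symmetric lower bound
  $P(H\mid D) > 1 - 1/ESS_{topology}$, by the same argument applied to
  the complement.

The bound is exactly $1/ESS$ as computed — rounding (three decimals for
exact odds, two significant figures for bounds, as in published
posterior-odds tables) happens only in the report layer
(`formatMonophylyReport()`).

When two independent MCMC chains are supplied, `runMonophyly()` tests
each chain separately and the pooled trace, and shows all three;
pooling is never implicit, so disagreement between chains stays
visible. Bayes-factor monophyly tests are deliberately out of scope:
they require prior probabilities of topological hypotheses that are
hard to justify, whereas posterior odds need none.

# Path distance and the three ESS estimators

Topologies are compared by the **path distance**: for each taxon pair
$(i,j)$, $p_{ij}(T)$ counts the edges on the $i$–$j$ path, and
$d(T_1,T_2) = \lVert p(T_1)-p(T_2)\rVert_2$. Branch lengths are
ignored (topological convergence is the target and the metric becomes
invariant to clock scaling), and trees are treated as rooted by
default, so the root's degree-2 node contributes edges.

* `scalarESS()` is the Tracer-style estimator
  $N / (1 + 2\sum_k \hat\rho_k)$ with the autocorrelation sum truncated
  at the first negative $\hat\rho_k$ and capped at
  $K_{max} = \min(N-1, 2000)$ — the standard desk-scale behaviour,
  robust to noisy tails. Results are clamped to $[1, N]$; values
  outside indicate estimator noise, not information.
* `pseudoTopoESS()` draws `nFocal = 20` focal trees uniformly with
  replacement (seeded), forms the distance series to each focal tree,
  applies `scalarESS()`, and reports the per-replicate values and their
  median. The median is the quoted $ESS_{topology}$ (basis "P").
* `approxTopoESS()` forms the topological autocorrelation
  $\rho_{topo}(k) = \max(0,\, 1 - \bar D(k)/\bar D_\infty)$, where
  $\bar D(k)$ is the mean distance between samples $k$ apart and
  $\bar D_\infty$ the mean over all pairs of distinct samples, then
  $ESS = N/(1+2\sum_k \rho_{topo}(k))$ truncated at the first zero
  term, with `maxLag` defaulting to $\min(N-1, 100)$ (basis "A").

**A numerical choice that matters.** $\bar D_\infty$ enters every lag
term, so any error in it is multiplied by up to `maxLag`. Estimating it
from 500 random pairs (an obvious cheap choice) carries a relative
error of order $1/\sqrt{500} \approx 4\%$, which we observed turning a
near-i.i.d. chain's $ESS/N \approx 1$ into $\approx 0.2$. Because all
distances are computed on the matrix of *distinct* topologies anyway,
the package computes $\bar D_\infty$ **exactly** as the
frequency-weighted mean over all ordered pairs of distinct samples
(denominator $N^2 - N$; same-topology pairs contribute distance 0)
whenever the distinct-topology count $U$ satisfies $U^2 \le 4\times
10^6$, and falls back to the seeded-pair estimate (knob `nPairs`) only
beyond that.

On the sticky-chain oracle (below) with $\alpha \in \{0.5, 0.8\}$ both
topological estimators recover $N(1-\alpha)/(1+\alpha)$ within a few
percent at $N = 20{,}000$; the test suite asserts 25%, and 15% for
`scalarESS()` on an AR(1) trace, matching what the truncated-sum
estimator can guarantee at these lengths.

# MCC trees, ages and HPD intervals

`mccTree()` scores every **sampled** tree by
$\sum_{\text{clades}} \log f(\text{clade})$ over its non-trivial
internal clades (leaves and the root clade excluded — they score 0 or
are shared by all trees) and returns the argmax; no consensus tree is
synthesised, so the summary tree is always a tree the sampler actually
visited. Ties go to the earliest sampled tree and are flagged.

`annotateAges()` collects, for each MCC clade, the ages of the matching
node in every trace tree **containing that clade** (no common-ancestor
fallback: mixing ages of non-homologous nodes blurs the estimate), and
attaches the posterior median and the HPD interval. Child medians can
exceed a parent's median because they are computed over different tree
subsets; such inversions are reported as-is with a warning, never
clipped. Clades below a support floor (default 0.5) keep their
summaries but are flagged.

`hpdInterval()` is the smallest-width window over the sorted samples
containing $\lceil level \cdot n\rceil$ points, earliest window on
ties. Published "95% CI" labels rarely say whether they are HPD or
central intervals; HPD is assumed (it is what standard tree annotators
emit) and a central-interval option is provided.

Node ages require ultrametric trees; `nodeAges()` accepts a relative
tolerance of $10^{-6} \times$ tree height by default, covering
floating-point drift in exported trees, and otherwise reports the
root-to-leaf spread it found.

# The synthetic-data generators

**Sticky chain (the estimator oracle).** The chain stays at the
current rooted topology with probability $\alpha$ and otherwise
regenerates from a stationary law $\pi$ over all $(2n-3)!!$ rooted
topologies (enumerated exhaustively; $n \le 6$). This kernel was chosen
over, say, NNI random walks precisely because everything about it is
closed-form: the stationary law is $\pi$, any clade's probability is
$\sum \pi$ over topologies containing it (computable by enumeration),
indicator autocorrelations are $\alpha^k$, and the autocorrelation time
is $(1+\alpha)/(1-\alpha)$. Every estimator in the package is tested
against these exact values. What the sticky chain does *not* emulate:
real tree-space samplers make local moves, so their distance traces
decay smoothly rather than by regeneration; passing these tests shows
estimator correctness under known mixing, not sampler-specific
behaviour.

**Birth–death + relaxed clock + GTR+Γ+I.** `simulateBDTree()` runs the
birth–death process forward from a crown pair, stops at the first
passage to $n$ extant lineages plus a uniform fraction of the next
inter-event wait (so terminal branches are positive), prunes extinct
lineages, and conditions on reaching $n$ by rejection (budget $10^5$
attempts). This simple first-passage convention is not the exact
conditioned birth–death distribution, but it is unbiased in the
properties the tests rely on (leaf count, ultrametricity,
reproducibility) at the small $n$ used.

Branch rates are i.i.d. lognormal with the **real-scale mean** pinned
to `ucldMean` (log-scale mean $\ln(ucldMean) - s^2/2$) and log-scale
standard deviation `ucldStdev` — stated explicitly because both
conventions exist in the wild. Defaults follow the standard insect
mitochondrial calibration: 0.0115 substitutions/site/Myr (0.004 in
nuclear mode, chosen to give a comparable tree height; a nuclear
time-scale should not be interpreted).

Sequences evolve under GTR (matrix normalised to one expected
substitution per unit at equilibrium, so branch length × rate reads as
substitutions/site) with among-site variation from **mean-based
equal-probability discrete gamma** categories (default shape 11.1 —
a prior coefficient of variation of about 0.3 — with six categories;
the mean-based convention matches standard inference software, and the
category means average to exactly 1 by construction) plus invariant
sites with proportion `pInv`. `sampleModelPriors()` draws full
configurations from the generative priors — Lognormal(1, 1.25)
speciation rate, Beta(1, 2) relative extinction, Gamma(1, 1)
exchangeabilities, Gamma(shape 0.5396, scale 0.3819) `ucldStdev`,
Uniform(0,1) `pInv`, Dirichlet(1) base frequencies. The lognormal
prior's parameters are taken as log-scale mean/sd (the convention of
the usual inference software); this only affects prior-predictive
mode.

What the sequence simulator does not emulate: indels (the intended
mitochondrial alignments are indel-free), codon structure, selection,
and base-composition heterogeneity across lineages. Tests passing on
these simulations validate the estimators' arithmetic and calibration,
not robustness to model violations in field data.

# I/O conventions and degenerate inputs

* Newick parsing is a recursive-descent parser reporting the character
  position of any syntax error; quoted labels are supported and
  underscores inside labels are kept verbatim (sample ids like
  `GY018_borb` depend on it). `[&...]` comments are stripped by
  default or retained as node annotations.
* Branch lengths absent from the input are **missing**, never zero;
  age-dependent operations refuse trees with missing lengths.
* Burn-in applies to the retained (post-thinning) samples of a trees
  file — exactly $\lfloor fraction \times N\rfloor$ leading trees are
  discarded — because sampler outputs are conventionally already
  thinned.
* Canonical Newick output orders children by smallest descendant leaf
  label, making outputs byte-stable under input rotation; annotated
  NEXUS embeds `[&posterior=..,age_median=..,age_hpd={..,..}]` comments
  readable by standard viewers.
* Degenerate traces fail loudly: zero-variance scalar traces, traces
  with a single distinct topology (topological ESS undefined), empty
  groups in haplotype tables, non-ultrametric trees beyond tolerance.

# Problem sizes

The test suite and the acceptance script run sticky chains of
$N = 20{,}000$ on the 105-topology 5-taxon space, AR(1) traces of
$10^4$, HPD calibration over 500 replicates of $10^3$ draws, JC
recovery at $5\times10^4$ sites, and $10^4$ prior-predictive draws —
sizes at which every analytic tolerance above has comfortable
Monte-Carlo headroom on a single core.

# Known limitations

* The approximate topological ESS reproduces the documented behaviour
  of the commonly cited implementation (autocorrelation of topological
  distances) and is validated against the analytic sticky-chain
  oracle, but numerical equality with other software is not guaranteed.
* Monophyly bounds depend on the topological ESS being a fair measure
  of independent information; a sampler stuck in one island of tree
  space can have a deceptively high ESS and hence an over-tight bound.
* The MCC candidate set is the sample itself; with very diffuse
  posteriors the MCC tree can be a low-probability compromise.
* Haplotype identity is exact string equality after uppercasing; IUPAC
  ambiguity codes are not expanded (an `N` makes a new haplotype), a
  conservative choice flagged by a strict-mode warning.
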