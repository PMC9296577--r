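---
title: "Ranking stable reference genes across expression compendia: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking stable reference genes across expression compendia: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refrank)
```

# The problem

Normalization of relative expression measurements assumes that the
reference genes in the denominator are unaffected by the biology under
study. That assumption is routinely violated by the habitual references
(*Gapdh*, *Actb*, rRNAs), and a gene that is stable in one tissue or
condition need not be stable in another. `refrank` therefore treats
reference-gene selection as a ranking problem over *all* genes measured
in a compendium of public expression studies of the tissue and condition
at hand, with no candidate preselection.

# The scoring model

## Per-study criteria

Within one study (genes × samples, linear scale, every sample labelled
condition or control) each gene receives two numbers:

* the **coefficient of variation** over all samples,
  $\mathrm{CV}_i = s_i / \bar{x}_i$, with the sample ($n-1$) standard
  deviation. The CV is unitless, so genes of very different absolute
  expression compare on one scale, and it implicitly favors high
  expression, because the CV of intensity data shrinks as expression
  grows — a desirable bias, since low-expression genes make poor qPCR
  references. The $n-1$ denominator is a convention choice; with the
  typical 6–20 samples per study it shifts all CVs by the same factor
  and leaves their ranks untouched.
* the **inverted fold change** between group means,
  $\mathrm{FC}_i = \max(r_i, 1/r_i)$ with
  $r_i = \bar{x}_{i,\mathrm{cond}} / \bar{x}_{i,\mathrm{ctrl}}$. Values
  start at 1 (no condition effect); direction is deliberately discarded.
  The fold change is taken on raw group means rather than through a
  moderated differential-expression fit: for ranking (not testing) the
  plain ratio is sufficient, monotone in the evidence, and free of
  distributional assumptions.

Both criteria are ranked ascending within the study with average ties
and combined as the rank product
$\mathrm{RP}_i = \mathrm{rank}(\mathrm{CV}_i) \times
\mathrm{rank}(\mathrm{FC}_i)$. The rank product is then *re-ranked* to
give the study's per-gene rank. Re-ranking matters when studies measure
different numbers of genes: raw rank products from a 20,000-gene array
and a 5,000-gene array live on different scales, whereas their re-ranked
versions are directly comparable. Only these ranks leave the study, which
is what lets heterogeneous platforms be combined with no cross-platform
normalization.

## Aggregation by dataset-level bootstrap

The unit of resampling is the **study**, not the sample: the question the
bootstrap answers is "how would the ranking change had a different mix of
studies been available?", i.e. robustness to study-selection bias. Each
of $B$ repetitions draws $D$ studies with replacement from the $D$
available; a gene's repetition score is the mean of its per-study ranks
over the drawn studies in which it was measured, and genes are re-ranked
by that mean (ascending, average ties), yielding one bootstrap rank per
gene per repetition. Two conventions keep the per-repetition ranking
defined:

* a gene absent from every drawn study scores the universe size $G$ —
  the worst plausible rank — for that repetition;
* ties are averaged everywhere, so each repetition's ranks always sum to
  $G(G+1)/2$ (a property the test suite checks).

The final score penalizes genes measured in only part of the compendium,
$$\mathrm{score}(i) = \overline{\mathrm{rank}}_i \times
\frac{D}{\mathrm{presence}(i)},$$
a multiplicative penalty chosen because it is monotone (losing a study
never helps — also property-tested), preserves the rank scale, is
neutral for fully present genes, and sends never-measured genes to
$+\infty$ so they cannot be reported. Residual score ties break
lexicographically on gene id, making the output deterministic given the
seed.

# The stability cross-check

Candidates can be cross-validated on an independent study with a
NormFinder-style stability value. With $z_{ig}$ the mean log2 expression
of gene $i$ in group $g$, $\alpha_i$ the gene's mean over groups and
$\theta_g$ the *centered* group effect (group mean of $z$ over genes
minus the grand mean), the gene-by-group residual is
$f_{ig} = z_{ig} - \theta_g - \alpha_i$ and the stability value
$$\rho_i = \left| \mathrm{mean}_g(f_{ig}) + \mathrm{sd}_g(f_{ig}) \right|,$$
with $\rho_i < 0.15$ (log2 units) calling the gene stable. Two design
choices deserve justification:

* **Centering $\theta_g$.** An uncentered group effect (the raw group
  mean of log expression) would assign nonzero $\rho$ to a data set in
  which every gene is perfectly constant, which no stability measure
  should do. Centering restores $\rho = 0$ for constant data and shifts
  every gene's $f_{ig}$ by the same per-group constant, so relative
  comparisons are unchanged. A consequence worth knowing: after
  centering, $\mathrm{mean}_g(f_{ig}) = 0$ identically, so $\rho_i$
  reduces to the standard deviation of the residuals over groups.
* **One $\rho$ per gene.** The residuals are aggregated over groups into
  a single per-gene value; that is the only reading under which "mean
  plus standard deviation of $f$" is well defined.

$\rho$ is invariant to adding a constant in log space (multiplying
linear expression by a constant), which the tests verify. This is a
deliberately lightweight rendition: the original NormFinder
variance-decomposition estimator with candidate pairing is out of scope.

# Concordance statistics

Agreement between candidate lists uses the overlap coefficient
$|A \cap B| / \min(|A|, |B|)$; the reproducibility measure $R$ is the
mean pairwise overlap of top-$k$ lists over repeated runs ($k = 50$ by
default; shorter lists are used whole, with a warning). Overlap
significance uses the one-sided hypergeometric tail
$P(X \ge k_{\mathrm{overlap}})$ with the ranking's gene universe as the
population — the standard test for fixed-size list intersections; the
implementation is `stats::phyper`, checked in the tests against direct
enumeration of the hypergeometric mass on small universes.

A caveat on $R$ as a metric: it is a set statistic with a hard boundary
at $k$. When two genes have (near-)identical expected scores *at the
boundary*, which seed wins slot $k$ is a coin flip in every run, and the
expected $R$ has a floor of $(k - m + c)/k$ for $m$ churning genes no
matter how many bootstrap repetitions are used. Observing $R$ slightly
below 1 therefore need not indicate algorithmic instability — inspecting
the penalized scores around position $k$ distinguishes a genuine
instability from an exact tie.

# qPCR normalization

The comparative method: per sample,
$\Delta Ct = Ct_{\mathrm{target}} - Ct_{\mathrm{ref}}$;
$\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{\mathrm{control}}$;
relative expression $= 2^{-\Delta\Delta Ct}$, with amplification
efficiency fixed at 2 (no efficiency correction). A multi-gene panel is
combined as the per-sample arithmetic mean of the member Cts — the
geometric mean of their linear expression, the standard multi-reference
practice. The panel's value is dilution of single-gene instability: a
reference gene shifted by $+1$ cycle in the condition group inflates the
target's apparent fold change $2\times$ when used alone but only
$2^{1/k}\times$ inside a $k$-gene panel (an algebraic identity the tests
check). Group summaries are reported as mean ± SEM of per-sample fold
changes.

# The synthetic compendium

Real compendia for a given tissue/condition are heterogeneous in
platform, scale, and gene coverage. The simulator emulates exactly those
features with a log-normal multiplicative noise model: per study and
gene, log2 expression is Gaussian around a study-specific baseline with
$\sigma_{\log_2} = \sqrt{\ln(1 + \mathrm{CV}^2)}/\ln 2$, which makes the
linear-scale CV equal the target CV exactly. Three planted roles form
the ground truth:

| role | baseline (log2) | noise CV | condition effect |
|---|---|---|---|
| stable (50 of 2000) | uniform 10–14 | 0.05 | none (FC = 1) |
| responsive (200) | uniform 4–12 | 0.30 | FC uniform 2–8, up or down |
| background (rest) | uniform 4–12 | 0.30 | none |

Defaults: 4 studies, 10 samples per group, 10% of genes dropped
independently per study (never all planted ones), half the studies
emitted log2-scale. The noise levels bracket what microarray
compendia show — a few percent CV for strong housekeeping genes, tens of
percent for typical genes across heterogeneous samples — and 2–8-fold
planted effects are ordinary differential-expression magnitudes. Roles
are assigned at random from the seed, or explicitly via
`stable_genes`/`responsive_genes`, which is how compendia with disjoint
planted truths are built for negative controls.

What the simulator does *not* emulate: probe-level artifacts,
within-study batch structure, correlated genes, count noise of RNA-seq,
or platform-specific intensity response. Recovery of planted genes on
this generator therefore demonstrates that the pipeline is correct and
robust to scale mixing, dropout and study resampling — not that any
particular recovery rate will transfer to real compendia.

# Numerical and interface choices

* **Log-scale detection**: a matrix is called log2 when its 99th
  percentile is ≤ 30. Log2 intensities live roughly in [0, 20]; linear
  ones reach thousands. The 99th percentile (rather than the maximum)
  makes the call robust to a handful of corrupted or saturated entries.
  Base 2 is assumed for exponentiation throughout.
* **Probe collapsing**: per gene, the probe with the highest mean
  expression is kept. Averaging would blend cross-hybridizing probes of
  very different intensity; the max-mean probe is the conventional
  best-responding proxy. Ties break by input order.
* **Missing and nonpositive values**: any gene row with a missing value
  (including `null` tokens in series-matrix files) or a nonpositive
  linear value is dropped from that study and treated downstream as
  absent — CV and fold change are undefined for it, and no imputation is
  attempted.
* **Gene harmonization** unions, never intersects, gene sets: a gene
  missing from one platform still competes, carrying its absence
  penalty. Cross-organism compendia require an ortholog table; genes are
  renamed to ortholog-group ids and never invented.
* **Determinism**: all randomness flows from a single integer seed; the
  same invocation reproduces every output file byte-for-byte, and each
  file-level run writes a session JSON with every parameter.

# Problem sizes

The bundled end-to-end checks run the default 4-study, 2000-gene
compendium with 1,000 bootstrap repetitions (ten seeds for the
reproducibility measure), a held-out study for the stability
cross-check, and 500-repetition runs for the disjoint-truth negative
control; the exact-oracle comparisons use two studies over five genes
(enumerable resampling multisets) and hypergeometric universes up to
100. These sizes keep the full suite in the tens of seconds while still
exercising tie handling, dropout, mixed scales and the absence penalty;
production use with the 10,000-repetition default on genome-scale
universes takes minutes.

# Known limitations

* The ranking is a heuristic composite; it carries no per-gene error
  control, and no p-value is attached to a gene's stability.
* The fold change uses raw group-mean ratios; confounders within a study
  (batch, covariates) are not modelled — the bootstrap addresses
  between-study sampling, not within-study confounding.
* The absence penalty's multiplicative form is one reasonable monotone
  choice among several; genes measured in few studies are ranked
  conservatively by construction.
* $R$'s boundary-tie sensitivity (above) means values marginally below 1
  should be read together with the score gaps around the truncation
  point.
* The stability score is the lightweight rendition described here, not
  the full NormFinder estimator.
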