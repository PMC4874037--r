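---
title: "Integrative pathway analysis with ipanet: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative pathway analysis with ipanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipanet)
```

`ipanet` combines pathway enrichment evidence from a gene-expression
matrix and a metabolite-abundance matrix measured on the same two-class
tissue samples, and validates the nominated pathways on the
pathway-interaction network. This vignette is the package's account of the
statistics it implements: the models and their assumptions, the tunable
parameters, the numerical choices, and what the synthetic-data tests do
and do not establish about real data.

## The two enrichment layers

### Gene layer: maxmean with restandardization

Per-gene evidence is the Welch two-sample *t* statistic (class 2 minus
class 1), robust to unequal class variances. A pathway with member
statistics $z_1,\dots,z_m$ is scored by the maxmean statistic
$$s = \begin{cases} s^+ & s^+ \ge s^- \\ -s^- & \text{otherwise}
\end{cases}, \qquad
s^+ = \tfrac1m \sum_i \max(z_i, 0),\quad
s^- = \tfrac1m \sum_i \max(-z_i, 0),$$
which retains power both when a few members move strongly and when many
move weakly in a common direction. Raw maxmean values depend on set size,
so each score is restandardized against a catalog of randomly drawn gene
sets of the same size: $s^* = (s - \mu_{\text{set}})/\sigma_{\text{set}}$,
with the catalog mean and SD recomputed under every label permutation from
the same frozen catalog draws. Significance is by class-label permutation,
$$p = \frac{1 + \#\{\,|s^*_{\text{perm}}| \ge |s^*_{\text{obs}}|\,\}}
{n_{\text{perm}} + 1},$$
two-sided, because the integrative analysis cares about perturbation, not
direction. When the number of distinct class assignments is at most
`n_perm` (e.g. $\binom{4}{2} = 6$ for a 2 + 2 design), assignments are
enumerated exhaustively and the p-value is the exact proportion. Ranks are
assigned by ascending p-value, ties broken by descending $|s^*|$ and then
pathway id, so that every ranking is a deterministic permutation of
$1,\dots,J$ — a property the bootstrap SDs depend on. Ranking by p-value
rather than raw score is isolated in one internal function
(`rank_pathways()`) so the alternative is a one-line change.

### Metabolite layer: reaction network, influence matrix, mixed model

Metabolite evidence travels through the biochemical reaction network: an
edge joins two metabolites whenever they form a substrate–product pair of
at least one reaction (never substrate–substrate or product–product;
self-pairs are dropped; an optional exclusion list removes currency
metabolites such as water or ATP, empty by default). With $\bar A$ the
row-normalized adjacency and $\rho \in [0, 1)$ a propagation strength
(default 0.3), the influence matrix is
$\Lambda = (I - \rho \bar A)^{-1}$: finite for every admissible $\rho$
because $\bar A$ has spectral radius at most 1; the identity at
$\rho = 0$; identity rows for isolated metabolites. Metabolites absent
from the network are attached as isolated nodes rather than dropped so
pathway eligibility is stable; metabolites removed by preprocessing are
removed from the network, since they cannot be modeled.

The per-sample model for sample $i$ in class $k$ is
$$y_i = \Lambda\beta_k + \Lambda\gamma_i + \varepsilon_i,\qquad
\gamma_i \sim N(0, \sigma_g^2 I),\ \varepsilon_i \sim N(0, \sigma_e^2 I),$$
so $y_i \sim N(\Lambda\beta_k,\ \Sigma)$ with
$\Sigma = \sigma_g^2\Lambda\Lambda' + \sigma_e^2 I$. The components are
estimated by REML after rotating into the eigenbasis of
$\Lambda\Lambda'$, where the model is diagonal; a method-of-moments fit
serves as the starting point and as a fallback if the optimizer fails to
converge (with a warning). Pathway $j$ with unit-sum membership vector
$b_j$ is tested through the contrast $\ell_j'(\hat\beta_2 - \hat\beta_1)$
with $\ell_j = \Lambda' b_j$.

**Why the default SE comes from the projected profile.** With a single
invertible influence matrix shared by both classes, the GLS estimate is
$\hat\beta_k = \Lambda^{-1}\bar y_k$ *regardless of* $\Sigma$, so the
contrast reduces algebraically to $b_j'(\bar y_2 - \bar y_1)$ — the
between-class difference of the projected per-sample profile
$u_i = b_j' y_i$. Under the model the $u_i$ are i.i.d. normal within
class, so estimating the contrast variance from the sample variance of
$u_i$ yields an *exact* $t_{n-2}$ reference distribution — including at
$\rho = 0$, where the test coincides, to machine precision, with the
classical two-sample *t*-test on pathway-mean profiles. This is the
default (`se_method = "profile"`). The component-based alternative
(`se_method = "model"`) plugs the REML estimates into
$\mathrm{SE}^2 = (1/n_1 + 1/n_2)(\sigma_g^2\|\Lambda' b_j\|^2 +
\sigma_e^2\|b_j\|^2)$ with Satterthwaite degrees of freedom from the REML
information matrix; it lets the network modulate the precision attributed
to well-connected pathways, at the price of an approximate reference
distribution and a residual model pooled across all metabolites. Both
routes report the REML components; the recovery of generating values is
exercised in the test suite (within 50 % relative error at $n = 28$,
$p = 60$). Reaction stoichiometry is carried as optional edge weights but
unused by default — no principled weighting scheme is available at this
level of abstraction.

## Bootstrap aggregation and the combined score

Each layer's ranking is recomputed on `n_boot` stratified bootstrap
resamples (samples drawn with replacement within class, class sizes
preserved; default 1,000). Resamples in which a class collapses to one
distinct sample are redrawn and counted. With $R(j,\cdot)$ and
$S(j,\cdot)$ the mean and SD of pathway $j$'s rank over resamples, the
combined score is
$$R(j) = \frac{J + 1 - R(j,G)}{\max(S(j,G), s_\text{floor})} +
         \frac{J + 1 - R(j,M)}{\max(S(j,M), s_\text{floor})}.$$
The printed form of this equation is typographically ambiguous; the
package reads it as variability-normalized reversed ranks, which matches
its description as a mean of *normalized* rankings — the alternative
$(J+1) - R/S$ reading remains available via
`combined_score(variant = "reversed_minus_ratio")` for sensitivity
analysis. The SD floor (default 0.5, half a rank unit — the smallest
meaningful rank uncertainty) prevents division blow-up when a pathway
holds the same rank in every resample; the score of such a stable
top-ranked pathway is then exactly $2(J)/0.5$ at $J = 87$: 348.

Outliers are nominated by an iterative one-sided Grubbs test: while the
maximal score is a significant upper outlier at `alpha_outlier` (default
0.03), flag and remove it, up to a cap (default 10). The Grubbs p-value is
the standard $t$-based form with the Bonferroni-style $N$ multiplier.

**The outlier test is a nomination heuristic, not a calibrated test.**
Bootstrap resamples share on average ~63 % of the samples, so a pathway
that happens to look enriched in the observed noise realization keeps a
high rank with a small rank SD across resamples. The null distribution of
$R(j)$ is therefore heavy-right-tailed, and a normal-theory outlier test
on it flags at least one pathway in a large fraction of pure-noise
datasets — a property the package's own null-calibration test documents
rather than hides. Nominations should be read as "most extreme under this
score", with error control delegated to the downstream permutation test;
the per-layer enrichment p-values themselves are calibrated (the
permutation test is exact under label exchangeability, and the profile-SE
metabolite test is exact under the model).

Concordance between the layers is the fraction of pathways whose rank
difference $d_j = \text{rank}_G(j) - \text{rank}_M(j)$ lies within one SD
of all differences, using centered differences
$|d_j - \bar d| \le \mathrm{sd}(d)$; when both rankings are complete
permutations of the same set, $\bar d = 0$ and the centered and uncentered
readings coincide.

## The neighbor permutation test

The pathway-interaction graph joins pathways whose members interact
across pathways: a reaction edge with one endpoint in each membership, or
a curated gene–gene link. Shared members alone are *not* edges —
biochemical pathways share hub metabolites so liberally that overlap
edges would make the graph near-complete and destroy the permutation
test's discrimination.

Enrichment labels are computed once from the observed gene ranking:
pathways interacting with the nominated set are re-ranked among
themselves and the top `top_frac` (default 50 %, ceiling rule) flagged;
all remaining nodes are labelled by the same rule applied to the global
ranking so that labels are total — randomized graphs have different
neighborhoods and must always be scorable. This labelling rule is the one
genuinely under-determined step of the published procedure; it is
isolated in `label_enriched()` and recorded in the labels' provenance
attribute.

For nominated pathway $j$, $N(j)$ counts enriched neighbors, and $B$
random networks are drawn by double edge swaps (two edges with four
distinct endpoints rewired unless a duplicate would result), each a fresh
chain of `n_swaps` attempts (default $10|E|$) restarted from the observed
graph and seeded `seed + b` — independent draws, not a single long chain.
The chain preserves every node's degree exactly and has the uniform
distribution over simple graphs with that degree sequence as its
stationary law. The reported p-value uses the strict inequality
$P(j) = \#\{N(j,b) > N(j)\}/B$ as published; it is anti-conservative by
at most $1/B$ relative to the $\ge$ version, and the conventional
add-one $\ge$ estimator is always reported alongside (`P_geq`). Whether
ties were counted in the original procedure is not recoverable; reporting
both resolves the ambiguity transparently.

## The synthetic study generator

`generate_study()` emulates the statistical structure the pipeline
assumes: a 16 + 12 two-class design; 87 pathways whose gene and
metabolite memberships form a ring, each pathway sharing a fraction
(default 0.25) of its successor's members — overlap keeps the
pathway-interaction graph connected, which the secondary analysis needs;
within-pathway reaction chains plus Poisson-distributed cross-pathway
reactions (mean 30); additive Gaussian noise on the log2 scale (the
simplest model consistent with the two-sample statistics the pipeline
applies to normalized microarray/LC-MS intensities); planted pathways
whose class-2 member means shift by `delta × noise_sd`; and
completely-at-random metabolite missingness (default 10 %). Pathway sizes
default to 5–30 genes and 3–15 metabolites; the calibration simulations
in the test suite use the low end of those ranges (5–8 genes, 3–5
metabolites per pathway) so that hundreds of replicates fit in a routine
test run — the statistical properties checked are size-stable.

What the generator does *not* emulate: probe effects, batch structure,
LC-MS peak artifacts, informative missingness, correlated noise between
layers, or realistic pathway-size distributions. Passing tests on
synthetic data therefore establish the pipeline's *statistical
correctness under its own assumptions* — calibration of p-values,
recovery of planted signal, exactness of the graph-permutation reference
— not robustness to the technical artifacts of real platforms.

## Preprocessing

The preprocessing step is deliberately plain and fully surfaced in
configuration: features missing in more than `max_missing_frac` of
samples (default 0.3) are removed; remaining missing metabolite entries
are imputed with half the feature's observed minimum (the field standard
for left-censored LC-MS intensities), gene entries with the feature
median; optional log2; per-sample median centering. Imputation happens on
the raw scale, before the log transform. With the log transform off the
operation is idempotent, feature count never increases, and output column
medians are zero — all tested.

## Numerical and design details

* All randomness flows from explicit seeds; stage seeds are fixed offsets
  of one master seed, and run logs contain no wall-clock content, so two
  runs from the same configuration are byte-identical (tested).
* Rank tie-breaking is fully deterministic (p, then $|s^*|$, then id).
* Catalog SDs in the restandardization are floored at $10^{-12}$;
  a zero-variance gene in both classes scores 0 with a warning.
* Grubbs at the degenerate maximum $G = (N-1)/\sqrt{N}$ (all other values
  equal) gets p = 0: it is the most extreme configuration possible.
* Pathway eligibility floors: 5 genes and 3 metabolites present (both
  configurable); ineligible pathways keep their graph node but receive no
  enrichment score. When the two layers' eligible sets differ, the
  combined table is restricted to their intersection and the rank scale
  extended to the largest observed mean rank.
* Problem sizes used by the shipped checks: the calibration suite runs
  200 null and 50 planted replicates at `n_boot = 100` with reduced GSA
  permutation counts inside the bootstrap (ranks, not p-values, are
  consumed there); the acceptance script runs one full study at
  `n_boot = 1000`, `B = 10000`.

## Known limitations

* The combined score has no calibrated null (see above); treat Grubbs
  flags as nominations.
* The influence matrix affects the default metabolite test only through
  eligibility and the model diagnostics, because the shared-Λ GLS
  contrast is algebraically network-free; network-weighted *inference*
  requires `se_method = "model"`, whose Satterthwaite reference is
  approximate.
* Reactions are undirected and unweighted by default; reversibility and
  stoichiometric magnitude are not modeled.
* Exactly two omics layers; no meta-combination of more.
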