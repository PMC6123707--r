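---
title: "Methods: phylogenetic mixed-model meta-analysis of mycorrhizal growth responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic mixed-model meta-analysis of mycorrhizal growth responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Most land plants trade carbon for soil nutrients with mycorrhizal fungi, but
the net effect of inoculation on plant growth ranges from strong mutualism to
parasitism. `mycometa` implements a meta-analytic pipeline for asking how much
of that variation is attributable to evolutionary history — early
phylogenetic divergence of hosts and symbionts, recent diversification,
independent evolutionary origins of the ectomycorrhizal (EM) lifestyle, and
evolved host–symbiont specificity — versus contemporary ecological context
(fertilization, soil sterilization, additional microbes, and so on), across
a database of inoculation trials spanning hundreds of plant species and
dozens of fungal genera.

## Effect sizes

Each trial contributes a log response ratio
$$\mathrm{LRR} = \ln\left(\bar x_{\mathrm{inoc}} / \bar x_{\mathrm{ctrl}}\right),$$
the log of mean inoculated over mean non-inoculated plant biomass, with
large-sample sampling variance
$$\hat\sigma^2 = \frac{SD_{\mathrm{inoc}}^2}{n_{\mathrm{inoc}}\,\bar x_{\mathrm{inoc}}^2}
              + \frac{SD_{\mathrm{ctrl}}^2}{n_{\mathrm{ctrl}}\,\bar x_{\mathrm{ctrl}}^2},$$
equivalently $CV_{\mathrm{inoc}}^2/n_{\mathrm{inoc}} + CV_{\mathrm{ctrl}}^2/n_{\mathrm{ctrl}}$.
For reporting, effect sizes are transformed to percent growth response,
$100(e^{\mathrm{LRR}}-1)$.

Trials that report means and replicate counts but no dispersion get their
missing coefficient of variation replaced by the **median CV** among rows of
the same analysis subset that did report SDs, and are flagged
(`variance_imputed`). Two choices here were genuinely open:

* *Pooling.* The median CV is taken over the pooled vector of inoculated and
  control CVs (`cv_pooling = "pooled"`, the default); separate per-group
  medians are available (`"per_group"`). Pooling uses all available
  dispersion information and is robust when one group's SDs are
  systematically less often reported.
* *Sided imputation.* A row missing only one SD keeps its reported side and
  receives the median CV on the missing side only; only dispersion is ever
  imputed — rows with missing means or replicate counts are rejected.

Computed variances are floored at `var_floor` (default `1e-8`), because a
reported SD of exactly zero would give an infinite meta-analytic weight;
flooring warns rather than failing.

Analyses run on three subsets: **AM-full** (all arbuscular mycorrhizal rows,
including multi-genus inocula), **AM-sub** (AM rows inoculated with a single
fungal genus) and **EM** (single-genus ectomycorrhizal rows); mixed AM+EM and
multi-genus EM rows are dropped with a reported count
(`partition_datasets()`).

## The multilevel meta-analytic mixed model

Effect sizes are modelled as
$$y = X\beta + \sum_k Z_k u_k + e, \qquad
  u_k \sim N(0, \sigma^2_k R_k), \qquad
  e \sim N(0, \mathrm{diag}(\hat v_i)),$$
where each random-effect term couples an incidence map $Z_k$ with a
correlation matrix $R_k$ (`cov_structure`). The shared term set
(`build_structures()`) is:

| term | $R$ | meaning |
|---|---|---|
| `plant_phylogeny` | Brownian | phylogenetically heritable host variation ("early" divergence) |
| `plant_species` | identity | non-heritable host variation ("recent" divergence, plasticity) |
| `fungal_phylogeny` | Brownian | heritable symbiont variation |
| `fungal_genus` | identity | non-heritable symbiont variation |
| four plant × fungus interactions | tensor products | evolved specificity at each depth |
| `study_id` | identity, one level/observation | residual between-studies heterogeneity ($\tau^2$); always included |
| `control_set` | identity | non-independence of effect sizes sharing a control group |
| `paper` | identity | non-independence within publications |

EM analyses add three origin terms (`plant_origin`, `fungal_origin`,
`plant_x_fungal_origin`) with identity correlation over origin clades —
independent evolutionary gains of the EM lifestyle are treated as
unstructured groups. AM-full analyses omit the six fungus-involving terms,
since multi-genus rows have no single fungal identity.

### Phylogenetic and tensor-product correlations

`brownian_correlation()` builds the Brownian-motion correlation: entry
$(i,j)$ is the shared root-to-MRCA path length divided by the maximum
root-to-tip depth, diagonal exactly 1. Shared paths are always measured on
the **full** tree, so restricting to a taxon subset is exactly a
row/column subset — the root and depth are never re-defined by pruning.
For non-ultrametric trees, raising the diagonal to 1 adds a non-negative
diagonal matrix and therefore preserves positive semi-definiteness; the
correlation convention (rather than a covariance convention) is required
because the model is parameterized as $\sigma^2_k R_k$ with unit-diagonal
$R_k$. A Pagel's-λ-style multiplier can shrink the off-diagonals
(default λ = 1, full Brownian motion; λ = 0 recovers the identity). λ is
fixed, not estimated.

`tensor_interaction()` builds interaction correlations by the element
product rule $R[(p,f),(p',f')] = R_P[p,p'] \cdot R_F[f,f']$, materialized
**only over the combinations realized in the data** (lexicographic
(plant, fungus) order), never via the full Kronecker product — real
datasets realize a few hundred of several thousand possible combinations.
On the full Cartesian set the result equals `kronecker(R_P, R_F)` exactly,
which is how it is tested.

### Likelihood and fitting

With $V = \sum_k \sigma^2_k Z_k R_k Z_k' + \mathrm{diag}(\hat v)$ and
$\beta$ profiled out by GLS, the package maximizes either the full (ML) or
restricted (REML) log-likelihood; REML includes the $+\tfrac12\log|X'X|$
constant used by standard meta-analytic software, so log-likelihoods are
directly comparable across tools.

Numerical choices:

* **Evaluation.** Terms whose $Z_k R_k Z_k'$ is diagonal (identity $R$, at
  most one observation per level — e.g. `study_id`) fold into the diagonal.
  The remaining terms are stacked as $U$ with $V = D + UU'$; when the total
  number of stacked columns $q$ is below $n$, $\log|V|$ and $V^{-1}$ come
  from the algebraically identical low-rank identity
  $\log|V| = \log|D| + \log|I_q + U'D^{-1}U|$ with sparse incidence
  algebra, which is what makes thousands of effect sizes and repeated
  profile evaluations tractable; the dense Cholesky of $V$ is kept as the
  $q \ge n$ fallback and as an independent oracle in the tests.
* **Optimization.** Components are parameterized on the SD scale with the
  non-negativity constraint enforced by a bounded quasi-Newton search
  (multi-start at $\{0.01, 0.1, 1\}\times$ a method-of-moments seed),
  with a derivative-free polish if a line search stalls at a boundary.
  Many true components sit exactly at zero, so boundary behaviour matters:
  estimates below `boundary_tol` ($10^{-8}$) are reported as exactly 0.
  Convergence tolerance is $10^{-8}$ on the relative log-likelihood change;
  all tolerances are configurable, and a fit that fails its formal
  convergence test is flagged, never silently accepted.
* **Profile CIs.** `profile_ci()` re-maximizes over all other components at
  each value of the focal one and brackets the points where the profile
  drops $\chi^2_1(0.95)/2 = 1.9207$ below its maximum (monotone bisection;
  lower endpoint truncated at 0; a profile that never drops on the upper
  side is reported as an open-ended bound and flagged). Warm starts from
  the previous profile point keep the inner optimizations cheap.

### Derived summaries

* `r2_summaries()`: the fixed-effect variance $\sigma^2_{\mathrm{fixed}}$ is
  the population variance (divide by $n$) of the fitted values $X\hat\beta$;
  the marginal $R^2$ is $\sigma^2_{\mathrm{fixed}}/D$ and each partial
  conditional $R^2$ is $\sigma^2_k/D$ with
  $D = \sigma^2_{\mathrm{fixed}} + \sum_k \sigma^2_k$. Sampling variances
  are excluded from the denominator because the summaries describe shares
  of *between-studies* variance; this definition reproduces published
  variance-share tables of this model family within rounding. Whether
  $\sigma^2_{\mathrm{fixed}}$ belongs in the denominator is not universally
  agreed, so the components-only alternative is retained behind
  `denominator = "components_only"`.
* `overall_mean()`: intercept of the intercept-only REML fit with all
  applicable random terms, reported on the percent scale. The percent-scale
  SE convention is not standardized, so both the delta-method SE
  ($100 e^{\hat\mu} \cdot se$) and back-transformed Wald endpoints are
  reported.
* `meta_blups()`: $\hat u_k = \sigma^2_k R_k Z_k' V^{-1}(y - X\hat\beta)$
  with SEs from the standard prediction-variance expression.
  `blup_matrix()` arranges interaction BLUPs over realized (plant, fungus)
  cells (unrealized cells are absent, not zero) with marginal means across
  realized cells — the data behind paired-phylogeny heat maps; rendering
  itself is out of scope. The matrix shows the single named interaction
  term, not a sum of nested terms; summing is left to the caller since
  which terms to pool is display-specific.
* `marginal_means()`: model-based means for one predictor with the others
  held at their observed proportions (an unbalanced meta-dataset's natural
  weighting; equal weighting is available), plus covariate-adjusted
  observations for display.

## Model selection

`select_fixed_effects()` follows a two-stage procedure: random terms whose
saturated-model REML estimate falls below `gate` ($10^{-6}$, configurable)
are dropped; every candidate fixed-effect model — all main-effect subsets,
augmented under marginality with allowed two-way interactions — is then
fitted with the identical random structure and ranked by
$$\mathrm{AICc} = -2\ell + 2k + \frac{2k(k+1)}{n-k-1},$$
with Akaike weights $w_m \propto e^{-\Delta_m/2}$ and per-predictor
relative variable importance $\mathrm{RVI}(p) = \sum_{m \ni p} w_m$ (a
predictor appearing only through an interaction counts as present). The
parameter count $k$ defaults to fixed coefficients plus free variance
components — the parameters the likelihood actually optimizes — with a
fixed-only count available, since published conventions differ. Ties are
broken by fewer parameters, then model id, so the ranking is deterministic.
ML is the default; REML comparison across fixed-effect structures is
non-standard but supported as a sensitivity check (with a logged caveat),
because practitioners of this model family use it.

## The synthetic-data generator

`simulate_dataset()` emulates the structure of the real trial database so
that every stage is testable without any download: pure-birth plant and
fungal trees scaled to unit height; a realized subset of the plant × fungus
grid; papers contributing several effect sizes that share non-inoculated
controls; binary ecological covariates (paper-level location, species-level
functional group); random effects drawn at configured true components
(Brownian correlations from the simulated trees, tensor products for the
interactions); heteroscedastic sampling variances $v_i$ (log-normal,
meanlog $\log 0.03$, sdlog 1 — a typical spread for biomass log response
ratios); and SD masking at the configured missing rate.

Group statistics are constructed to invert exactly: $\bar x_{\mathrm{ctrl}}
= 1$, $\bar x_{\mathrm{inoc}} = e^{y_i}$, and $SD_g = \bar x_g
\sqrt{v_i n_g / 2}$, which splits $v_i$ equally across groups so the
variance formula returns exactly $v_i$. Recomputing effect sizes from the
simulated trial table therefore round-trips the truth on every unmasked row
— the key identity linking the generator to the effect-size module.

Defaults are the two study conditions the pipeline targets: AM mode mirrors
the single-genus AM subset (234 plant species, 14 fungal genera, 297
papers, ~8 effect sizes per paper, realized-pair density 0.14, 3.5%
missing SDs, components {plant species 0.15, study 0.10, control set 0.16,
paper 0.15, plant phylogeny 0.009, plant phylogeny × fungal genus 0.06},
intercept $\ln 1.62$); EM mode mirrors the EM subset (62 plants, 40 fungal
genera, 83 papers, density 0.077, 21.2% missing SDs, 7 plant and 24 fungal
origin clades, components {plant origin 0.232, plant phylogeny × fungal
phylogeny 0.11, plant × fungal origin 0.01, study 0.04, control set 0.15,
paper 0.65}, intercept $\ln 1.80$). By default each paper has one control
set; several tests instead use the configurable fan-out
(`control_fanout`), because the control-set and paper components are only
separately identifiable when papers contain multiple control sets.
Origin clades are contiguous clades cut from the corresponding tree's
cophenetic distances. One seeded generator with fixed per-component
sub-stream offsets makes trees invariant to edits of other config fields.

What the generator deliberately does **not** emulate: the taxonomic
identities of real taxa, publication-bias mechanisms, correlations between
covariates and phylogeny, and non-normal effect-size errors. Passing
recovery tests therefore demonstrates that the estimator recovers the
model's own data-generating process at realistic sizes — not that the
model is correct for any particular real dataset.

## Problem sizes used in the shipped experiments

The recovery experiment fits ~2000 effect sizes (250 papers × 8, fan-out
2.5) over 20 replicate worlds with profile CIs for four components; the
variable-importance experiment uses ~500 effect sizes over 10 worlds; the
optimizer-fidelity check compares 200 instances of ≤ 10 observations
against a derivative-free global search. These sizes were chosen to match
the study conditions (the AM-sub subset has n = 2398) while keeping each
experiment reproducible in minutes on a single core.

## Known limitations

* λ is fixed (default 1), not estimated; OU or other trait-evolution
  kernels are out of scope.
* Variance-component uncertainty is not propagated into BLUP or
  marginal-mean SEs (the usual empirical-BLUP caveat).
* Origin labels are taken as input columns; reconstructing evolutionary
  origins from character states is out of scope.
* Single-value median-CV imputation only; a multiple-imputation hook would
  slot into `impute_variances()` but is not provided.
* REML-based AICc comparison across fixed-effect structures is offered for
  sensitivity analysis despite its known conceptual problems.
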