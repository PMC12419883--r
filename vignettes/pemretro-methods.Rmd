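---
title: "Phylogenetic eigenvector maps for fossil trait retrodiction: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic eigenvector maps for fossil trait retrodiction: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pemretro)
```

## The model

Let a rooted phylogeny with branch lengths $\phi_e \ge 0$ cover $n$
training tips (taxa with an observed response) and any number of held-out
tips. The **influence matrix** $B$ is the binary $n \times m$ indicator of
which of the $m$ edges lie on each tip's root path. Under Brownian motion
with rate $\sigma^2$, the trait covariance between two tips is
$\sigma^2$ times the branch length their root paths share, i.e.
$\sigma^2\, B\,\mathrm{diag}(\phi)\,B^\top$. This identity is the
package's central invariant: the brute-force shared-path matrix
(`path_length_matrix()`) is computed by a completely independent
enumeration of root paths and must agree with the influence-matrix algebra
exactly.

The **edge weighting** generalizes the Brownian case:
$w(\phi) = \sqrt{\psi}\,\phi^{(1-a)/2}$ with steepness $a \in [0,1]$ and
global rate $\psi > 0$. At $a = 0$ the squared weights reproduce branch
lengths (gradual change); at $a = 1$ every edge contributes equally
regardless of length (punctuated change). The weighted influence matrix
$B_w = B\,\mathrm{diag}(w(\phi))$ is column-centered on its training-tip
means $m$ and decomposed, $B_w - \mathbf{1}m^\top = U\,D\,V^\top$. The
orthonormal, mean-zero columns of $U$ are the phylogenetic eigenvectors
used as regression covariates; at most $n - 1$ survive centering.

A held-out tip is described by a **location** on the training tree: the
attachment edge, the length already traversed along it, and a pendant
length (recorded but unused — it would contribute prediction variance
only, and the package reports point retrodictions). Its influence row
takes full weight $w(\phi_e)$ on every completely traversed edge,
$w(\text{traversed})$ on the attachment edge, and zero elsewhere; scores
are $(\text{row} - m)\,V\,D^{-1}$, which for a training tip at its own
position reproduces its row of $U$ — the self-consistency check in the
test suite.

## Candidate models and selection

For each response the grid of the four fitted models is: one of the three
ln-scale histometric co-predictors (osteocyte lacuna volume, vascular
canal harmonic-mean diameter, canal minimum calibre) plus eigenvectors, or
eigenvectors alone. The fit is ordinary least squares; eigenvectors enter
by greedy forward selection.

Two selection criteria are provided because "maximize the fit" is
genuinely ambiguous with 20 training taxa:

* `criterion = "aicc"` (default): add the eigenvector giving the lowest
  small-sample-corrected AIC, stop when AICc stops improving. AICc counts
  the residual variance among the $k$ parameters and returns $\infty$ once
  $n - k - 1 \le 0$, which hard-stops selection before the design
  saturates.
* `criterion = "r2"`: add the eigenvector giving the largest
  residual-sum-of-squares reduction until the budget `max_k` is exhausted
  (R² is nondecreasing in nested OLS, so no information criterion can stop
  it).

The default budget `max_k = n - |Z| - 3` keeps at least two residual
degrees of freedom. Ties are broken by the lowest eigenvector index, and
eigenvector signs are fixed (largest-magnitude entry positive), so
selection and coefficients are bit-reproducible.

Responses are modelled on the natural-log scale by default: the
histometric predictors are ln-transformed, cell dimensions are strictly
positive, and the log scale makes the proxy coupling linear. Predictions
are back-transformed by plain `exp`; Duan's smearing factor
$\exp(\hat\sigma^2/2)$ is available (`smearing = TRUE`) but off by
default, since the headline quantities are point retrodictions.

Each model's reported p-value is the overall F-test against the
intercept-only model — the natural reading of "one p per model". Across
the four-model grid these are adjusted by the step-down Holm–Šidák rule
$\tilde p_{(i)} = \max_{j \le i}\,\{1 - (1 - p_{(j)})^{m-j+1}\}$, capped
at 1, and both raw and adjusted values are reported side by side (whether
published tables of this kind print raw or adjusted values is often
ambiguous). The adjustment is computed as `-expm1(k * log1p(-p))`: the
textbook expression underflows to zero for $p < 10^{-16}$ and would
violate $\tilde p \ge p$. A model whose selection retains zero
eigenvectors and has no co-predictor degenerates to the intercept-only
null; it has nothing to test and is reported with $p = 1$.

"Best" is the highest R² — matching how such grids are typically ranked
when one model must be chosen for reporting — with AICc printed alongside
for readers who weight parsimony differently.

## Numerical choices

* **Edge enumeration** is depth-first preorder from the root; among a
  node's children, subtrees are visited in order of their
  lexicographically smallest descendant tip label. Any fixed order would
  give the same Gram matrix, but a canonical one makes $U$, $V$ and hence
  every downstream coefficient reproducible.
* **Pruning keeps the original root.** Removing fossils can leave the
  root with a single child; the chain is merged into one root edge rather
  than re-rooting at the training crown. This preserves shared root-path
  lengths among survivors (stem edges included) and keeps targets that
  attach above the training crown placeable. The resulting all-ones
  influence column is annihilated by centering, so the basis is unchanged.
* **Rank cut**: singular values below $10^{-10}$ of the largest are
  discarded — this separates exact rank deficiency (centering, duplicated
  rows, zero-length edges) from round-off, and is far below any
  biologically meaningful component.
* **Zero-length branches** are allowed and keep their (zero-weight)
  column so edge indexing is stable.
* **$\psi$ is a pure convention**: it rescales $B_w$, $D$ and target rows
  together, so scores, fits and predictions are invariant to it (tested
  numerically at $\psi = 1$ vs $100$), as they are to uniform branch-length
  rescaling at $a = 0$.
* **Steepness.** The default is $a = 0$ (Brownian): the source analyses
  of this kind do not report a fitted steepness, and Brownian weighting is
  the canonical default. A profile-likelihood estimator
  (`estimate_steepness()`, CLI `--steepness estimate`) maximizes the
  Gaussian likelihood of the centered response under
  $\sigma^2 B_w B_w^\top$ with $\sigma^2$ profiled out, over $a \in [0,1]$
  with $\psi$ held at 1 ($\psi$ and $\sigma^2$ are not jointly
  identifiable). On Brownian-simulated data the estimate concentrates near
  the 0 boundary, which the suite checks over 20 seeds.

## What the synthetic generator emulates — and what it does not

`sim_config()` states the simulated world once; its defaults are not
tuning knobs. 40 tips with half masked as fossils mirror the 20-extant /
20-extinct structure of the motivating dataset. The tree is pure-birth
(Yule, rate 1): fossils in this framing are extant-topology tips whose
response is unobserved — proxies present, response masked — not extinct
lineages, so no birth–death or fossilized-sampling process is needed. The
ln trait (RBC area) starts at $\ln 100$ (a 100 µm² cell, mid-range for
non-avian sauropsids) and evolves with $\sigma^2 = 0.05$ per unit depth,
giving roughly a 2–3-fold spread of areas across tips — comparable to the
span between a pigeon-sized and a turtle-sized cell. Each ln proxy is
`intercept + 1.0 × ln_area + N(0, 0.1²)`; the intercepts (1.0, −2.2,
−2.4) place the proxies at realistic magnitudes (osteocyte lacunae of
hundreds of µm³, canals around 10 µm). Width and length are half-power
correlates of area (an ellipse of fixed aspect ratio) with 0.05
independent noise. One generator is seeded once per run
(`simulate_dataset()`); fixtures regenerate byte-identically.

The generator deliberately omits features of real data: measurement error
structured by specimen preservation, non-Brownian trait dynamics (OU,
early bursts), proxy slopes differing from 1, phylogenetic signal in the
proxy noise, and literature-substituted response values. A green test
therefore establishes that the pipeline recovers what the stated model
puts in — not that bone histometrics predict RBC size in nature, and not
that any particular published number is reproduced. The published
model-comparison table and per-fossil values depend on the archived
character matrix and time-calibrated tree, which are not bundled here;
with those files in hand, `pemretro reproduce` runs the identical
computation (report both selection criteria — which one matches depends on
the reference workflow's defaults).

## Degenerate inputs and edge cases

Malformed Newick fails with the character offset of the offending token;
duplicate tip labels, negative branch lengths and multi-rooted edge lists
are rejected up front. Taxon names are matched exactly after whitespace
trimming — no fuzzy matching, because a silent misjoin is the worst
failure mode in comparative data — and a tree/matrix mismatch aborts with
both unmatched lists (CLI exit code 3) unless `--allow-drop`. A fossil row
carrying a response value is an error, not silently dropped. A fossil
missing the best model's co-predictor fails alone; other taxa are still
predicted. Collinear designs are refused with the offending columns named.
Polytomies simply contribute more edge columns; ultrametric and
non-ultrametric trees are both accepted (the method needs only root
paths).

## Known limitations

No prediction intervals or ancestral-node estimates; point retrodictions
only. Steepness is global (no per-edge heterogeneity) and the weighting
function is fixed. The Holm–Šidák adjustment spans the four models within
one response; no correction is applied across responses. Retrodiction
quality degrades gracefully but silently as a fossil's attachment moves
deep into the tree — the pendant length that would quantify that
uncertainty is recorded in every `tip_location` but unused.
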