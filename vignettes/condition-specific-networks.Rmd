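---
title: "Condition-specific co-occurrence networks by sparse PLN inference and edge arithmetic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-specific co-occurrence networks by sparse PLN inference and edge arithmetic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizonet)
```

## The question the pipeline answers

When two crops (here: wheat and pea) grow intercropped on the same plot, is
the microbial community in each crop's rhizosphere simply the community it
hosts when grown alone, or does the plant-plant interaction create
co-occurrence structure of its own? Diversity summaries often cannot tell:
alpha and beta diversity may be indistinguishable between sole cropping (SC)
and intercropping (IC) while the *interaction structure* among taxa changes.
The pipeline therefore compares co-occurrence networks across five
conditions — bare soil, wheat SC, wheat IC, pea SC, pea IC — and isolates
what is unique to intercropping by explicit edge arithmetic:

1. infer one signed network per condition;
2. *clean* each IC network by removing every OTU pair that also occurs in
   bare soil or in either sole crop (these edges are interferences, not
   intercropping effects);
3. *intersect* the two cleaned IC networks, yielding the wheat-unique
   fraction, the pea-unique fraction, and the common fraction present in
   both rhizospheres only under intercropping.

## The network model

Counts are not Gaussian, sequencing depth varies per sample, and
correlations among relative abundances are confounded by the common
denominator. The pipeline therefore models counts with a Poisson log-normal
(PLN) latent Gaussian model: for sample $i$ and OTU $j$,

$$Z_i \sim \mathcal N(\mu, \Sigma), \qquad
  Y_{ij} \mid Z_{ij} \sim \text{Poisson}\!\left(e^{o_i + Z_{ij}}\right),$$

where $o_i$ is a known log-offset (by default $\log$ of the sample's total
count), so depth acts multiplicatively on the Poisson rates and the latent
layer carries the biology. Edges are conditional dependencies: the support
of the precision matrix $\Omega = \Sigma^{-1}$. The reported edge weight is
the partial correlation

$$r_{jk} = -\frac{\Omega_{jk}}{\sqrt{\Omega_{jj}\,\Omega_{kk}}},$$

whose sign distinguishes co-occurrence ($r > 0$) from exclusion ($r < 0$).

### Estimation

The posterior of each $Z_i$ is intractable; the fit uses a variational
Gaussian approximation with free per-observation means and diagonal
variances. Each iteration alternates

* a variational step: diagonally preconditioned Newton proposals for the
  means and a fixed-point update for the variances, accepted through
  geometric backtracking so the evidence lower bound (ELBO) never
  decreases (this monotonicity is asserted by the tests);
* an M-step: closed-form update of $\mu$, then either the inverse of the
  implied latent covariance (no penalty) or a graphical-lasso step that
  maximises the $\ell_1$-penalised Gaussian likelihood of the latent layer,
  giving a sparse $\Omega$.

The graphical lasso is solved by block coordinate descent (compiled code)
with warm starts along the penalty path. Convergence is declared at
relative ELBO change below $10^{-4}$ (maximum 200 iterations; failure to
converge is an error that carries the ELBO trace). Initialisation is
deterministic ($m_{ij} = \log(y_{ij} + 0.5) - o_i$), so a fit is a pure
function of (data, penalty).

### Model quality: pseudo-R²

Following the convention of the PLN ecosystem, model fit is summarised by a
nested pseudo-R²,
$(\ell - \ell_0) / (\ell_{sat} - \ell_0)$, where $\ell$ is the model's
ELBO, $\ell_0$ the log-likelihood of the offset + per-OTU-intercept Poisson
model and $\ell_{sat}$ the saturated Poisson log-likelihood. Values are
clipped to $[0,1]$ and the clipping is recorded. BIC is reported as
ELBO $- \tfrac{k}{2}\log n$ with $k$ counting means, variances and selected
edges. The exact definition behind the source ecosystem's "BIC R²" is not
published, so this explicit nested form is the package's documented choice.

## Penalty selection: StARS

The sparsity penalty is selected by stability: for each penalty on a
30-value log-spaced grid spanning from the empty-support penalty
$\lambda_{\max} = \max_{j\neq k}|S_{jk}|$ down to $\lambda_{\max}/100$,
the graphical lasso is run on 30 random sample subsamples and each edge's
selection frequency $f$ yields an instability $2f(1-f)$; the total
instability of a penalty is the mean over all OTU pairs. The selected
penalty is the densest one whose monotonised instability stays at or below
0.05. Two implementation choices matter:

* **Subsample size.** The classical $\lfloor 10\sqrt n\rfloor$ rule was
  derived for $n$ in the hundreds-to-thousands; at this study's per-condition
  $n \approx 70$ it exceeds $n$, and subsamples of size $n-1$ make all
  instabilities vanish so that the densest (and least reliable) penalty is
  always chosen. The package instead caps the subsample at
  $\lfloor 0.8\,n\rfloor$, the small-$n$ convention of the sparse
  microbial-network literature, which restores informative resampling.
* **Early stopping.** The instability running maximum never decreases, so
  once it exceeds the threshold no denser penalty can be selected and the
  path walk stops. This is exact for the selection rule and is what makes
  the full 30-value grid affordable inside the resampling loop.
* **Resampling scheme.** Edge frequencies are computed by re-estimating the
  graphical lasso on subsample latent covariances taken from the full-data
  variational fit, rather than refitting the entire variational model per
  subsample. Sharing the variational positions slightly understates
  between-subsample variability but keeps the procedure deterministic,
  fast, and monotone in the penalty.

After selection, the precision matrix is refitted restricted to the
selected support (a support-constrained graphical-lasso solve with
effectively infinite penalty off-support). This removes lasso shrinkage
from the reported partial correlations, which matters because edges are
subsequently thresholded on $|r|$.

## Thresholds and edge calls

An edge enters a per-condition network iff $|r_{jk}| > 0.06$ *and* its
StARS selection frequency at the chosen penalty is at least 0.9 (the
stability reading of edge significance; no parametric test on partial
correlations is defined in this setting). The common fraction, produced
after the intersection, is re-thresholded at the laxer $|r| > 0.03$. Both
cutoffs are configuration values; per-condition thresholding happens before
the arithmetic, the common threshold after the intersection.

Edge identity throughout the arithmetic is the **unordered OTU pair,
sign-insensitive** by default: a pair that co-occurs in bare soil is
removed from an IC network even if its sign flipped. A `sign_sensitive`
flag switches both operations to (pair, sign) identity; conflicting-sign
intersections are flagged either way.

## Network summaries

Degree, node and edge betweenness are computed on the unweighted undirected
topology — partial-correlation magnitudes are not distances, and no edge
length convention exists for these graphs — as unnormalised shortest-path
pair counts with even splitting across ties (verified against brute-force
path enumeration on small graphs). Keystone OTUs are nodes whose degree
exceeds the network mean by more than $k = 3$ standard deviations (an
operationalisation of "outstanding degree"; $k$ is configurable, and
betweenness is reported alongside for context). Modules come from greedy
modularity maximisation on absolute edge weights — the reference analysis
names no algorithm, so this standard choice is a stand-in. Human-readable
summaries round to one decimal; machine outputs keep full precision.

## Diversity statistics

Alpha diversity reports observed richness, Shannon entropy (natural log)
and the Gini-Simpson index $1 - \sum p^2$ (the "evenness" reading of
Simpson; the inverse form can be derived from it). Rarefaction draws
without replacement (multivariate hypergeometric), drops samples below the
target depth with a warning, and is seeded. Beta diversity uses unweighted
UniFrac (presence/absence shared-branch fractions on a rooted phylogeny;
basal polytomies are resolved with zero-length branches, which provably
leaves distances unchanged), classical-scaling PCoA with the full
eigenvalue spectrum reported, and PERMANOVA via the standard
permutation machinery with the $+1$ convention
($p = (1 + \#\{F^\ast \ge F\})/(1 + B)$, so $p$ is never 0) and optional
strata restricting permutations within experiments. Only additive main
effects are fitted in the two-factor case; the result flags that no
interaction term is included. Group comparisons of diversity indices
delegate to the standard rank tests (Wilcoxon–Mann–Whitney,
Kruskal–Wallis with pairwise follow-ups).

Networks are fitted on *unrarefied* counts — the PLN offsets absorb depth —
while diversity indices use rarefied counts; this mirrors the separation
between the model-based network stage and the classical diversity stage.

## The synthetic study and what it does (not) show

Because the real study's raw reads are not required by this package, every
stage is validated against a generator with known truth. The default
design mirrors the study layout: 200 OTUs, two experiments sharing 80% of
their OTUs (so the pooling rule has work to do), five conditions with 35
samples each per experiment, and planted precision matrices composed of a
40-edge soil backbone plus, per crop, 15 sole-crop edges, 15
intercrop-specific edges, and a 15-edge common-intercrop set shared by the
two IC conditions — so the cleaned/intersected fractions are exactly the
planted IC-specific and common sets, a self-consistency the tests assert on
the true edge lists. Planted partial correlations are $\pm 0.35$ with a
10% negative fraction (echoing the strong positive:negative imbalance of
real rhizosphere networks). Latent log-means are drawn around 3 (mean
counts of a few dozen, the scale of prevalent OTUs after rarefaction);
depth offsets are log-normal with $\sigma = 0.3$.

Planted graphs are sampled with a per-node degree cap of 2 so every
planted precision matrix is strictly diagonally dominant: positive
definiteness holds without repair and planted partial correlations equal
the nominal strength exactly. (If a design does need repair, the smallest
uniform diagonal inflation is applied and recorded; this preserves signs
but shrinks magnitudes, and designs where repair would halve the strength
are rejected.) Real networks have hubs and heavier-tailed degree
distributions than this; the generator also makes no attempt to simulate
read-level artefacts, taxonomy errors, or compositional closure. Passing
the synthetic suite therefore demonstrates the correctness of the
machinery and the behaviour of the estimator under the declared model — not
performance on real reads.

A genuine property of these study conditions, visible in the workflow
diagnostics (`analysis/04_networks.R` writes the instability path,
`analysis/05_fractions_metrics.R` the recovery scores): with ~70 samples
per condition against ~160 OTUs and moderate effect sizes, stability-based
selection at instability 0.05 with a 0.9 frequency filter is conservative.
Per-condition recall of planted edges sits near one half, and the common
fraction — which requires an edge to be recovered in *both* IC networks and
in *neither* interference network — inherits roughly the square of that
recall, with high precision. Relaxing the stability threshold would raise
recall at the cost of false edges; the package keeps the canonical
threshold and reports the trade-off rather than hiding it.

## Numerical choices and degenerate inputs

* Graphical-lasso tolerances: working-covariance change below
  $10^{-4}\times$ mean $|S_{jk}|$ (inner coordinate descent $10^{-7}$);
  $10^{-3}$ inside the resampling loop where only the support matters.
* Exact zeros come from the soft threshold, so supports are exact, not
  `abs() < eps` calls against dense estimates.
* A single-OTU table degenerates to a scalar latent variance; penalties are
  irrelevant and the fit still reports a monotone ELBO.
* Empty networks are first-class: metrics return zeros, the arithmetic
  treats them as empty sets, and thresholding everything away is not an
  error.
* All randomness (subsampling, rarefaction, simulation, permutations) is
  seeded through one RNG-preserving helper; identical seeds give
  bit-identical outputs, and the caller's RNG state is never disturbed.

## Problem sizes used by the validation suite

Unit tests run the tiny design (40 OTUs, 12 samples per condition) for
pipeline-level checks and the full default design for the five-seed
end-to-end recovery experiment; oracle comparisons use graphs of up to 12
nodes (exhaustive path enumeration), 500 replicated null datasets for the
PERMANOVA calibration, and 400 Monte-Carlo draws for the rarefaction
fairness check. These sizes are the package's own validation choices and
are stated here so they can be scaled up by anyone wanting tighter Monte
Carlo error.
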