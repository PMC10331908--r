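---
title: "Models and methods behind beaknest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind beaknest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the models it
fits, the assumptions they rest on, the knobs that matter, and the choices we
made where the design was genuinely open. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## The scientific problem

Across bird species, both beak shape and nest-material use vary enormously.
A flexible classifier can almost always find *some* association between the
two — the hard question is how much of its apparent accuracy reflects
ecology, how much reflects shared evolutionary history (related species
resemble each other in everything), and how much reflects the bookkeeping of
imbalanced data (most species use grass or fibre; a model that always guesses
the common categories looks accurate). `beaknest` implements the full chain:
coding raw material descriptions, fitting the classifiers, and — centrally —
quantifying those two biases.

## Material coding

Free-text descriptors are matched *exactly* (lower-cased, whitespace-
normalized) against an editable lexicon shipped as a plain CSV; there is no
fuzzy matching, so every coding decision is auditable and every miss is
logged as `unknown` rather than guessed. The primary-material rule per source
is a strict precedence: the descriptor flagged as most-used, else the single
category represented, else the first categorizable descriptor listed. Across
sources the primary is the unanimous candidate or the sentinel `mixed`. The
used-material set is always the union across sources — only the primary
carries the `mixed` sentinel — and a species is a *specialist* exactly when
its used set has size one. Species with no categorizable descriptor anywhere
are flagged `omit` and excluded from every model, never silently dropped.

One rule the sources leave open: when several sources each lack an emphasis
but list different first materials, we resolve through the same cross-source
unanimity rule (disagreeing first-listed candidates give `mixed`). The
original tie-breaking convention of such datasets is not documented anywhere
we could follow, so we chose the rule that never invents agreement.

## Random forests and out-of-bag accuracy

Forests are bootstrap-aggregated CART trees via the randomForest package,
with native categorical splits (encoding recorded as `"factor"` in report
metadata; a one-hot path would only be needed for backends without factor
support). Defaults: 5000 trees at study scale, `floor(sqrt(p))` features per
split — the conventional classification default, since nothing in the
problem dictates otherwise. Accuracy is always **out-of-bag**: each species
is predicted by majority vote over the trees whose bootstrap sample excluded
it. This is both the field's convention for these models and a guard against
optimism without a holdout split. Species never out of bag (possible at very
small tree counts) are excluded from accuracy with a warning, and every fit
is preceded by a seed so reports are bit-reproducible.

The contribution decomposition refits the model once per predictor with that
predictor removed (*marginal* contribution, full minus reduced accuracy) and
once with only that predictor (*independent* contribution), under the same
seed policy, reporting the majority-class frequency alongside as the chance
baseline. With correlated predictors a variable can have high independent
and near-zero marginal contribution; the duplicated-column test encodes that
redundancy behaviour.

## The phylogenetic-simulation null

The null asks: *if the predictors carried nothing but phylogenetic signal,
how accurate would the model look?* Per topology of the supplied tree
sample, each continuous predictor is refit under Brownian motion — tip values
multivariate normal with mean $z_0$ and covariance $\sigma^2 C$, $C_{ij}$
the shared root-to-tip path length; ML closed forms $\hat z_0$ = GLS mean,
$\hat\sigma^2 = (x-\hat z_0)^\top C^{-1}(x-\hat z_0)/n$ (ML rather than
REML, matching the standard continuous-trait fitters) — and re-simulated at
its fitted parameters. Each categorical predictor is refit under the
equal-rates Mk model (single rate $q$; Felsenstein pruning with a uniform
root prior, optimized over $\log q$) and re-simulated. The forest is then
refit against the **observed** labels (labels are never simulated) and its
OOB accuracy recorded; the distribution over topologies is summarized by
median and IQR.

Design choices worth stating:

* All 12 predictors are replaced jointly per replicate, but simulated
  independently of each other (each at its own fitted parameters). Trait
  covariances beyond what the shared tree induces are therefore not
  preserved; the null is a *per-trait* phylogenetic null.
* Parameters are refit on every topology rather than fitted once, so
  topology uncertainty propagates into the null.
* The summary across topologies is the median with IQR, chosen for symmetry
  with the downsampling null's median convention.
* The discrete predictors use equal-rates Mk because it is the discrete
  analogue of the single-rate Brownian null: one rate, no asymmetry to
  over-fit on desk-scale data.
* Predictors whose simulation comes out constant (a zero fitted rate) are
  dropped from that replicate with a warning rather than fed to the forest.

Passing `simulate_predictors = FALSE` routes the observed predictors through
unchanged; the null then reproduces the observed accuracy exactly, a no-op
identity the tests assert.

## The downsampling null

Class imbalance lets a classifier harvest accuracy by guessing common
categories. The null subsamples, per replicate, exactly $m$ species from
every class ($m$ = smallest class size), refits, and reports the median over
replicates (100 at study scale). Retained rows are untouched — subsampling
only, no reweighting — and already-balanced data reduce every replicate to
the full model. On two-class no-signal data with 90/10 frequencies the full
model scores ≈ 90 while the downsampled median collapses to ≈ 50; that
collapse is the quantity of interest.

## Trees

Input trees are rooted with branch lengths; polytomies are resolved
arbitrarily with zero-length branches before model fitting (likelihood-
neutral for both BM and Mk). Tree samples are summarized by the
**maximum-clade-credibility** tree — the member of the sample maximizing the
product of clade frequencies, the TreeAnnotator convention — rather than a
majority-rule consensus, so the summary is always an actual sampled
topology; ties take the first maximum. Branch lengths of the MCC tree are
replaced by per-clade medians over the trees containing each clade, with
terminal edges treated as singleton clades. Pruning preserves path lengths
exactly (degree-2 nodes collapsed, lengths summed), which also preserves the
trait-model likelihood of the retained tips.

## Phylogenetic logistic regression

With phylolm-style machinery in mind, `phylo_logistic` implements an
estimating-equation (GEE) fit in the spirit of Ives & Garland (2010): binary
response, mean $p_i = \mathrm{logit}^{-1}(x_i^\top\beta)$, working
correlation $R_{ij} = \exp(-\alpha\, d_{ij})$ with $d_{ij}$ the patristic
distance normalized so the tree's maximum tip-to-tip distance is 1 — the
correlation of an OU-type latent process with attraction rate $\alpha$
(large $\alpha$ = little signal). For fixed $\alpha$, coefficients solve the
GEE score equation $X^\top A^{1/2} R^{-1} A^{-1/2}(y-p) = 0$
($A = \mathrm{diag}(p_i(1-p_i))$) by damped Fisher scoring; $\alpha$
maximizes the Gaussian quasi-likelihood of the standardized residuals,
profiled on the log scale over $[10^{-2}, 5\times 10^3]$. The wide upper
bound matters: on large trees sister species can sit at patristic distances
of $10^{-3}$, and only a large $\alpha$ lets the working correlation reach
effective independence there when the data warrant it. On a star phylogeny
the score equation reduces *exactly* to ordinary logistic regression — the
module's key correctness gate, asserted to $10^{-3}$.

Model comparison uses a QIC-style criterion, the standard information
criterion for estimating-equation fits (Pan 2001): the reported `loglik` is
the independence-model Bernoulli log-likelihood at the GEE coefficients and
`aic = 2k − 2·loglik` with $k$ counting coefficients plus one for $\alpha$.
The Gaussian quasi-likelihood used to profile $\alpha$ is kept separately
(`alpha_profile_loglik`); it is unsuitable for cross-model comparison
because its value depends on the fitted variance scale. `select_model` ranks
candidate predictor subsets by this AIC, reports ΔAIC to the best, treats
ΔAIC ≤ 2 as statistically indistinguishable (never silently resolved) and
flags competitors beyond 2 units. Candidate sets are configuration, not
code; the pipeline default spans intercept-only, PC1, PC2, PC1+PC2 and
PC1+PC2+hand-wing index, all of which are numeric after the beak-morphospace
PCA. Separation is detected once, on the independence fit (it is a property
of $(y, X)$, not of the correlation), and raised as an explicit error.

The beak-morphospace PCA is run on the correlation matrix by default
(`scale. = TRUE`, togglable and recorded): the five inputs mix millimetres
and grams, and only the correlation form supports the usual size/shape
reading of PC1/PC2. Scores use a deterministic sign convention (the
largest-magnitude loading of each component is positive), so results do not
flip between runs or platforms. Standardization uses the sample (n−1)
standard deviation, with centers and scales stored for exact inversion.

## The synthetic-data generator

The generator emulates the *statistical structure* of a nest-material study
so the full pipeline is testable without external downloads:

* **Tree sample** — one Yule (pure-birth) base tree scaled to unit height,
  plus branch-length-jittered copies (multiplicative lognormal jitter,
  topology fixed, default SD 0.1) standing in for a posterior sample.
  Independent Yule trees would make the phylogenetic null mis-specified by
  construction — real posterior topologies are correlated samples for one
  clade — so the jittered copies are the honest desk-scale analogue.
* **Continuous predictors** — standardized mixtures
  $w\,\mathrm{BM} + (1-w)\,\mathrm{noise}$ (the `signal_mix` knob, default
  0.7 — strong but imperfect signal, the regime typical of avian
  morphometrics), mapped to positive measurement scales by exponentiation
  with fixed log-scale locations (so bill lengths land in plausible mm,
  masses in plausible g).
* **Categorical predictors** — equal-rates Mk with total leave-rate 1 per
  unit tree height (converted to the per-pair rate internally), giving
  moderate signal for factors of 3–11 levels.
* **Labels** — multinomial logit: category scores are a 7×6 coefficient
  matrix times the standardized continuous predictors, plus per-category
  intercepts (`class_bias`, whose softmax sets the class frequencies; the
  default tilts toward grass/fibre/twig and makes mineral and silk rare,
  max/min frequency ratio ≈ 9, echoing the strong imbalance of real
  nest-material data), plus a per-category latent Brownian trait scaled by
  `phylo_effect_sd`. The latent effect enters the *scores*, not the
  predictors, so phylogeny-driven and ecology-driven accuracy can be dialled
  independently — exactly what validating the bias decomposition requires.
  The primary label is the argmax of scores plus Gumbel noise; extra used
  categories join the set with probability decaying by rank (default 0.35,
  halving), producing both specialists and generalists.

What the generator does **not** emulate: the covariance structure of real
trait databases beyond tree-induced correlation, multi-source disagreement
(synthetic profiles are single-source, so `mixed` arises only through the
coding module), observation error in the literature descriptions, and real
class frequencies beyond the `class_bias` knob. Passing tests on synthetic
data therefore demonstrate that the machinery measures what it claims under
a known generating process — not that any particular real-world accuracy
value will recur.

## Numerical choices and degenerate inputs

* BM with a constant trait returns $\hat\sigma^2 = 0$ (infinite density
  reported as `Inf` log-likelihood); a zero-length star with duplicate tips
  raises a singular-covariance error.
* Mk with a single observed state warns and returns $q = 0$ with the uniform
  root prior likelihood $\log(1/k)$.
* The Mk rate search runs over $\log q \in [\log(10^{-7}/H), \log(500/H)]$
  ($H$ = tree height); the pruning recursion rescales partial likelihoods
  per node to avoid underflow.
* The GEE solver damps Fisher-scoring steps (max step 5 on the logit scale),
  clamps probabilities to $[10^{-10}, 1-10^{-10}]$, adds a $10^{-8}$ ridge
  only if the correlation Cholesky fails, and returns $-\infty$ profile
  values rather than erroring when a candidate $\alpha$ is pathological.
* MCC ties take the first maximum; identical candidate models produce exact
  AIC ties reported as indistinguishable.

## Problem sizes

The packaged tests and the acceptance script run reduced configurations
chosen to exercise every stage at desk scale: synthetic studies of 80–800
species, forests of 100–200 trees, 8–20 topologies in the phylogenetic null,
20–30 downsampling replicates, and 30–50 replicates for parameter-recovery
checks (200-tip trees for the Brownian rate, 500 tips for the logistic
slopes). Study-scale defaults (5000 trees, 100 topologies, 100 downsampling
replicates) remain one argument away in `rf_config`/`run_config`.

## Known limitations

* Only Brownian motion and equal-rates Mk are offered for the null — no
  OU/early-burst continuous models, no asymmetric or covarion discrete
  models, no rate heterogeneity.
* The phylogenetic GLM track is binary-response only; there is no
  multinomial phylogenetic model, and no continuous-response PGLS.
* GEE z-scores can be anti-conservative when the working correlation
  under-represents true residual dependence (the null-simulation test
  tolerates fat tails for exactly this reason); treat borderline
  significance accordingly.
* The phylogenetic null simulates predictors independently of one another;
  correlated-trait nulls would require a multivariate Brownian fit that the
  package deliberately does not attempt.
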