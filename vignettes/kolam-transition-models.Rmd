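---
title: "Hierarchical Markov models of kolam gesture sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Markov models of kolam gesture sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(KolamMarkov)
```

## The scientific problem

Kolam are ritual loop drawings made by Tamil women on a dot grid. Each
closed loop decomposes into a sequence of standardized gestures, and each
gesture belongs to one of three geometric spaces: orthogonal (O), diagonal
(D), or transitional (T). The drawing grammar forbids direct contact
between orthogonal and diagonal gestures — the two spaces are only bridged
by transitional gestures — so a loop is naturally modeled as a Markov chain
over gesture states.

The question the package answers is a cultural-evolution one: how much of
the stylistic variation in these sequences maps onto *group* identities
(caste, neighbourhood of residence, migration background) versus
*individual* identity (the artist herself, and her expertise measured as
years of practice)? If styles were ethnic markers, group terms should
absorb a large share of the variation; if art is a stage for individual
distinctiveness, the artist term should dominate.

## Data model

* **Lexicon.** 29 raw gesture codes: 12 left/right chiral pairs plus 2
  achiral loop gestures (26 loop codes collapsing onto 14 model states:
  6 O, 4 T, 4 D) and 3 decorative gestures that are never part of a loop.
  The mapping ships as a plain CSV (`inst/extdata/kolam_lexicon.csv`) and
  can be replaced by a user file with the same layout, because published
  descriptions of the lexicon do not pin down machine-readable code
  spellings, and because the 14 states could in principle arise either by
  chirality collapse (implemented as the default) or by restriction to a
  14-gesture subset. The mapping file makes either choice explicit and
  auditable.
* **Counting.** For every artist, all transition pairs of all her loops are
  tallied into a 14×14 aggregate matrix. Because loops are closed and the
  starting gesture is an artifact of transcription, the pair from the last
  gesture back to the first is counted too (cyclic closure); a no-closure
  mode exists for validation studies. The aggregate factors into a 3×3
  between-space matrix `S` (block sums, space order O, T, D throughout) and
  three within-space matrices (the diagonal blocks, 6×6 / 4×4 / 4×4).
  Cross-space transitions contribute only to `S`: this is the only reading
  consistent with the factorization
  P(o2 | o1) = P(O | O) × P(o2 | o1, within O).
* **Neighbourhoods.** Households are clustered on the geodesic
  (haversine, spherical Earth R = 6,371 km) distance matrix by
  agglomerative clustering cut at 500 m. The linkage is configurable;
  complete linkage is the default so that a neighbourhood's diameter is
  controlled by the threshold. At the few-kilometre extent of such field
  studies the spherical-vs-ellipsoidal error is negligible.

## The model

Each row of each of the four matrices is a multinomial over its columns,
modeled with the softmax link. For artist $i$, row $r$, non-reference
category $c$:

$$\eta_{irc} = \alpha_{rc} + a_{irc} + g_{\mathrm{caste}(i),rc} +
u_{\mathrm{nb}(i),rc} + \beta^{\mathrm{prac}}_{rc} z_i +
\beta^{\mathrm{nat}}_{rc}\,\mathrm{native}_i$$

with the row's **last category as reference** ($\eta = 0$; the softmax is
shift-invariant so one category must be pinned — the published analysis
does not state its parameterization). Group offsets are partially pooled:
$a \sim N(0, \sigma^{\mathrm{artist}}_r)$ etc., one standard deviation per
(term, matrix, row) shared across the row's categories; an equality
constraint sharing σ across the rows of a matrix is available
(`sigma_sharing = "matrix"`). Practice duration is standardized (mean 0,
sd 1, denominator n − 1); nativity is an indicator (0 = native,
1 = non-native).

Priors default to Normal(0, 1) on intercepts and slopes and half-Normal(0,
1) on group standard deviations, all on the logit scale — weakly
informative for transition rows, keeping prior-predictive rows off the
simplex corners while allowing rows as skewed as 0.99/0.01. They are fully
configurable (`defaultPriors()`), so externally calibrated choices can be
substituted.

Seven model variants form the comparison ladder (`kolamModelSet()`):
intercepts only; + artist; + artist + practice; + artist + practice +
nativity; + artist + caste; + artist + caste + neighbourhood; and the full
five-term model.

Grammar-forbidden between-space cells (O→D, D→O) are free softmax
categories by default — every row is probabilistic, and grammar-valid data
simply put zero counts there — with `structural_zeros = TRUE` available to
pin them to probability zero.

## Computation

Sampling uses a static-trajectory Hamiltonian Monte Carlo sampler written
for this posterior: non-centered parameterization throughout, diagonal
mass-matrix estimation in a mid-warmup window, dual-averaging step-size
adaptation (target acceptance 0.9), and trajectory lengths jittered over
the upper half of `L_max` (default 60) to avoid periodicity. Rows are
conditionally independent given the design, so each transition matrix is
fitted as its own block of a few hundred to a few thousand parameters.
Divergences are flagged when the Hamiltonian error exceeds 1000, and the
fit fails loudly when any parameter's split-Rhat reaches 1.01 or the
divergence rate exceeds its cap; the group-level scale parameters are the
slowest movers, which is why the default trajectories are long.

Degenerate inputs are handled explicitly: empty rows contribute zero
log-likelihood, a zero-count design returns the prior, a positive count on
a structurally zero cell is an error, and non-finite linear predictors
abort.

## Evaluation

* **Pointwise log-likelihood.** One observation unit is one artist's
  multinomial count row in one matrix (the published analysis does not
  state its unit; a per-row multinomial is the finest exchangeable unit
  here). The log pmf includes the multinomial coefficient.
* **PSIS-LOO.** Importance ratios per observation are tail-smoothed with a
  generalized-Pareto fit (Zhang–Stephens profile estimator, shape
  regularized toward 0.5); observations with Pareto k > 0.7 are reported,
  never silently refitted. Exact refit LOO on small fits is the test
  oracle.
* **Weights.** Pseudo-BMA weights are regularized by the Bayesian
  bootstrap (1,000 Dirichlet replicates, seeded). Stacking maximizes the
  summed log of weighted leave-one-out predictive densities over the
  simplex via a softmax-parameterized quasi-Newton search started at the
  uniform vector; vertex solutions are checked explicitly so a model that
  dominates every observation receives weight exactly 1, and exact ties
  stay uniform.
* **ICC.** For each draw and each transition-matrix cell, each term's
  isolated contribution to the linear predictor is computed per individual
  (artist offset; caste offset via membership; neighbourhood offset via
  residence; slope × covariate), the variance is taken across individuals,
  and the five variances are normalized to shares. Shares are averaged
  over draws, then over cells — unweighted within a matrix by default,
  with a count-weighted option. Cells are the non-reference categories
  only: the reference logit is fixed at 0 under every term, so it carries
  no variance and would only contribute 0/0 cells. The across-spaces row
  uses the 3×3 matrix's cells; each within-space row uses its own
  matrix's. By construction each row of the ICC table is non-negative and
  sums to 1.
* **Equilibrium.** An artist's long-run space occupancy is the stationary
  distribution of her posterior-mean 3×3 between-space matrix, solved
  linearly after verifying a single recurrent communicating class;
  computing per-draw stationary laws and averaging is available
  (`per_draw = TRUE`) since the order of averaging is a genuinely open
  choice.

## The synthetic-data generator

`simulateDataset()` is the generative inverse of the model, with known
ground truth, so every stage is testable without field data. Defaults
emulate the shape of the field study this model family was built for: 192
artists, 19 caste categories, 8 neighbourhood clusters, 16 drawings per
artist, ≈18% non-native artists, shifted-geometric loop lengths (min 1,
default mean 8 gestures — a realistic loop scale for dot-grid drawings).
The default population between-space matrix is the field-style pattern
(orthogonal rows ≈ 0.99/0.01/0, diagonal ≈ 0/0.51/0.49, grammar cells
structurally zero). Within-space population rows are not published
anywhere, so the default gives each gesture a 0.45 self-transition weight
with a mild gradient across destinations — chosen once as a plausible
"motif-sticky" regime. Group effects default to the artist-dominant
hierarchy (σ_artist = 1.0, σ_caste = σ_neigh = 0.2, practice slope 0.4,
nativity slope 0.2), matching the qualitative effect ordering the model
family is designed to detect.

Loops are emitted by Markov simulation: initial space from the artist's
between-space stationary law, initial gesture from the within-space
stationary law, same-space steps from the within-row, and space switches
landing via the destination space's stationary law (a parameter-free
assumption, needed only for full-chain simulation, not for the
likelihood). The generator emits linear sequences while counting applies
cyclic closure; this mild mismatch is deliberate and documented, and a
no-closure counting mode (`cycle = FALSE`) removes it for strict recovery
studies. A sequence whose wrap pair would violate the O/D grammar is
extended until the wrap is legal, so every simulated loop passes the
grammar validator including the wrap pair. GPS coordinates are placed on a
~1.1 km grid of neighbourhood centers with ≤100 m jitter, so 500 m
clustering recovers the true neighbourhoods exactly.

What the generator does **not** emulate: 2-D dot-grid geometry, symmetry
or fractal structure, drawing-session ordering effects, transcription
noise, and realistic imbalance in drawings per artist. Passing tests
therefore show that the estimators recover the generative model's own
structure at field-like sample sizes — not that field corpora satisfy the
model's assumptions.

## Validation-harness choices

Estimator-validation tests (consistency of the intercept-only model, LOO
against exact refits, σ recovery, ICC-ordering recovery) use a *balanced*
between-space truth (rows 0.70/0.30/0, 0.35/0.30/0.35, 0/0.30/0.70) rather
than the field-like default: with the field-like matrix, diagonal and
transitional rows receive too few transitions at desk-scale corpus sizes
for tolerance-tight checks, which would test sample size rather than
correctness. Recovery fits use no-closure counting, matching the
generator's linear sequences. The PSIS-vs-exact-LOO agreement check runs
on a small pooled (intercepts-only) fit with a handful of transitions per
observation: that is the moderate-Pareto-k regime in which importance
sampling is supposed to agree with exact refits. Leaving one multinomial
row out of a four-artist hierarchical fit removes a large share of that
artist's information, pushes Pareto k past 0.7, and is exactly the regime
PSIS is required to *flag* (which it does) rather than match. Replicates are excluded from recovery
summaries when their worst split-Rhat reaches 1.05 (1.01 is the reporting
contract for production fits; 1.05 marks a clearly unusable replicate in a
deliberately short harness chain).

Problem sizes used by the test-suite and the acceptance script were chosen
to make each check statistically decisive at desk scale: consistency at
~8,000 transitions against a ±0.03 band, law-of-large-numbers convergence
at >150,000 transitions against ±0.02, σ recovery at 80 artists × 30
loops, ICC-ordering recovery over 10 replicates of 40 artists, and the ICC
simplex on a 40-artist full-model fit with reduced draws (2 chains × 400).

## Known limitations

* The exact seven-variant ladder, priors and equality-constraint scheme of
  the original analysis live in unpublished supplementary material; the
  registered ladder and default priors here are explicit, documented
  stand-ins, and both are configurable.
* Whether published population matrices are posterior means or medians is
  not stated; means are implemented.
* The HMC sampler is tuned for this model family, not a general-purpose
  engine; heavy funnels (tiny groups with large σ) mix slowly and show up
  honestly in Rhat/ESS diagnostics.
* Wrap-closure counting applied to the generator's linear sequences biases
  per-loop rows slightly toward the stationary law; at the default mean
  loop length the effect is ≈1/8 of transitions and vanishes as loops
  lengthen. Use `cycle = FALSE` when exactness matters.
* ICC shares are relative: they compare terms within a model and say
  nothing about absolute predictive strength.

## A worked run

```{r example}
sim <- simulateDataset(defaultGroundTruth(),
                       simConfig(n_artists = 40, drawings_per_artist = 8,
                                 seed = 1))
nb <- clusterNeighborhoods(distanceMatrix(sim$corpus))
design <- buildDesign(sim$corpus, nb)
fit <- fitKolam(design, kolamModel("full"), chains = 2, warmup = 400,
                sampling = 400, seed = 1, convergence = "warn")
transitionMatrixEstimate(fit)$S
iccDecompose(fit)
equilibriumOccupancy(fit, artists = "population")
```
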