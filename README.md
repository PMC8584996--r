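# KolamMarkov

Hierarchical Bayesian Markov models for kolam gesture sequences.

Kolam are ritual loop drawings made by Tamil women on dot grids. Every
closed loop decomposes into a sequence of standardized gestures, each
belonging to one of three geometric spaces — orthogonal (O), diagonal (D)
or transitional (T) — with a grammar that only lets transitional gestures
bridge O and D. Treating the gesture sequence as a Markov chain, this
package asks a cultural-evolution question: how much of the stylistic
variation between drawings maps onto *group* identity (caste,
neighbourhood, migration background) versus *individual* identity (the
artist and her expertise)? If drawing styles acted as ethnic markers,
group terms should explain much of the variation.

It is aimed at researchers analysing behavioral sequence corpora
(material-culture production, gesture, song) who need partial pooling over
crossed group memberships and a defensible variance decomposition.

## The model

Per artist *i*, transition counts are factored into a 3×3 between-space
matrix and three within-space matrices (6×6 O, 4×4 T, 4×4 D):
P(o2 | o1) = P(O | O) · P(o2 | o1, within O). Each matrix row is a
multinomial with softmax link; for non-reference category *c* of row *r*:

```
eta[i,r,c] = alpha[r,c] + a[i,r,c] + g[caste(i),r,c] + u[nb(i),r,c]
             + b_prac[r,c] * z_practice[i] + b_nat[r,c] * native[i]
```

with partially pooled offsets a ~ N(0, σ_artist[r]), g ~ N(0, σ_caste[r]),
u ~ N(0, σ_neigh[r]) and weakly informative Normal(0,1) / half-Normal(0,1)
priors on the logit scale. Fitting is by Hamiltonian Monte Carlo
(non-centered parameterization, adaptive step size and mass matrix,
split-Rhat/ESS/divergence diagnostics). Seven registered model variants
are compared by PSIS-LOO with stacking and pseudo-BMA+ weights, and a
prediction-variance decomposition turns each term into an intraclass
correlation (ICC): its share of the across-individual variance of the
linear predictor, averaged over posterior draws and matrix cells. Each
artist's long-run space occupancy is the stationary distribution of her
between-space matrix.

A seeded synthetic-corpus generator (the generative inverse of the model,
with known ground truth) makes the whole pipeline testable without field
data, including parameter-recovery experiments.

## Worked example

```r
library(KolamMarkov)

sim    <- simulateDataset(defaultGroundTruth(),
                          simConfig(n_artists = 40, drawings_per_artist = 8,
                                    seed = 1))
nb     <- clusterNeighborhoods(distanceMatrix(sim$corpus))
design <- buildDesign(sim$corpus, nb)
fit    <- fitKolam(design, kolamModel("full"), chains = 2, warmup = 400,
                   sampling = 400, seed = 1, convergence = "warn")

transitionMatrixEstimate(fit)$S
iccDecompose(fit)
equilibriumOccupancy(fit, artists = "population")
```

which prints (the short demo chains trigger an honest non-convergence
warning, max split-Rhat 1.19 — production fits use the 4 × 1,000 default):

```
NeighborhoodAssignment: 40 artists in 8 clusters (threshold 500 m, complete linkage)

Population between-space matrix:
      O     T     D
O 0.899 0.086 0.016
T 0.469 0.321 0.209
D 0.025 0.468 0.507

ICCTable (share of across-individual prediction variance):
              individual expertise nativity caste residence
across-spaces      0.403     0.116    0.062 0.178     0.242
orthogonal         0.622     0.174    0.049 0.104     0.051
diagonal           0.245     0.276    0.053 0.221     0.205
transitional       0.351     0.168    0.033 0.212     0.236

Population equilibrium occupancy:
               O     T     D
population 0.752 0.157 0.091
```

Reading the output: the population-level chain is strongly
orthogonal-sticky (O row ≈ 0.90/0.09/0.02), each ICC row sums to 1 and
splits one matrix's prediction variance across the five terms — here the
artist term dominates, as the generator's artist-dominant ground truth
intends — and the equilibrium row says a typical artist spends ~75% of her
gestures in orthogonal space.

`runPipeline()` (or `inst/scripts/kolam-pipeline.R` from a shell)
orchestrates encode → count → cluster → fit → compare → ICC → equilibrium
from a YAML config and writes a hashed artifact manifest.

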