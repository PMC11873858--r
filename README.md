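# rmixtree

Bayesian estimation of a **response-mixture IRTree model** (RMM) for
Likert-scale items whose middle category can mean two different things: a
genuine neutral position, or a covert "don't want to answer / don't know"
non-response.

## The model

Item scores take values `0..h` (`h` even) with middle category `m = h/2`.
Each response traverses a two-node probit decision tree, driven by a pair of
latent person variables `(theta1, theta2)`:

1. **Non-response node.** With probability
   `P(Z = 1 | theta1) = Phi(-alpha1 * theta1 - beta_i)` the response is
   *informative* (`Z = 1`); `theta1` is the person's non-response tendency,
   `alpha1` a common slope and `beta_i` an item intercept. A
   non-informative response (`Z = 0`) emits the middle category.
2. **Graded response node.** An informative response follows a normal-ogive
   graded response model (GRM) on all `h + 1` categories:
   `P(X >= k | Z = 1) = Phi(alpha2_i * theta2 - delta_ik)` with ordered
   thresholds `delta_i1 < ... < delta_ih`.

A non-middle score identifies `Z = 1`; a middle score is a mixture of the
two paths,
`P(X = m) = (1 - p1) + p1 * g_m`, where `p1` is the informative probability
and `g_m` the GRM middle-category probability — so `Z` is a latent
per-response indicator there. Ignoring the mixture (fitting a plain GRM)
biases `theta2` estimates toward 0 and distorts the item parameters;
modeling it recovers both, and the posterior of `Z` estimates *which*
middle answers were non-responses.

Estimation is by Gibbs sampling with probit (Albert–Chib) data
augmentation, with the latent population mean and covariance of
`(theta1, theta2)` sampled under a normal/inverse-Wishart hyperprior and
mapped to the identified (standardized) scale in every retained draw. Two
baselines are included: the plain GRM and a pure IRTree in which *every*
middle response is routed through the first node. Model comparison uses
the DIC, with `theta1` integrated out by 10-node Gauss–Hermite quadrature
for the tree-based models.

## Worked example

Simulate 300 persons answering 10 five-category items with a 20% overall
non-response rate, then fit the RMM:

```r
library(rmixtree)

space <- likert_space(4)                      # scores 0..4, middle = 2
persons <- generate_person_bank(300, seed = 1)
items <- generate_item_bank(10, nr_rate = 0.2, seed = 2)
sim <- generate_responses(persons, items, space, seed = 3)
table(sim$scores)
#>    0    1    2    3    4
#>  344  575 1234  498  349

fit <- fit_likert(sim$scores, space,
                  chain_config("rmm", n_iterations = 2500, burnin = 500,
                               thin = 2, seed = 4))
fit
#> Gibbs fit of the RMM model
#>   data: 300 persons x 10 items (scores 0..4)
#>   chain: 2500 iterations, 500 burnin, thin 2 -> 1000 retained draws
#>   posterior mean alpha1 = 0.692, mean beta = -1.617
#>   posterior mean cor(theta1, theta2) = -0.137
```

How much of the observed middle-category use was non-response?

```r
nr_summary(fit, sim$scores)
#> Estimated non-informative responses: 14.89% of all responses
#>   36.20% of middle-category responses (middle share 41.13%)
```

(The generating rate was 20% of all responses.) Point estimates of the
substantive trait are posterior means on the standardized scale:

```r
cor(coef(fit, "theta2"), persons[, "theta2"])
#> [1] 0.8445079
```

Model comparison against the plain GRM by DIC (smaller is better — the
generating mixture model wins):

```r
fit_grm <- fit_likert(sim$scores, space,
                      chain_config("grm", n_iterations = 2500, burnin = 500,
                                   thin = 2, seed = 5))
dic(fit, sim$scores)
#> [1] 7803.017
dic(fit_grm, sim$scores)
#> [1] 7845.176
```

## Parameter-recovery study

`simulation_design()` / `run_simulation_study()` reproduce the package's
recovery experiment: persons and items are drawn from calibrated banks,
data are simulated from the tree, and each model's posterior-mean estimates
are scored against truth (average absolute bias, variance, MSE, per
parameter block).

```r
des <- simulation_design(N = 1000, K = 50, nr_rate = 0.2,
                         n_replications = 10, models = c("rmm", "grm"),
                         seed = 1)
res <- run_simulation_study(des)   # ~16 min on one CPU
as.data.frame(res)
```

At this condition (seed 1) the RMM reduces the GRM's average absolute bias
for `theta2` by **35.3%** and its MSE by **20.6%**. The headline contrasts
can be regenerated in one step:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

which writes `{"t2": {"value": ..., "n": 10}, "t3": {"value": ..., "n": 10}}`
(t2 = bias reduction in %, t3 = MSE reduction in %).

## Command line interface

A ready-made entry point is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "rmixtree.R", package = "rmixtree"))')
Rscript "$CLI" simulate --N 500 --K 20 --nr-rate 0.2 --seed 1 --out-dir sim/
Rscript "$CLI" fit --data sim/responses.csv --model rmm --iterations 2500 \
    --burnin 500 --thin 2 --seed 2 --out-dir fit/
```

`simulate` writes the response matrix, the generating truth and a run
manifest; `fit` writes posterior-mean summaries, a draws CSV and a
manifest (seed, config, input checksum) sufficient to reproduce the run.

## Package layout

- `R/model-core.R` — closed-form tree probabilities and likelihoods;
  Gauss–Hermite marginalization of `theta1`.
- `R/fit.R` — the Gibbs samplers (RMM, GRM, IRTree) with data
  augmentation, identification rescaling, and a burn-in-only collapsed
  accelerator for the mixture chain (see the vignette).
- `R/evaluation.R` — DIC, recovery metrics, non-response summaries.
- `R/simulate.R`, `R/items.R` — calibrated person/item banks, tree
  simulation, the recovery-study driver.
- `R/io.R`, `R/cli.R` — CSV/JSON I/O, manifests, trace export, CLI.
- `vignettes/response-mixture-model.Rmd` — model, priors, sampler design
  and limitations.

See the vignette for the estimation details and the package's modeling
assumptions.
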