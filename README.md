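# coalpf: demographic inference with a coalescent particle filter

`coalpf` infers the history of effective population size, Ne(t), and a
genome-wide recombination rate from a handful of whole-genome haplotypes.
It is aimed at population geneticists who want full coalescent-with-
recombination inference — no discretisation of coalescence times, no
composite-likelihood shortcuts — at the price of Monte Carlo computation.

## The model and the method

Along the genome, the local genealogy `x_s` of the n sampled haplotypes
evolves as a Markov jump process: recombination interrupts the tree at rate
`ρ·B(x_s)` per base pair (B is the total branch length), the detached
lineage re-coalesces at instantaneous rate `b_u·C(u)`, where `b_u` is the
number of contemporary branches and `C(u) = 1/(2·Ne(u))` the coalescence
rate (SMC'-type dynamics: re-coalescence into the origin branch leaves the
tree unchanged). Variant sites are a Cox process driven by the genealogy:
mutations fall at rate `μ·B(x_s)` per base pair, and an allelic pattern A
has probability density `μ × (length of branches whose descendant tips are
exactly A's carriers)` under the infinite-sites model.

Inference runs a particle filter over this doubly continuous process:

* **Waypoints.** Weights are evaluated, and systematic resampling may
  occur, at every variant site plus an in-fill grid no coarser than
  `1/(2θ)` bp (θ the heterozygosity), which bounds the per-gap loss of
  effective sample size to about `e^{-1/2} ≈ 0.6`.
* **Unbounded lookahead.** Resampling is steered by an auxiliary weight
  that multiplies each particle's likelihood by an approximate likelihood
  `h` of a *digest* of future data — the distance to the next singleton on
  each haplotype, and up to n/2 mutually consistent "cherries" supported by
  future doubletons. This counteracts the long forgetting times of recent
  coalescences, the dominant source of bias in recent epochs.
* **Parameter updates.** Per-epoch coalescence counts and opportunities
  (and their recombination analogues) are harvested from the particle
  paths with epoch-specific fixed lags, and rates are updated either by
  stochastic EM (`rate = E[count]/E[opportunity]`) or by Variational Bayes,
  which keeps a conjugate `Gamma(α, β)` posterior per rate, avoids the
  zero-rate fixed points of EM, and re-weights sampled events by
  `η = e^{ψ(α)}/α` during filtering.

The package also contains the sequential simulator itself, so studies are
fully self-contained: `simulate_genomes()` draws data under any
piecewise-constant or piecewise-exponential demography.

## A worked example

```r
library(coalpf)

truth <- demographic_model(ne = 10000, rho = 1e-8, mu = 2.5e-8)
set.seed(31)
sim <- simulate_genomes(truth, n = 4, L = 1e6)   # two diploids, 1 Mb

ep   <- parse_epoch_spec("400,800,1200,2000,4000,8000,20000,40000,60000")
init <- demographic_model(ne = rep(5000, length(ep)), epoch_start = ep,
                          rho = 2e-8, mu = 2.5e-8)
set.seed(32)
ft <- fit(sim$obs, init, n_particles = 500, iterations = 5,
          mode = "vb", lookahead = TRUE, verbose = TRUE)
#> iter  1  loglik -15307.67  rho 1.86e-08  Ne[1] 6112  mean ESS 275
#> iter  2  loglik -15293.16  rho 1.71e-08  Ne[1] 5021  mean ESS 280
#> iter  3  loglik -15273.95  rho 1.63e-08  Ne[1] 9294  mean ESS 281
#> iter  4  loglik -15277.36  rho 1.56e-08  Ne[1] 1.078e+04  mean ESS 279
#> iter  5  loglik -15251.92  rho 1.5e-08  Ne[1] 1.016e+04  mean ESS 282
```

Each line reports the marginal log-likelihood estimate of the pass, the
current recombination-rate estimate, the most-recent-epoch Ne and the mean
effective sample size of the ensemble. After five iterations the epochs
between 2,000 and 20,000 generations — where 1 Mb of two diploid genomes
carries most of its information — recover the simulated Ne = 10,000 within
a few percent (median 10,280 in this run), while the initial guess was
5,000. `write_results()` exports per-iteration rate tables, the final
Ne-vs-time table (generations and years) and a JSON manifest; a command
line front end lives in `inst/cli/coalpf.R` with `simulate` and `infer`
subcommands.

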