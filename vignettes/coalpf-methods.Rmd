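---
title: "Methods: particle-filter inference under the coalescent with recombination"
author: "coalpf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: particle-filter inference under the coalescent with recombination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The probabilistic model

`coalpf` treats the local genealogy $x_s$ of $n$ haplotypes as the state of
a Markov jump process indexed by genome position $s \in [0, L)$.  The prior
path measure has density

$$\pi(x) \;=\; \exp\Big\{-\int \rho\,B(x_s)\,ds\Big\}\;
\prod_{j=1}^{|x|}\exp\Big\{-\int_{\nu_j}^{\tau_j} b_u(x_{s_j})\,C(u)\,du\Big\}
\;\rho\;C(\tau_j),$$

where $B$ is total branch length, $b_u$ the number of branches at
evolutionary time $u$ (equal to 1 above the root, whose infinite branch
attracts no recombination), $C(u) = 1/(2N_e(u))$ the coalescence rate, and
$(s_j, \nu_j, \tau_j)$ the locus, recombination height and re-coalescence
height of the $j$-th event.  The dynamics are the SMC$'$ limit of the
sequential coalescent: the detached lineage re-coalesces with *all*
contemporary branches of the current tree, including the remnant of its
origin branch — a "silent" event that changes nothing but still counts in
$|x|$ and in the recombination sufficient statistics, because the path
measure is over all sampled recombinations.  Non-local branches are fully
culled; retaining them (for exactness beyond SMC$'$) is out of scope.

Observations are variant sites, modelled as a Cox process with intensity
$\mu B(x_s)$.  Site patterns follow the infinite-sites model: pattern $A$
has density $\mu$ times the total length of branches whose observed
descendant-tip set equals $A$'s carrier set (missing tips marginalised,
unphased genotypes summed over compatible phasings).  This linear-in-length
emission makes $\sum_{A \neq 0} P(A \mid g, \mu) = \mu B(g)$ an exact
identity, which the test suite checks to $10^{-12}$; a finite-sites
substitution model would break it.  The combinatorial constant of the Cox
density is particle-independent and dropped, so reported likelihoods are
densities with respect to $(ds)^{|y|}$.

## The filter

Between waypoints, particles evolve under the prior (the proposal equals
the prior, so weight updates contain only emission factors), and the
emission survival factor $e^{-\mu B \ell}$ uses only masked-in sequence
length.  Waypoints comprise every variant site plus an in-fill grid with
spacing at most $1/(2\theta)$: under a stationary Gaussian approximation to
the mutation intensity, the per-gap ESS retention is bounded by
$e^{-\sigma^2 \ell^2}$ with $\sigma^2 = \theta^2\pi^2/6$, which at the
recommended spacing is $e^{-1/2} \approx 0.6$.  By default $\theta$ is
estimated from the data with a Watterson-type estimator (segregating sites
over observed length times $\sum_{i<n} 1/i$), so a misspecified starting
model cannot thin the waypoints.  Resampling is systematic (single
stratified sweep) and triggered when the ESS drops below half the particle
count; at resampling, weights are reset to the pre-resampling mean so the
final weight sum estimates the marginal likelihood density.

### Lookahead

Recent coalescences produce short terminal branches that attract few
recombinations and few mutations: such states persist across long genomic
stretches, and a plain filter discovers too late that its ensemble lacks
them.  The lookahead filter maintains auxiliary weights $v$ that multiply
the target weights by an approximate likelihood $h$ of a digest of future
data given the particle's current tree:

* per haplotype, the distance $s_i$ to the next singleton, with a
  censoring flag when data end first; the singleton term integrates over
  the first change of the terminal branch length (total change rate
  $2 l_i \rho (n-1)/n$) to a hypothesised new length $l'$, marginalised
  over an empirical distribution of $l'$; the removable singularity at
  $\rho_i + \mu_i = \mu_i'$ is evaluated by its limit;
* up to $n/2$ mutually consistent cherries, fixed greedily in locus order
  from future doubletons (a doubleton sharing one leaf with a fixed cherry
  is discarded); a cherry present in the tree contributes
  $e^{-\rho_C s''} + \frac{2}{3(n-1)}(1 - e^{-\rho_C s''})$, an absent one
  $\frac{2}{3(n-1)}(1 - e^{-\rho_C' s'})$, where $2/(3(n-1))$ is the
  equilibrium probability that a specific pair forms a cherry.

To model correlation between successive changes, the whole product is
averaged over $\rho' \in \{\rho, \rho/2\}$ with equal weights — a
two-component mixture of the full likelihood, applied to every lookahead
rate.  Resampling is then triggered by, and performed proportionally to,
$v$; target weights are corrected by $w \leftarrow N^{-1} w/v$ so posterior
expectations and the likelihood estimate are unchanged in expectation (the
test suite verifies this agreement between the two filters directly).

Three choices here were genuinely open.  (1) The empirical $l'$
distribution is taken from the current ensemble's terminal branch lengths,
pooled with the resampling weights $v$ and summarised by at most 32
equal-weight quantile atoms (refreshed at every resampling event and every
32 waypoints); the ensemble is the only available estimate of that
distribution.  (2) The cherry-present rate $\rho_C = 4 l \rho (n-2)/n$
needs a height $l$; we use the cherry's own height in the particle's tree
(its two terminal branches are equal by construction).  (3) Whether $v$- or
$w$-weights should feed the $l'$ atoms is unstated in the literature we
follow; we use $v$, the resampling measure, since $h$ only shapes
resampling.  Lookahead defaults to on for phased and off for unphased
input, where next-singleton distances are far less informative and the
digest can misguide resampling in early epochs.

### Degenerate sites

Under the exact infinite-sites emission, a pattern whose carrier set
corresponds to no branch of a tree has probability exactly zero.  If every
particle is in that situation the ensemble weight vanishes identically; at
practical particle counts this happens occasionally on megabase runs.
Aborting would make long runs fail stochastically, so the engine instead
skips the offending site's weight factor entirely (for all particles,
keeping weights comparable), counts it, and warns.  The likelihood estimate
then omits that site's factor; with adequate particle counts the recovery
never triggers.  True numerical underflow of finite weights still aborts.

## Sufficient statistics and parameter updates

Each recombination produces one event record: locus, $(\nu, \tau)$, the
epoch of each, the per-epoch coalescence opportunity
$\int_\nu^\tau b_u\,du$, and the per-epoch recombination opportunity of the
tree segment it terminates.  Records form backward-linked chains shared
between particles after resampling (reference-counted; records unreachable
from live particles, or harvested for every epoch, are reclaimed, so memory
stays bounded on long runs).  The per-particle multiplicity optimisation —
advancing $k$ identical particles by one simulation at $k$-fold exit rate
and spawning on events — is implemented and tested as its own operation
(`multiplicity_advance`); the engine advances particles independently,
which is statistically identical and keeps the record bookkeeping simple.

Harvesting is fixed-lag: epoch $e$'s statistics in a record are consumed
only once the filter has moved $\mathrm{lag}_e$ beyond the record's locus,
with the then-current normalised weights.  The natural lag scale is the
genomic correlation distance of tree nodes of that epoch's age.  On the
first iteration we use the analytic estimate $1/(2\rho t_e)$ at the epoch
midpoint (a node of age $t$ carries about $2t$ of descendant branch, hence
is destroyed at rate $2\rho t$ per bp) — note recent epochs get the *long*
lags; later iterations use the empirical mean creation-to-removal distance
of nodes per epoch, pooled over particles, falling back to the analytic
value for epochs with no observed removals.  The lag multiplier
$\alpha_{\mathrm{lag}}$ defaults to 1.  At the end of the sequence all
remaining records are harvested regardless of lag (discarding the final
window is selectable but wastes data on short test genomes).

Rates update either by stochastic EM, $\hat\theta = E[c]/E[q]$ per event
type (the recombination rate is a single constant; coalescence rates are
per-epoch), or by Variational Bayes with conjugate Gamma posteriors:
$\alpha' = \alpha_0 + E[c]$, $\beta' = \beta_0 + E[q]$.  The VB pass
samples paths at the posterior-mean rates and multiplies a particle's
weights by $\eta = e^{\psi(\alpha)}/\alpha$ per sampled event, which tilts
the path distribution toward the VB optimum; $\eta < 1$ always and
$\eta \to 1$ as $\alpha \to \infty$.  Defaults: $\alpha_0 = 1$ and
$\beta_0 = \alpha_0/\theta_{\mathrm{init}}$, i.e. a weak prior whose mean
is the initial rate guess and whose weight is about one event — weak,
scale-matched, and free of zero-rate fixed points.  Because iteration 1 has
no data-informed posterior, applying $\eta(\alpha_0) = 0.56$ to every
sampled event there would penalise path length itself and collapse the
ensemble at practical particle counts; the first pass therefore samples at
the initial point rates, and the $\eta$-weighted VB path distribution is
targeted from iteration 2 onward, where $\alpha$ is large for
well-observed event types and $\eta$ is near 1 exactly where it matters
little.  VB expectations use the target weights $w$ (not $v$), since they
estimate posterior functionals.

Only re-coalescence excursions contribute coalescence counts and
opportunities; the $n-1$ coalescences of the initial tree at a chunk start
are $O(1)$ against the $O(|x|)$ recorded events and are not harvested.
Genomes may be processed as independent chunks whose statistics are summed
before each update; cross-chunk genealogy continuity is knowingly
sacrificed.

## The simulator

`simulate_genomes()` runs the same jump process forward along the genome
and drops mutations per segment at rate $\mu B$, so simulated data follow
exactly the model the filter assumes — including piecewise-exponential
growth epochs (ms-style sign convention: positive growth means expansion
forward in time), which the zigzag-style scenarios need but which inference
itself does not estimate (inference requires piecewise-constant $C$).  What
passing tests on these data show is therefore internal consistency of
model, simulator and filter; they cannot show robustness to features real
data have and the model lacks: recurrent and doublet mutations, gene
conversion, variable recombination and mutation maps, background selection,
phasing and calling errors.  Positions are continuous internally and
rounded to integer base pairs only at the VCF boundary (colliding
duplicates dropped).

## Numerical and interface choices

* Exponentials with $|x| < 0.03$ use the continued fraction
  $1 + 2x/(2 - x + x^2/6)$ (relative error below $10^{-10}$, asserted over
  a dense grid); weights live in log space with a running offset folded
  out whenever the maximum drifts past $\pm 200$.
* Epochs and genomic intervals are half-open $[a, b)$; a time exactly on a
  boundary belongs to the later epoch.  Loci are 0-based and continuous; a
  site lying exactly on a waypoint is evaluated on the tree at arrival.
* One seeded R RNG drives every stochastic choice (also inside the
  compiled engine), in documented order, so a run is bit-reproducible from
  `set.seed()`.
* Epoch grids parse from explicit boundary lists, log-spaced
  "A B k*1" triples, and PSMC-style merge patterns over a base grid;
  multiplicities that do not cover the base grid are an error.
* Degenerate inputs: $n < 2$, non-positive $N_e$, growth in the final
  epoch, all-missing patterns, carrier-free patterns, overlapping masks
  and inconsistent record chains are rejected with specific errors; an
  epoch whose expected coalescence opportunity falls below one
  branch-generation triggers a merge-epochs warning.

## Problem sizes used by the test suite

The suite exercises the method at sizes chosen to give stable Monte Carlo
verdicts in minutes on one core: the emission identity on 100 random trees
($n \le 8$); the closed-form $n = 2$, $\rho = 0$ oracle at $10^4$
particles; cherry equilibrium on $10^5$ stationary trees for
$n \in \{4, 6, 8\}$; ESS retention on a 1 Mb constant-size simulation;
filter self-consistency on 200 kb across 20 seeds; the directional
recent-epoch bias comparison on 15 replicates of 500 kb; and full recovery
of a constant $N_e = 10^4$ from two diploids over 5 Mb with 1000 particles
and five VB iterations.  Larger designs sharpen all of these but change
none of their logic.

## Known limitations

Beyond the model restrictions above: no migration, admixture or population
splits (the jump-process machinery would admit them, but neither simulator
nor estimator implements them); a single constant recombination rate along
the genome; phased-or-unphased but not genotype-likelihood input; the
lookahead digest ignores tripletons and higher frequency classes; and the
recent-most epochs (younger than a few hundred generations) remain hard at
desk-scale particle counts, as the directional-bias test's tolerances
reflect.
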