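---
title: "Modelling differential expression dynamics with dynb"
author: "dynb authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling differential expression dynamics with dynb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A replicated RNA-seq time course asks two coupled questions: does a gene's
expression *trajectory* differ between two biological conditions, and do
the biological replicates even run on the same clock? In differentiation
experiments (the motivating system is the polarization of naive CD4+
T helper cells into the Th17 lineage versus plain activation, Th0, sampled
at 0, 12, 24, 48 and 72 h in three cultures), cultures routinely
differentiate at slightly different speeds, so a replicate can look
"different" at the last timepoints purely because it lags. Timepoint-wise
differential-expression tools cannot separate these effects; dynb models
them jointly.

## The model

For one gene, let $y_j(t_i)$ be the read count of replicate $j = 1,\dots,M$
at design timepoint $t_i$, $i = 1,\dots,N$. The model has three layers.

**Latent trajectory.** A latent expression trajectory $f$ carries a
Gaussian-process prior with constant mean $m$ and squared exponential
covariance $k(t_p, t_q) = \sigma_1 \exp(-\tfrac12 \sigma_2 |t_p - t_q|^2)$.
Any finite set of evaluations of $f$ is jointly Gaussian, which is all the
sampler needs.

**Observation model.** Counts are negative binomial with identity link,
$y_j(t_i) \sim \mathrm{NB}(\mu, \sigma^2(\mu))$ with mean
$\mu = s_{j,i}\, f(t'_{j,i})$, where $s_{j,i}$ is the library-size factor
of the sample (median-of-ratios; the scaling is applied to the latent
trajectory, not to the discrete counts) and $\sigma^2(\cdot)$ is a
quadratic mean-variance function
$\sigma^2(\mu) = a_0 + a_1 \mu + a_2 \mu^2$ pooled across all genes: genes
expressed at similar levels have similar variance, and borrowing strength
across genes stabilizes the variance estimate at 2-3 replicates. The NB is
parameterized from its moments, $p = (\sigma^2 - \mu)/\sigma^2$,
$r = \mu^2/(\sigma^2 - \mu)$, which requires $\sigma^2 > \mu$; a
multiplicative floor $\sigma^2(\mu) \ge \mu(1 + \epsilon)$ with
$\epsilon = 0.01$ keeps the distribution defined (and near-Poisson) where
the fitted polynomial dips below the mean.

**Time scaling.** Each replicate may run on its own clock: replicate $j$'s
effective time is $t'_{j,i} = k_j\, t_i$, with one reference replicate
fixed at $k = 1$ for identifiability (by default the second replicate, so
other cultures can drift in either direction). The factors are discrete:
$k = 1 + \Delta/T$ where the time difference $\Delta$ at the last design
timepoint $T = 72$ h runs from $-32$ to $+32$ h in 4 h steps — 17 grid
points with extreme factors $5/9$ and $13/9$. A single latent function
evaluated on every replicate's scaled grid couples the replicates: if a
replicate lags, its late samples sit on the *earlier* part of the shared
curve. The `timescale_convention = "divide"` switch reports divisor-style
factors $t' = t/k$ with $k = T/(T + \Delta)$; both conventions produce the
same effective times on the shared $\Delta$ grid, so the choice only
changes how $k$ is printed.

**Replicate nugget.** Each (replicate, timepoint) evaluation of the latent
trajectory carries independent Gaussian noise with variance
`nugget` $\times$ the local observation variance (default 0.5, i.e. half
an observation's worth of extra culture-level variability). This is a
model term, not a numerical trick: it represents replicate-level
biological variability beyond counting noise, and it is what couples
replicates on the observation-noise scale so that time scaling is
identified. With no nugget, coincident replicate coordinates are tied
exactly and the prior density becomes singular there, which both
misrepresents replicate variability and traps the time-scaling chain at
the identity.

## Priors

Gene-specific, data-dependent rules avoid per-gene tuning across five
orders of magnitude of expression:

* $\theta_2$ (inverse squared length-scale of the *proposal* kernel)
  $\sim U[0.5, 1]$, favouring smooth trajectories. Kernel distances are
  computed on a day scale (`time_unit_h = 24`), so this support
  corresponds to length scales of roughly 24-34 h — smooth over a 3-day
  course but able to follow a late induction. On an hour scale the same
  support would make adjacent 12 h timepoints essentially independent
  white noise, which contradicts the smoothing intent and destroys the
  identifiability of time scaling (scaling is identified *through* the
  coherence of one smooth curve across replicate grids).
* $\theta_1 = 10\,\mathrm{sd}(y)$, fixed per gene (floored at 10 for
  near-constant genes), caps the trajectory proposal amplitude.
* GP prior mean $m = (\max y + \min y)/2$;
  $\sigma_1 = \max\{500\, m,\ ((\max y - \min y)/2)^2\}$ and
  $\sigma_2 = 0.75$ per squared day. The $500 m$ rule is well-calibrated
  for weakly expressed genes; the range-based term guarantees the prior
  standard deviation covers half the gene's count swing. Without it, a
  strongly induced gene (counts $10^2$ to $10^5$) sits more than ten prior
  standard deviations outside its own prior, the prior quadratic term
  overwhelms the likelihood, and the posterior can neither track the
  counts nor move the time-scaling factors.
* Time-scaling prior: a pmf over the discrete $\Delta$ grid, by default a
  discretized Gaussian centered at zero delay with sd 12 h — symmetric
  around identity scaling, with ~99% of its mass inside the $\pm 32$ h
  grid. A uniform variant is available, and a nonzero mode
  (`k_prior_mode`) gives an informative delay prior for designs where all
  genes are expected to share a common lag.

## Posterior sampling

A Metropolis-Hastings sampler updates $(\theta_2, \mathbf{k}, f)$ jointly
(one accept/reject per iteration):

* $\theta_2^\ast \sim N_{[0.5,1]}(\theta_2, 0.01^2)$ (truncated normal;
  the truncation normalizers are kept in the proposal ratio because they
  do not cancel near the bounds);
* each non-reference replicate's $\Delta$ moves $+4$ h, $-4$ h or stays,
  with probability $1/3$ each; proposals beyond $\pm 32$ h carry zero
  prior mass and are always rejected, preserving the three-way proposal
  without reflection;
* $f^\ast$ takes a Gaussian random-walk step whose correlation structure
  is the squared exponential kernel at $\theta_2^\ast$ on the proposed
  scaled times, mixed with an independent component
  ($0.7\,R + 0.3\,I$), and whose per-coordinate amplitude is
  $\min(\sqrt{\theta_1},\ 0.4 \times \text{local observation sd})$.

Three of these choices deserve comment, because the textbook versions
fail quietly:

* *Per-coordinate proposal scale.* A single scalar amplitude
  $\sqrt{\theta_1}$ is a 20-sigma move at the low-count timepoints of a
  strongly induced gene, so once converged the chain would never move
  again (measured acceptance exactly 0). Scaling each coordinate to its
  local observation noise — which is precisely what a gene-level amplitude
  is trying to approximate — restores uniform acceptance across the
  count range, with $\sqrt{\theta_1}$ kept as the global cap.
* *Mixture proposal.* A pure kernel-correlated proposal is near-singular
  when replicate coordinates coincide; the reverse density of a move that
  decorrelates them underflows by thousands of nats and the time-scaling
  chain freezes. The independent component bounds the condition number so
  forward and reverse densities stay commensurate. The kernel stays
  exactly reversible: forward densities use the proposed
  $(\theta_2^\ast, k^\ast)$, reverse densities the current values.
* *Initialization.* Chains start at the cross-replicate per-replicate
  normalized count profile (floored at 1), $\theta_2 = 0.75$ and
  $\Delta = 0$. Starting the trajectory at the prior mean is also valid
  but needs a burn-in roughly the square of the count range over the
  proposal step, which is prohibitive for induced genes.

The acceptance ratio is computed entirely in log space. Defaults are
20,000 iterations, 5,000 burn-in, 4 chains — long enough that the
Gelman-Rubin potential scale reduction factor of the log-likelihood stays
below 1.1 on the benchmark fits (`psrf()`; the [0.5, 1]-truncated
$\theta_2$ random walk at proposal sd 0.01 mixes more slowly than the
rest of the state, so its own PSRF is the last to settle). For large gene
panels, shorter chains (e.g. 2,000/500 over 2 chains) give stable Bayes
factors; convergence should then be spot-checked.

## Evidence, Bayes factors and the differential call

The marginal likelihood of each model is estimated by the harmonic mean of
the sampled likelihoods,
$p(y) \approx \big(\tfrac1m \sum_i p(y \mid f^{(i)}, \theta^{(i)},
k^{(i)})^{-1}\big)^{-1}$, computed through log-sum-exp so spreads of
hundreds of nats cannot overflow. The harmonic-mean estimator is known to
be noisy; `dynb_fit()` therefore reports a bootstrap standard deviation of
the estimate over chain resamples, and more chains/iterations are one
configuration flag away.

For each gene, M1 fits one model per condition and M0 one pooled model
over both conditions' replicates (each replicate keeping its own size
factors and scaling factor, with one global reference). With equal prior
model probabilities,
$\mathrm{BF} = p(y \mid M_1)/p(y \mid M_0)$, and a gene is called
differential when $\mathrm{BF} > 10$ (strong evidence) *and* the
fold change between the two conditions' posterior-mean trajectories
exceeds 2 in at least one design timepoint. Fold changes use pseudocount
1, $\max(r, 1/r)$ with $r = (\bar f_1 + 1)/(\bar f_2 + 1)$. No
multiple-testing correction is applied across genes: the decision rule is
the per-gene evidence threshold, not a frequentist error rate.

## Normalization details

Size factors are median-of-ratios over genes with nonzero geometric mean,
rescaled to geometric mean 1. The mean-variance polynomial is fitted to
pooled per-(gene, condition, timepoint) sample means and unbiased sample
variances of *normalized* counts (normalizing first prevents library-size
differences inflating the variance). The default fit is on the log scale:
minimize $\sum\big(\log s^2 + c_n - \log(a_0 + a_1\mu +
a_2\mu^2)\big)^2$ with non-negative coefficients, where
$c_n = \log\tfrac{n-1}{2} - \psi(\tfrac{n-1}{2})$ corrects the downward
bias of the log of a chi-square-distributed sample variance. Relative
errors of sample variances are homoscedastic, so this gives every
expression stratum equal say; direct least squares on the raw pairs
(available via `method = "ls"`, optionally $1/\mu^2$-weighted) is
dominated by whichever stratum is noisiest and its linear coefficient is
unstable from data set to data set — in recovery simulations the log fit
returns all three coefficients within 10% at the standard 2 × 3 × 5
design, where raw-scale fits mis-estimate $a_1$ severely. The non-negative
constraint reflects that a variance law with negative terms is a
small-sample fitting pathology, not a model. One assumption remains, as
for all global normalization: the majority of genes share dynamics across
conditions.

## The synthetic-data generator

`simulate_counts()` draws from exactly the generative process above:
per-gene template trajectories (logistic induction, mirrored repression,
Gaussian transient, or flat), per-replicate scaling factors on the
discrete grid, per-sample size factors, and NB noise with the quadratic
variance law (default dispersion $(0, 1, 0.05)$, modest overdispersion;
size factors log-uniform on $[2/3, 3/2]$ in the panel scenarios).
`fig2_benchmark()` is the canonical delayed-replicate setting: one
IL17A-like induction (logistic from $\sim 10^2$ to $\sim 10^5$ counts,
midpoint 56 h, slope 0.2/h — the exact template is parametric since only
the magnitude range is fixed by the motivating data) in three replicates,
the first generated at $(48/72)\,t$ so its nominal 72 h sample behaves
like 48 h (true $\Delta = -24$ h, $k = 2/3$). `simulate_panel()` builds
null and differential two-condition panels; differential focal genes are
embedded in a 4:1 null background because median-of-ratios normalization
presumes a null majority — a panel consisting only of globally induced
genes would confound induction with sequencing depth.

What the generator does *not* emulate: zero inflation, transcript-length
or GC bias, within-condition correlation between genes, or continuous
(off-grid) time warps. Passing tests therefore demonstrate correctness of
the inference under the model's own assumptions, not robustness to every
artefact of real libraries.

Benchmark problem sizes used by the test suite, chosen to make the checks
statistically decisive at desk scale: the delayed-replicate benchmark is
fitted at the default 20,000 x 4 chains; prior-recovery checks use 20,000
draws (Kolmogorov-Smirnov distance of $\theta_2$ against $U[0.5,1]$ <
0.05) and 200,000 draws (total-variation distance of the $\Delta$
marginal against its prior < 0.05); the sampler's stationary distribution
is compared against a brute-force importance-sampling posterior on an
enumerable two-timepoint toy (total variation < 0.05 at $10^5$
iterations); normalization recovery uses 2,000 genes at the standard
design; Bayes-factor calibration uses 100 null
genes (at most 10% with BF > 10) and power 20 strongly induced genes (at
least 90% called) at 2,000-iteration chains.

## A worked single-gene run

```{r example}
library(dynb)

sim <- fig2_benchmark(seed = 1)
vf <- variance_function(sim$truth$dispersion)
fit <- dynb_fit(sim$counts, sim$sheet, gene = "IL17A_like",
                sf = 1, vf = vf, control = dynb_control(seed = 1))
summary(fit)
plot(fit)
timescale_posterior(fit, 1)   # the delayed replicate
predict(fit, times = seq(0, 72, by = 2))
```

For the single-gene benchmark the variance law and unit size factors come
from the generator's recorded truth: the polynomial is pooled genome-wide
in practice and cannot be re-estimated from one gene, and single-gene
"size factors" would absorb the dynamics themselves.

## Numerical choices, edge cases

* Degenerate genes: all-equal counts get $\theta_1$ floored at 10; genes
  with no reads in one condition are excluded from testing and flagged
  (`dynb_de()$excluded`), mirroring the expressed-gene filter of
  genome-wide analyses.
* Positivity: under the identity link, any proposed trajectory value
  $\le 0$ at an evaluation point gets log-likelihood $-\infty$ and is
  rejected — no clamping, so the NB stays exactly defined.
* Covariance diagonals carry a $10^{-6}$ relative numerical jitter on top
  of the replicate nugget; prior-only sampling (used for validating the
  sampler against its priors) substitutes a 1% relative nugget, without
  which coincident coordinates make the prior singular.
* Ties in the posterior-mode time difference resolve to the first grid
  value (most-negative); in practice posteriors at default chain lengths
  localize the mode to within one 4 h grid step.
* Per-gene and per-chain seeds derive deterministically from the master
  seed, so `dynb_de()` results do not depend on gene order and are
  bit-reproducible.

## Known limitations

* The harmonic-mean evidence estimator has infinite variance in theory;
  in calibration runs its noise stays well below the BF > 10 decision
  threshold for null genes, but borderline Bayes factors (say 3-30)
  should be read with its bootstrap spread in hand.
* Time scaling is discrete and linear ($t' = kt$, anchored at 0 h);
  nonlinear warps and start-point shifts are out of scope.
* Two conditions only in `dynb_de()`; the model itself poses no obstacle
  to more, but the pooled-null bookkeeping is written for pairs.
* The posterior-mode $\Delta$ can sit one grid step toward deceleration
  for strongly induced genes: over-delay compresses a replicate's
  coordinates into the flat low-count region where mismatches are cheap,
  an asymmetry of the likelihood rather than a sampler artefact.
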