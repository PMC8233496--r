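---
title: "Models and methods in chronotree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in chronotree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronotree)
```

chronotree estimates evolutionary timetrees from rooted phylogenies with
branch lengths, using a relative-rate relaxed-clock framework. This
vignette is the package's account of the science: the models, their
assumptions, the tunable parameters, the numerical choices, and what the
bundled simulator does and does not establish about real data.

## The relative-rate framework

The input is a rooted phylogram: branch lengths in expected substitutions
per site. A branch length is the product of an elapsed time and an
evolutionary rate, so times are only identifiable up to rate assumptions.
Instead of assuming a single clock, `reltime()` estimates a *relative*
rate for every lineage by comparing sister subtrees, post-order:

At a node with children $c_1, c_2$, let $d(c_i)$ be the child's branch
length plus the mean rate-adjusted node-to-tip path length below it. Since
sister lineages span the same amount of time, the ratio of their depths
estimates the ratio of their rates; chronotree uses the symmetric form

$$ r(c_1) = \frac{2\,d(c_1)}{d(c_1)+d(c_2)}, \qquad
   r(c_2) = \frac{2\,d(c_2)}{d(c_1)+d(c_2)}, $$

so the two local rates average to 1 at every node. A lineage's rate is
the product of local rates on its root path. Dividing each branch by its
lineage rate makes the tree exactly ultrametric by construction, and the
adjusted node heights — identical through either child, which the test
suite asserts to 1e-9 — normalized by the root height are the *relative
node times* $t_{rel} \in [0, 1]$.

Assumptions and consequences:

* Rates are compared only between sister lineages; no global prior on
  rate variation is imposed. An ultrametric input is a fixed point: all
  rates are exactly 1 and relative times equal normalized node heights.
* The estimate is invariant to rescaling all branch lengths, so the
  substitutions/site unit convention is immaterial to relative times.
* Polytomies are resolved as caterpillars of zero-length branches (input
  order preserved) and single-child chains are collapsed first; an
  all-zero subtree gets unit local rates with a warning rather than a
  division failure. Lineage rates are floored at 1e-9.
* Sister averaging uses the arithmetic mean of tip paths. Whether a
  geometric mean would behave better deep in large trees is an open
  methodological question; the arithmetic form is fixed here and validated
  by the clock-identity and simulation-recovery properties.

Uncertainty is propagated by Monte Carlo (`monte_carlo_time_samples()`):
every lineage rate is perturbed by independent lognormal noise with a
chosen coefficient of variation (`rate_cv`), heights are recomputed, and
the replicate matrix of relative times drives all confidence intervals.
When only a tree is supplied (no alignment), the variance contributed by
branch-length estimation cannot be reproduced, so these intervals are
deliberately narrower than full-data intervals would be; `rate_cv`
defaults to 0.2, an arbitrary but explicit choice the user should override
when better information about rate heterogeneity exists (for the
simulation studies below we set it to the generating value,
$\sqrt{e^{\sigma^2}-1}$ for lognormal rates with log-sd $\sigma$).

## Node calibrations

`fit_time_scale()` converts relative times into absolute times with a
single scaling factor $f$: $t(v) = f \cdot t_{rel}(v)$. Calibrations
attach prior information about node ages:

| kind | parameters | role in fitting |
|------|------------|-----------------|
| normal | mean, sd | log-density term |
| lognormal | offset, mean, sd (log scale, on time − offset) | log-density term; support bounds $f$ |
| exponential | offset, decay (rate, on time − offset) | log-density term; support bounds $f$ |
| uniform | min, max | bounds $f$; flat density inside |
| point | time | fixes $f$ (hard constraint) |
| minbound / maxbound | time | one-sided hard constraint on $f$ |

$f$ maximizes the sum of log densities over the feasible interval implied
by the hard constraints (all-normal sets have the weighted least-squares
closed form; mixed sets use 1-D numerical maximization with tolerance
1e-9). Fitting one shared factor rather than averaging per-calibration
scales keeps the objective well defined with mixed density types. An
infeasible constraint pair is an error that names both constraints; a
density that is zero everywhere on the feasible interval is an error too,
rather than a silent boundary fit. With only uniform calibrations any
interior point is optimal and the midpoint of the feasible interval is
returned, a documented tie-break.

After scaling, ages are clamped into any per-node hard windows and a
single upward max-propagation pass restores parent ≥ child order (bounds
can otherwise invert it). CIs take the 2.5/97.5 percentiles of
$f_r \cdot t_{rel,r}$ across Monte-Carlo replicates, where each replicate
draws a fresh age from every density calibration and refits $f_r$ by
least squares against the replicate's relative times — so calibration
uncertainty and rate heterogeneity both enter the interval. CI bounds are
clamped into the same hard windows.

`fixed_rate_scale()` covers the common no-calibration situation: a known
substitution rate converts adjusted heights directly to ages.

## Tip dating (RelTime with dated tips)

For serially sampled sequences (fast-evolving pathogens, ancient DNA),
`rtdt_fit()` estimates a global rate $\mu$ and root date $T_0$ from the
sampling dates themselves. The naive approach — regressing raw
root-to-tip distances on dates — is exact under a strict clock but
degrades with rate variation; plain relative-rate adjustment, on the other
hand, would force all tips to identical adjusted depths and erase the date
signal. chronotree therefore estimates lineage rates on a *time-completed*
tree: each dated tip's terminal branch is provisionally extended by
$\hat\mu\,(s_{max} - s_j)$, which under a clock makes the completed tree
exactly ultrametric (undated tips are provisionally pinned to the deepest
sampled horizon). Rates from that tree adjust the *original* depths
$D_j$, which are regressed by unweighted least squares on sampling dates,

$$ D_j = \mu\,(s_j - T_0), $$

and the completion is iterated (3 rounds; one round is already exact
under a clock — the bundled 3-tip fixture recovers $\mu = 0.01$/year and
$T_0 = 1990$ to 1e-9). Node dates are $T_0 + \mathrm{depth}(v)/\mu$,
which makes ancestor-before-descendant exact by construction; tips with
unknown dates are placed on the same fitted axis and flagged as inferred.
Two structural laws are enforced by tests at 1e-9: shifting all dates by
$k$ shifts $T_0$ and all node dates by $k$ with $\mu$ unchanged, and
scaling all branch lengths by $k$ scales $\mu$ by $k$ with dates
unchanged. CIs re-fit the regression per Monte-Carlo rate perturbation;
replicates that lose temporal signal ($\hat\mu_r \le 0$) are dropped with
a warning when they exceed 10%.

Date conventions: ISO dates map to decimal years as
year + (day-of-year − 0.5)/days-in-year; year-only dates pin to January 1
and month-only dates to the 1st (`pin = "mid"` selects mid-interval
instead). A fit needs at least 3 dated tips spanning more than zero time,
and a non-positive fitted rate is reported as "no temporal signal" rather
than a numeric result.

## Neutral evolutionary probabilities (EP)

`ep_scores()` asks, for every alignment position: given the states of the
other species and the timetree, what is the posterior probability of each
possible allele in the focal (first) sequence? Alleles with EP below 0.05
are flagged evolutionarily nonneutral — under neutrality the observed
allele should be among the probable ones, so a low EP marks candidate
function-altering (disease or adaptive) variants.

The focal tip is treated as missing data. An inside (pruning) pass and an
outside pass meet at the focal tip, yielding its marginal posterior per
site; per-configuration scaling constants are tracked in log space and
discrete-gamma categories are mixed in log space, so long branches and
many categories do not underflow. The machinery is validated against
exhaustive summation over all internal-state assignments on small trees
(1e-9). Branch durations come from the input timetree, or from `reltime()`
when the input is a phylogram; one global rate converts durations to
expected substitutions, fitted by maximizing the likelihood of the
non-focal sequences (per-branch free rates would defeat the timetree
constraint). Nucleotide models are JC/HKY; the amino-acid default is the
Poisson equal-rates model — empirical exchangeability matrices are out of
scope, a documented limitation since real protein EP values are sensitive
to them. Sites where every non-focal sequence is missing fall back to the
stationary frequencies with a warning.

## Testing rate autocorrelation

`corrtest()` addresses a different question: are branch rates inherited
(autocorrelated) along lineages, or do they vary independently? The
statistic is a CorrScore in [0, 1] from a logistic model over four
features: Pearson and Spearman correlations of parent-child and of
sister-sister lineage-rate pairs. The coefficients were trained once on
the package's own simulator (independent-lognormal vs geometric-Brownian
rates, 400 trees per class, tip counts 50-300; the training script and its
seed ship in `scripts/train_corrtest.R`) and are frozen in the package.

One property matters for interpretation: estimated lineage rates are
products of local rates along root paths, so parent and child *estimates*
are positively correlated (~0.8 Pearson) even when the true branch rates
are independent. Raw feature values are therefore not interpretable
against zero. The P-value handles this by construction: it is the
fraction of independent-rate null simulations (fresh Yule topologies at
the same tip count, lognormal rates, log-sd 0.3) whose CorrScore reaches
the observed one, with the +1/(n+1) correction — so it is calibrated
against the estimator's own null behavior. Empirical type-I error at
$\alpha = 0.05$ measures ~0.04-0.07 across 400-replicate suites, and
power against a strongly autocorrelated alternative (step log-sd 0.15,
300 tips) is essentially 1. A strict-clock tree (zero rate variance) is
rejected as inapplicable, and fewer than 10 tips is an error because the
correlations are too unstable to score.

## The likelihood engine

All likelihood work runs on site configurations: the distinct columns of
the alignment, with integer weights summing to the site count L. The
total log-likelihood is the weight-weighted sum of configuration
log-likelihoods, so memory and time scale with the m distinct
configurations instead of L — the compression factor m/L is reported and
can be substantial for large or conserved alignments. Gaps and ambiguity
codes are treated as missing data (all-ones partials) but remain part of
a column's identity: two columns differing only in gap placement are
distinct configurations, a deliberate choice that keeps compression
conservative. The suite verifies the weighted sum against a site-by-site
oracle to 1e-9 on random alignments, and against an independent
implementation (phangorn) and brute-force state enumeration on small
cases.

Models: JC and HKY (+ discrete gamma with 4 categories by default) for
nucleotides, Poisson equal-rates for amino acids. This minimal zoo
exercises every algorithmic path (unequal frequencies, transition bias,
rate mixtures) without reproducing a full model catalogue; GTR, codon and
partitioned models are out of scope. Rate matrices are normalized to one
expected substitution per unit branch length; transition matrices come
from an eigendecomposition with rows renormalized, and are
row-stochastic to 1e-12 with P(0) = I.

Branch lengths for a fixed topology are optimized coordinate-wise
(round-robin scalar maximization per branch, tolerance 1e-6 on lengths,
at most 50 sweeps, lengths capped at 10 substitutions/site). The
log-likelihood is non-decreasing by construction; non-convergence warns
and returns the best tree. Under a reversible model the position of the
root on its two child branches is unidentifiable (only their sum is), a
standard caveat the tests respect.

## The synthetic-data generator

`simulate_timetree()` (Yule pure-birth via ape, ultrametric, true node
ages recorded), `apply_rate_model()` (strict / independent-lognormal /
geometric-Brownian autocorrelated branch rates, true rates recorded),
`sample_tip_dates()` (exponentially staggered sampling offsets within a
window) and `simulate_alignment()` (root states from stationary
frequencies, branch-wise evolution with the same transition matrices the
likelihood uses) generate every fixture in the test suite. All generators
require a seed and are bit-reproducible under it.

What the simulator emulates: clock-like and non-clock rate variation with
known truth, serial sampling, sequence evolution under the supported
models. What it does not: birth-death extinction, coalescent population
dynamics, recombination, indels and alignment error, model
misspecification, or branch-length estimation noise when a tree is taken
as given. Passing recovery tests therefore demonstrate correctness of the
estimators under their own assumptions — not robustness to the many ways
real data violate them.

Study sizes used by the test suite and `scripts/acceptance.R` (the
package's own choices, balancing Monte-Carlo error against desk-scale run
times): 100-200 random alignments for compression checks; 100 clock
trees for the identity property; 100 50-tip trees (lognormal rates,
log-sd 0.3, normal root calibration centered on the true age with 10%
sd, `rate_cv` matched to the generating value) for recovery and coverage;
100 serially sampled 50-tip clock trees for tip-dating recovery; 400
null and 50 alternative trees for the autocorrelation test's calibration
and power. Under those conditions measured values are: normalized
node-time error ~3% of the root age, CI coverage 92-94% at 95% nominal,
tip-dating rate error ~0 under the clock, type-I error 4-7% at the 5%
level, power ~1. Note the recovery metric is normalized by the root age;
per-node relative errors are dominated by very shallow nodes, whose two
or three noisy branches carry an irreducible ~20% relative error no
estimator can remove.

## Known limitations

* Relative times carry no absolute meaning without at least one
  calibration, rate, or dated tips.
* CIs from tree-only input omit branch-length estimation variance.
* The EP amino-acid model is Poisson; empirical matrices would change
  absolute EP values.
* The autocorrelation test's null fixes lognormal rate variation at
  log-sd 0.3; extreme real-data rate spreads may be less well calibrated.
* Outgroup handling reports rates but suppresses times for outgroup
  nodes; it does not re-root.
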