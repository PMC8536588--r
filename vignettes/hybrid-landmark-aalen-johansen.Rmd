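---
title: "Transition probabilities in partially non-Markov multi-state models"
author: "hajmsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transition probabilities in partially non-Markov multi-state models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hajmsm)
```

## The estimation problem

A multi-state process $X(t)$ moves between states $1,\dots,K$ along a set
$E$ of permitted direct transitions on a bounded interval $[0,\tau]$.  The
running example is the illness-death model with recovery: state 1
(employment), state 2 (sick leave), state 3 (permanent disability,
absorbing), with transitions $1\to2$, $1\to3$, $2\to1$, $2\to3$.  The
quantities of interest are the transition probabilities
$$P_{lk}(s,t) = \Pr\{X(t)=k \mid X(s)=l\}.$$

With counting processes $\bar N_{jk}$ and at-risk processes $\bar Y_j$
aggregated over $n$ subjects, the Nelson-Aalen estimator of the cumulative
transition rates is
$$\hat\Lambda_{jk}(t) = \int_s^t
  \frac{J_j(u)\,\mathrm{d}\bar N_{jk}(u)}{\bar Y_j(u)},
  \qquad J_j(u) = 1\{\bar Y_j(u)>0\},$$
with diagonal $\hat\Lambda_{jj} = -\sum_{k\neq j}\hat\Lambda_{jk}$, and the
Aalen-Johansen (AJ) estimator is the matrix product integral
$$\hat P^{\mathrm{AJ}}_l(s,t)
  = e_l \prod_{u\in(s,t]}\bigl(I + \Delta\hat\Lambda(u)\bigr).$$
The AJ estimator is consistent for $P_{lk}(s,t)$ only under the Markov
property.  Without it, one can condition by subsampling: the landmark
Aalen-Johansen (LMAJ) estimator applies the same product integral to the
rates estimated from the landmark population $\{i: X_i(s)=l\}$ only.  That
restores consistency for arbitrary dependence on the past, but the
landmark risk sets can be small, inflating the variance.

The hybrid landmark Aalen-Johansen (HAJ) estimator interpolates.  Given a
set $A\subseteq E$ of transitions flagged as non-Markov, it builds the
hazard matrix from landmark rates for transitions in $A$ and full-sample
rates for the rest,
$$\hat\Lambda^{(H)}_{jk} =
  \begin{cases}\hat\Lambda_{jk}, & jk\notin A,\\
  \hat\Lambda^{(\mathrm{LM})}_{jk}, & jk\in A,\end{cases}$$
and plugs it into the product integral.  $A=\emptyset$ reproduces AJ
exactly; $A=E$ reproduces LMAJ; in between, the estimator spends landmark
subsampling only where the Markov assumption actually fails.  An
equivalent construction removes non-landmark subjects from the risk sets
of the $A$-transitions only; the package implements hazard merging and
keeps the removal construction as an internal cross-check — the two agree
bitwise by design, and the test suite asserts this.

`transprob()` is the single fitting function; `method = "aj" | "lmaj" |
"haj"` selects the estimator:

```{r}
h <- toy_histories()
fit <- transprob(h, s = 0.5, l = 1, tau = 5, method = "haj",
                 nonmarkov = "2-1")
predict(fit, 4)
```

On this three-subject worked example all products can be done by hand:
the full-sample curve from time 0 is $(0.25, 0, 0.75)$ at $t=4$ and the
landmark/hybrid curve from $s=0.5$ is $(0.5, 0, 0.5)$.

## Data model and conventions

Histories are long-format sojourn records `id, entry, exit, from, to`; a
subject occupies `from` on `[entry, exit)`, and `to = 0` marks the end of
observation without a transition.  A final row with `to != 0` means the
subject entered that state and is taken to remain there (the usual case is
absorption), so paths are defined through $\tau$ without writing an
explicit closing row.  Conventions, chosen once:

* path evaluation $X(s)$ is right-continuous (the state *at* $s$);
  left limits $X(u-)$ are used only for at-risk counting;
* ties across subjects at one event time are aggregated into a single
  jump; within-subject simultaneous events are excluded by the strict
  `entry < exit` invariant;
* times are exact reals — no binning;
* subjects censored at or before a landmark time cannot be evaluated at
  $s$ and are excluded from the landmark population (they could not
  observably satisfy $X_i(s)=l$);
* probability rows are clipped to $[0,1]$ only for reporting; internally
  curves are exact products, and row sums stay within $10^{-12}$ of one.

Two algebraic identities pin down the implementation and are asserted
exactly (to $10^{-12}$) in the tests, on cohorts with complete observation:
the landmark curve equals the landmark occupancy fractions,
$e_l\hat P^{(\mathrm{LM})}(s,t) = \bar Y^{(\mathrm{LM})}(t+)/
\bar Y^{(\mathrm{LM})}_\bullet(s)$, and the AJ plug-in occupation
probabilities equal the empirical occupation fractions.

## Testing the Markov property transition by transition

For a transition $j\to k$, Markov behaviour implies that the intensity
given the landmark state does not depend on that state.  Two disjoint
landmark groups ($X(s)\in l_1$ vs $X(s)\in l_2$; by default $l_1$ is the
origin state of the tested transition and $l_2$ the remaining states) are
therefore compared with a standard two-sample log-rank statistic on the
transition-specific risk sets over $(s,\tau]$; the *point test* uses one
landmark time $s$ and the *grid test* takes the maximum statistic over a
grid $s_1,\dots,s_m$.

The null distribution of the maximum is approximated by a wild bootstrap:
each subject's martingale-residual contribution to every score $U(s_i)$ is
multiplied by one standardized compensated Poisson multiplier ($Q-1$,
$Q\sim\mathrm{Poisson}(1)$) per subject and replicate.  The multiplier is
*shared across grid times* within a replicate — this preserves the
dependence between the per-time statistics, which is what makes the
maximum's null distribution valid.  P-values use $(1+\#\{\mathfrak X^*\ge
\mathfrak X\})/(B+1)$, avoiding exact zeros.  Within-subject recurrence
violates the independence behind the hypergeometric variance (the default;
a Poisson-type variance is also available) — this is exactly why the grid
test is bootstrap-calibrated rather than referred to a chi-squared bound.

`select_nonmarkov()` runs the grid test on every transition and collects
those with $p < \alpha$ into $A$.  No multiple-testing adjustment is
applied: the tests are diagnostics, and $\alpha$ (default 0.05) acts as
the tuning parameter of the hybrid estimator.  Transitions carrying no
two-sample information (all variances zero, e.g. one group never occupies
the origin state) are reported as untestable and never selected.

## Variance estimation

For curves built on landmark subsamples the recommended tool is the
nonparametric bootstrap (`bootstrap_transprob()`): subjects are resampled
with replacement keeping their complete histories, the estimator is
recomputed per replicate, and pointwise sample variances and percentile
intervals are taken on the union of replicate jump grids.  By default the
non-Markov set is fixed from the original sample; `retest = TRUE` reruns
the selection inside each replicate, propagating selection uncertainty.
Replicates with an empty landmark population are kept as curves constant
at $e_l$ and counted in the output rather than silently dropped.

A Greenwood-type plug-in variance is also provided
(`variance = "greenwood"` in `transprob()`, or `greenwood_variance()`).
The exact recursion is a design choice of this package: the covariance of
the probability row is propagated through each factor and incremented by
the multinomial plug-in covariance of the increment rows,
$$V(u) = F(u)^\top V(u-)F(u) + \textstyle\sum_j p_j(u-)^2\,C_j(u),$$
with $C_j$ built from $\Delta\bar N_{jk}(\bar Y_j-\Delta\bar N_{jk})/
\bar Y_j^3$ terms.  For hybrid hazards, increments of the same origin row
estimated from different samples are treated as uncorrelated — a plug-in
approximation with no exact counterpart.  The recursion assumes
independent increments (Markov), so it can be anti-conservative for
landmark/hybrid curves; the tests validate it against the bootstrap on
Markov-simulated data (agreement within a third at $n=150$) and the
package treats it as the fast, approximate option.

## The frailty simulator

`simulate_histories()` generates cohorts on the illness-death model with
recovery (any `state_space()` plus rate table is accepted).  Conditional
on a subject's frailty vector $V$, the path is a time-homogeneous Markov
chain with intensities $\lambda_{jk} = V_{jk}\alpha_{jk}$, simulated by
competing exponential sojourns; marginally over a non-degenerate frailty
the process is non-Markov, with the frailty acting as the unobserved
shared past.  The defaults are the study conditions used throughout the
package's validation:

* baseline rates $\alpha = (\alpha_{12},\alpha_{13},\alpha_{21},
  \alpha_{23}) = (0.12, 0.03, 0.15, 0.1)$ per unit time, $\tau = 1000$;
* experiment 1: a gamma frailty with mean 1 and variance
  $\sigma^2\in\{0, 0.4, 1.2, 2\}$ on the $2\to1$ transition only, so
  exactly one transition is non-Markov when $\sigma^2>0$;
* experiment 2: the whole vector $V$ jointly log-normal with mean 1 and
  covariance `lognormal_frailty_sigma()`, making every transition
  non-Markov with strong cross-transition correlations;
* all subjects start in state 1 at time 0.  The initial rule is a package
  assumption (exposed via `initial`): a single cohort entry state is the
  natural reading of the employment example, and state-2 occupancy builds
  up well before the landmark grids used below.  At the earliest landmark
  time of experiment 2 ($s=1$) the state-2 population is accordingly
  small; results there carry large Monte-Carlo error.

Two details of the log-normal generator deserve a note, because the
obvious parameterisation is subtly infeasible.  For $V=\exp(W)$ to have
mean one and covariance $\Sigma$, $W$ must be normal with
$\mathrm{cov}(W_j,W_k) = \log(1+\Sigma_{jk})$ and
$EW_j = -\log(1+\Sigma_{jj})/2$ (the first-order version
$-\Sigma_{jj}/2$ undershoots the mean by ten percent at
$\Sigma_{jj}=0.8$, and the generator's moments are acceptance-tested, so
the exact mapping is used).  Second, the bundled $\Sigma$ — a published
matrix rounded to two decimals — makes $\log(1+\Sigma)$ indefinite: the
implied $\mathrm{corr}(W_3,W_4)$ is $-1.99$.  `draw_frailties()` therefore
rejects an infeasible matrix by default, reporting the offending
eigenvalue; with `repair = TRUE` (the bundled model's setting) the
$W$-correlation matrix is projected to the nearest correlation matrix
(`Matrix::nearPD`) while keeping $\mathrm{var}(W_j) = \log(1+\Sigma_{jj})$
fixed, so the mean (1) and variances ($\Sigma_{jj}$) of $V$ are preserved
exactly and only the infeasible correlations move.

Because the marginal process has no closed form under frailty, "true"
transition probabilities are themselves simulation-based:
`true_probability_oracle()` averages the LMAJ estimator over independent
fresh cohorts (the LMAJ is consistent without the Markov assumption, so
its average over many cohorts approximates the estimand; the residual
Monte-Carlo error shrinks with the number of repetitions and is the same
caveat any simulated truth carries).  Curves are averaged on a fixed
200-point evaluation grid rather than the union of all repetition jump
grids, which would grow without bound.

## Evaluation metrics and what the experiments show

`mrse()` implements the squared $L_2$ distance
$\int_s^\tau(f-g)^2\,\mathrm{d}t$ between step curves as a left-endpoint
Riemann sum on the union of jump times — exact for step functions.
`pointwise_bias_variance()` and `coverage_curve()` give the pointwise
summaries.  `run_frailty_experiment()` ties everything together: per
repetition it simulates a cohort, selects $A$ with the grid test applied
to all transitions (wild bootstrap, $B=500$, $\alpha=0.05$; landmark grid
$\{6,9,12,14,17,20,22,25,28,30\}$ for experiment 1 and
$\{1,4,6,\dots,30\}$ for experiment 2), and computes the three estimator
curves from each landmark time.

The package's acceptance tests rerun the core of experiment 1 at reduced
size and assert its qualitative conclusions: under the Markov null
($\sigma^2=0$) the grid test rejects at close to its nominal 5% level
(200 repetitions, $n=500$, $B=200$); at $\sigma^2=2$ the $2\to1$
transition is selected into $A$ in over 90% of repetitions, and for
$P_{21}(17,\cdot)$ the AJ estimator has a larger absolute bias than both
landmark estimators while the hybrid's pointwise variance does not exceed
the LMAJ's (200 repetitions of $n=1000$; truth from a 100-repetition
oracle; bias and variance averaged over a fixed one-unit grid on
$(17, 117]$, the window where state-2 landmark occupancy is
non-negligible).  These are scaled-down versions of the full study
(1000 repetitions), sized so the whole suite runs in minutes; the
directions, not the exact figures, are the assertions.

## Numerical and degenerate-input choices

* Empty risk sets contribute zero increments ($J_j$ convention); an empty
  landmark population yields a zero hazard and a curve constant at $e_l$ —
  legal everywhere, counted where it matters (bootstrap).
* Curve evaluation between jumps follows the right-continuous step
  convention; queries before the first jump return the initial vector.
* The point statistic is defined as 0 when its variance is 0 (no
  information), and an empty group yields statistic 0 with a flag rather
  than an error.
* With a landmark *set* $l$ (supported because the two-sample tests group
  by sets of states), the initial vector is the empirical occupancy
  distribution over $l$ at $s$ in the estimation sample.
* Seeds: every stochastic function accepts `seed` and restores the
  caller's RNG state; identical seeds give byte-identical output.

## Known limitations

* Censoring is representable and handled by risk-set exit, assuming
  independent censoring; there is no IPCW correction for dependent
  censoring, and no covariate-adjusted (Cox/additive) rates.
* Interval-censored or panel data are out of scope; sojourns must be
  exactly observed.
* The Greenwood-type recursion is approximate off the Markov case, as
  discussed above.
* The simulated "truth" is itself a Monte-Carlo object; comparisons
  against it inherit its error.
* What passing simulation tests show is fidelity to the frailty
  data-generating mechanism above — continuous event times (no ties
  beyond aggregation), no censoring before $\tau$, a single entry state.
  Real registry data have tied days, staggered entry and dependent
  censoring, none of which the generator emulates.
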