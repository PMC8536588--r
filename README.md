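# hajmsm

Transition probabilities in multi-state models that are Markov for some
transitions and not for others.

## The problem

In a multi-state model (states `1..K`, permitted direct transitions `E`),
the quantities epidemiologists usually want are the transition
probabilities

    P_lk(s, t) = Pr{ X(t) = k | X(s) = l },

for example the probability of being back at work at time *t* given sick
leave at time *s*.  The classical **Aalen-Johansen (AJ)** estimator — the
product integral `e_l ∏_{u ∈ (s,t]} (I + ΔΛ̂(u))` of the Nelson-Aalen
cumulative rate matrix — is consistent for these only under the Markov
property.  The **landmark Aalen-Johansen (LMAJ)** estimator restores
consistency for arbitrary history dependence by estimating the rates from
the landmark subsample `{i : X_i(s) = l}` only, but the subsample can be
small, so the variance grows.

The **hybrid landmark Aalen-Johansen (HAJ)** estimator implemented here
interpolates: given a set `A ⊆ E` of non-Markov transitions, it uses
landmark rates for transitions in `A` and full-sample rates elsewhere,

    Λ̂_jk^(H) = Λ̂_jk      for jk ∉ A,
    Λ̂_jk^(H) = Λ̂_jk^(LM)  for jk ∈ A,

and plugs the hybrid matrix into the product integral.  `A = ∅` gives AJ,
`A = E` gives LMAJ.  The set `A` is chosen by transition-wise two-sample
log-rank tests of the Markov property (point test at one landmark time,
grid test maximising over a landmark grid), calibrated by a wild
bootstrap with standardized compensated Poisson multipliers.  The result
is typically less biased than AJ and less variable than LMAJ.

The package also provides nonparametric bootstrap variance/percentile
intervals, a Greenwood-type plug-in variance, a frailty-driven simulator
of the illness-death model with recovery (intensities
`λ_jk = V_jk α_jk` with gamma or joint log-normal frailties `V`), a
simulation-based oracle for the true probabilities under frailty, and
evaluation metrics (MRSE, pointwise bias/variance, interval coverage).

## Worked example

Simulate 1000 subjects from the gamma-frailty design (variance 2 on the
2→1 transition, so exactly that transition is non-Markov), select the
non-Markov set, and compare estimators from landmark time `s = 17`,
landmark state 2 (sick leave):

```r
library(hajmsm)
h <- simulate_histories(1000, frailty = frailty_gamma(2), seed = 42)

sel <- select_nonmarkov(h, grid = experiment_defaults(1)$landmark_grid,
                        tau = 1000, B = 500, seed = 1)
sel
#>   transition     p_value
#> 1        1-2 0.477045908
#> 2        1-3 0.680638723
#> 3        2-1 0.001996008
#> 4        2-3 0.471057884
#> Non-Markov set A: 2->1

fit <- transprob(h, s = 17, l = 2, tau = 1000, method = "haj",
                 nonmarkov = sel$nonmarkov)
round(predict(fit, c(30, 60, 120)), 3)
#>        p1    p2    p3
#>  30 0.128 0.255 0.617
#>  60 0.030 0.012 0.957
#> 120 0.000 0.000 1.000

round(predict(transprob(h, 17, 2, 1000, "aj"), c(30, 60, 120)), 3)
#>        p1    p2    p3
#>  30 0.185 0.222 0.592
#>  60 0.040 0.011 0.949
#> 120 0.000 0.002 0.998
```

The grid test flags only the genuinely non-Markov 2→1 transition
(p = 0.002; the Markov transitions get p ≈ 0.5).  The AJ estimate of the
return-to-work probability `P_21(17, 30)` is 0.185 against the hybrid's
0.128: ignoring the frailty-induced selection in the sick-leave state
makes the Markov estimator too optimistic, while the hybrid corrects it
using the landmark sample only where needed.  Bootstrap intervals:

```r
bt <- bootstrap_transprob(h, 17, 2, 1000, "haj", nonmarkov = sel$nonmarkov,
                          B = 200, seed = 2)
#> P_21(17,60): 0.03   95% CI [0.012, 0.049]
```

A thin command-line wrapper over the same functions is in
`inst/cli/haj.R` (`simulate`, `estimate`, `test`, `bootstrap`
subcommands).

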